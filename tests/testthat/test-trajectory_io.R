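write_water_pdb <- function(path, n_models = 1L, shift = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models)) {
    if (n_models > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    x <- shift * (m - 1)
    writeLines(c(
      sprintf("ATOM      1  O   HOH W   1    %8.3f%8.3f%8.3f  1.00  0.00           O", x, 0, 0),
      sprintf("ATOM      2  H1  HOH W   1    %8.3f%8.3f%8.3f  1.00  0.00           H", x + 0.96, 0, 0),
      sprintf("ATOM      3  H2  HOH W   1    %8.3f%8.3f%8.3f  1.00  0.00           H", x - 0.24, 0.93, 0)),
      con)
    if (n_models > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

test_that("reading a water molecule assigns exactly one water_oxygen role", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_water_pdb(tf)
  top <- read_structure(tf)
  expect_equal(top$n_atoms, 3L)
  expect_equal(sum(top$atoms$role == "water_oxygen"), 1L)
  expect_equal(top$atoms$role[top$atoms$name == "O"], "water_oxygen")
  ## role assignment is a pure function of (res_name, name)
  expect_identical(read_structure(tf)$atoms$role, top$atoms$role)
})

test_that("malformed and invalid structure files are rejected with context", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH W   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      1  H1  HOH W   1       0.960   0.000   0.000  1.00  0.00           H"),
    tf)
  expect_error(read_structure(tf), "duplicate")
  writeLines("ATOM      1  O   HOH W   1       garbage", tf)
  expect_error(read_structure(tf), "line 1")
  writeLines("END", tf)
  expect_error(read_structure(tf), "no ATOM")
  ## insertion codes rejected
  writeLines(
    "ATOM      1  O   HOH W   1A      0.000   0.000   0.000  1.00  0.00           O",
    tf)
  expect_error(read_structure(tf), "insertion")
})

test_that("a synthetic peptide round-trips through the PDB writer", {
  pep <- synthetic_peptide(20L)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pep$top, pep$coords, tf)
  top2 <- read_structure(tf)
  expect_identical(top2$atoms, pep$top$atoms)
  traj2 <- read_trajectory(top2, tf)
  expect_equal(traj2$n_frames, 1L)
  expect_equal(frame_coords(traj2, 1), unname(pep$coords), tolerance = 1e-9)
})

test_that("multi-model PDB trajectories load with the declared frame count", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_water_pdb(tf, n_models = 5L, shift = 1.0)
  top <- read_structure(tf)
  traj <- read_trajectory(top, tf)
  expect_equal(traj$n_frames, 5L)
  expect_equal(traj$topology$n_atoms, 3L)
  expect_equal(frame_coords(traj, 3)[1, 1], 2.0)
  ## degenerate single-model file is a one-frame trajectory
  tf1 <- withr::local_tempfile(fileext = ".pdb")
  write_water_pdb(tf1, n_models = 1L)
  expect_equal(read_trajectory(top, tf1)$n_frames, 1L)
})

test_that("generator trajectories round-trip through both dialects", {
  spec <- make_paper_scenario_fixtures(n_frames = 20L, seed = 5L)$WT
  gen <- generate_toy_trajectory(spec)
  traj <- gen$trajectory
  ## multi-model PDB: 3-decimal format precision
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, tf, "pdb")
  back <- read_trajectory(traj$topology, tf, "pdb")
  expect_equal(back$n_frames, traj$n_frames)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
  expect_true(max(abs(back$coords - traj$coords)) <= 5e-4 + 1e-12)
  ## DCD: single-precision floats, read back through an independent reader
  td <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(traj, td, "dcd")
  back2 <- read_trajectory(traj$topology, td, "dcd")
  expect_equal(back2$n_frames, traj$n_frames)
  expect_equal(back2$coords, traj$coords, tolerance = 1e-5)
})

test_that("trajectory structural errors are caught", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_water_pdb(tf, n_models = 3L)
  top <- read_structure(tf)
  pep <- synthetic_peptide(2L)
  expect_error(read_trajectory(pep$top, tf), "mismatch")
  expect_error(read_trajectory(top, tf, dialect = "xtc"), "arg")
  expect_error(trajectory(top, array(Inf, c(1, 3, 3))), "finite")
})

test_that("the packaged scenario file loads with its substitution", {
  path <- system.file("extdata", "aH245G.yaml", package = "halfchannel")
  sc <- load_scenario(path)
  expect_s3_class(sc, "scenario_spec")
  expect_equal(sc$label, "aH245G")
  expect_equal(nrow(sc$substitutions), 1L)
  expect_equal(sc$substitutions$chain_id, "A")
  expect_equal(sc$substitutions$res_seq, 245L)
  expect_equal(sc$substitutions$from_res, "HIS")
  expect_equal(sc$substitutions$to_res, "GLY")
  expect_setequal(vapply(sc$regions, `[[`, "", "name"), c("W1", "W2/W3"))
})

test_that("scenario validation fills defaults and rejects bad configs", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("label: WT",
               "source: {chain: A, resseq: 219}",
               "sink: {chain: C, resseq: 61}"), tf)
  sc <- load_scenario(tf)
  expect_equal(vapply(sc$regions, `[[`, "", "name"), c("W1", "W2", "W3"))
  writeLines(c("source: {chain: A, resseq: 219}"), tf)
  err <- tryCatch(load_scenario(tf), error = conditionMessage)
  expect_match(err, "label")
  expect_match(err, "sink")
  writeLines(c("label: x",
               "source: {chain: A, resseq: 219}",
               "sink: {chain: C, resseq: 61}",
               "regions:",
               "  - {name: W1, anchor_a: {resseq: 214}, anchor_b: {resseq: 61}}",
               "  - {name: W1, anchor_a: {resseq: 245}, anchor_b: {resseq: 214}}"),
             tf)
  expect_error(load_scenario(tf), "duplicate region")
  ## scenario YAML round trip
  sc2 <- toy_scenario("WT")
  ty <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc2, ty)
  sc3 <- load_scenario(ty)
  expect_equal(sc3$label, sc2$label)
  expect_equal(length(sc3$regions), length(sc2$regions))
})

test_that("results tables round-trip and enforce a shared schema", {
  tf <- withr::local_tempfile(fileext = ".csv")
  write_results(data.frame(a = numeric(), b = character()), tf, "csv")
  expect_equal(readLines(tf)[1], "\"a\",\"b\"")
  expect_equal(length(readLines(tf)), 1L)
  tj <- withr::local_tempfile(fileext = ".json")
  write_results(list(list(region = "W1", occupancy_pct = 92)), tj, "json")
  back <- read_results(tj, "json")
  expect_equal(nrow(back), 1L)
  expect_equal(back$occupancy_pct, 92)
  ## packaged stability table round-trips losslessly through JSON
  tab <- load_stability_table()
  write_results(tab, tj, "json")
  expect_equal(read_results(tj, "json"), tab)
  expect_error(write_results(list(list(a = 1), list(b = 2)), tj, "json"),
               "schema")
})
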