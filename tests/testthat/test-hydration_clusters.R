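## A two-residue topology with CA anchors plus a pool of water oxygens at
## controllable positions.
anchored_system <- function(n_waters, anchor_a = c(0, 0, 0),
                            anchor_b = c(2, 0, 0)) {
  rows <- rbind(
    data.frame(serial = 1L, name = "CA", element = "C", res_name = "GLY",
               res_seq = 1L, chain_id = "A", stringsAsFactors = FALSE),
    data.frame(serial = 2L, name = "CA", element = "C", res_name = "GLY",
               res_seq = 2L, chain_id = "A", stringsAsFactors = FALSE))
  if (n_waters > 0L)
    rows <- rbind(rows, data.frame(
      serial = 2L + seq_len(n_waters), name = "O", element = "O",
      res_name = "HOH", res_seq = seq_len(n_waters), chain_id = "W",
      stringsAsFactors = FALSE))
  top <- topology(rows)
  coords <- rbind(anchor_a, anchor_b,
                  matrix(0, n_waters, 3))
  list(top = top, coords = unname(coords))
}

region12 <- function(radius = 3.5)
  cluster_region("R", list(chain = "A", resseq = 1L, name = "CA"),
                 list(chain = "A", resseq = 2L, name = "CA"), radius)

test_that("region centers are anchor-centroid midpoints per frame", {
  sys <- anchored_system(0)
  expect_equal(resolve_region_center(sys$coords, region12(), sys$top),
               c(1, 0, 0))
  ## coincident single-atom anchors
  sys2 <- anchored_system(0, anchor_a = c(3, 1, 2), anchor_b = c(3, 1, 2))
  expect_equal(resolve_region_center(sys2$coords, region12(), sys2$top),
               c(3, 1, 2))
  ## multi-atom anchors: direct arithmetic oracle
  rows <- data.frame(
    serial = 1:4, name = c("CA", "CB", "CA", "CB"), element = "C",
    res_name = "ALA", res_seq = c(1L, 1L, 2L, 2L), chain_id = "A",
    stringsAsFactors = FALSE)
  top <- topology(rows)
  m <- rbind(c(0, 0, 0), c(2, 2, 0), c(10, 0, 0), c(10, 4, 2))
  rg <- cluster_region("R", list(resseq = 1L), list(resseq = 2L), 3)
  expect_equal(resolve_region_center(m, rg, top),
               (colMeans(m[1:2, ]) + colMeans(m[3:4, ])) / 2)
  bad <- cluster_region("R", list(resseq = 9L), list(resseq = 2L), 3)
  expect_error(resolve_region_center(m, bad, top), "anchor_a")
})

test_that("water counts respect the inclusive radius boundary", {
  sys <- anchored_system(0)
  expect_equal(count_waters_in_region(sys$coords, region12(), sys$top), 0L)
  ## 3 waters just inside, 2 just outside a 3.5 A radius around (1,0,0)
  sys5 <- anchored_system(5)
  r <- 3.5
  inside <- c(1, 0, 0) + c(r - 0.1, 0, 0)
  outside <- c(1, 0, 0) + c(r + 0.1, 0, 0)
  sys5$coords[3:5, ] <- matrix(rep(inside, 3), 3, byrow = TRUE) +
    cbind(0, c(-0.3, 0, 0.3), 0)
  sys5$coords[6:7, ] <- matrix(rep(outside, 2), 2, byrow = TRUE)
  expect_equal(count_waters_in_region(sys5$coords, region12(r), sys5$top), 3L)
  ## brute-force distance oracle on random placements
  set.seed(31)
  sysr <- anchored_system(40)
  sysr$coords[3:42, ] <- matrix(runif(120, -6, 8), 40, 3)
  ctr <- c(1, 0, 0)
  brute <- sum(sqrt(rowSums(sweep(sysr$coords[3:42, ], 2, ctr)^2)) <= r)
  expect_equal(count_waters_in_region(sysr$coords, region12(r), sysr$top),
               brute)
})

test_that("cluster statistics follow their definitions exactly", {
  ## counts [0, 1, 2, 1] over 4 frames
  sys <- anchored_system(2)
  far <- c(50, 0, 0)
  fr <- array(NA_real_, c(4, 4, 3))
  place <- function(w1, w2) rbind(c(0, 0, 0), c(2, 0, 0), w1, w2)
  fr[1, , ] <- place(far, far)
  fr[2, , ] <- place(c(1, 1, 0), far)
  fr[3, , ] <- place(c(1, 1, 0), c(1, -1, 0))
  fr[4, , ] <- place(far, c(1, 0, 1))
  traj <- trajectory(sys$top, fr)
  st <- cluster_stats(traj, region12())
  expect_equal(st$count_series, c(0L, 1L, 2L, 1L))
  expect_equal(st$occupancy_pct, 75)
  expect_equal(st$capacity_pdf, c(`0` = 0.25, `1` = 0.5, `2` = 0.25))
  ## invariants: pdf normalization and occupancy/pdf consistency
  expect_equal(sum(st$capacity_pdf), 1, tolerance = 1e-12)
  expect_equal(st$occupancy_pct, 100 * (1 - st$capacity_pdf[["0"]]))
  ## all-frames occupied
  traj2 <- trajectory(sys$top, fr[2:4, , , drop = FALSE])
  expect_equal(cluster_stats(traj2, region12())$occupancy_pct, 100)
})

test_that("enlarging the radius never decreases counts or occupancy", {
  gen <- generate_toy_trajectory(
    make_paper_scenario_fixtures(n_frames = 40L, seed = 13L)$WT)
  sc <- toy_scenario("WT")
  base <- sc$regions[[1]]
  radii <- c(2.0, 3.5, 5.0, 8.0)
  stats <- lapply(radii, function(r)
    cluster_stats(gen$trajectory,
                  cluster_region(base$name, base$anchor_a, base$anchor_b, r)))
  for (i in seq_len(length(radii) - 1L)) {
    expect_true(all(stats[[i + 1]]$count_series >= stats[[i]]$count_series))
    expect_gte(stats[[i + 1]]$occupancy_pct, stats[[i]]$occupancy_pct)
  }
})

test_that("scenario comparison flags absent clusters and occupancy drops", {
  specs <- make_paper_scenario_fixtures(n_frames = 150L, seed = 3L)
  run <- function(nm) {
    gen <- generate_toy_trajectory(specs[[nm]])
    sc <- toy_scenario(nm, specs[[nm]]$substitutions)
    st <- lapply(sc$regions, function(r) cluster_stats(gen$trajectory, r))
    names(st) <- vapply(sc$regions, `[[`, "", "name")
    st
  }
  wt <- run("WT"); mut <- run("aH245G")
  cmp <- compare_cluster_stats(list(WT = wt, aH245G = mut))
  w23 <- cmp[cmp$region == "W2/W3", ]
  expect_true(w23$cluster_absent[w23$scenario == "aH245G"])
  expect_false(w23$cluster_absent[w23$scenario == "WT"])
  expect_false(any(cmp$cluster_absent[cmp$region == "W1"]))
  ## identical inputs give zero deltas
  cmp0 <- compare_cluster_stats(list(a = wt, b = wt))
  expect_true(all(cmp0$delta_occupancy_pct == 0))
  expect_error(compare_cluster_stats(list(a = wt)), "at least two")
  expect_error(compare_cluster_stats(list(a = wt, b = wt["W1"])), "mismatch")
})

test_that("occupancy deltas track generator presence probabilities", {
  ## p = 0.9 vs p = 0.3: delta within 3 binomial SE of -60 points
  nf <- 400L
  mk <- function(p, seed) {
    cm <- toy_cluster_model("W1", p, c(`1` = 1), c(12.9, 0, 0))
    spec <- toy_system_spec(paste0("p", p), cluster_models = list(cm),
                            n_frames = nf, seed = seed)
    gen <- generate_toy_trajectory(spec)
    rg <- toy_scenario("x")$regions[[1]]
    cluster_stats(gen$trajectory, rg)$occupancy_pct
  }
  d <- mk(0.3, 101L) - mk(0.9, 102L)
  se <- 100 * sqrt(0.9 * 0.1 / nf + 0.3 * 0.7 / nf)
  expect_lt(abs(d - (-60)), 3 * se)
})
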