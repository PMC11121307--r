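## Pipeline orchestration: run the full analysis stack for one scenario,
## and compare verdicts and hydration across scenarios.

.study_label_order <- function() {
  c("WT", "aE219G", "aE219Q", "aH245G", "aH245S", "aH245Y",
    "aN214L", "aN214H", "aE219H/aH245E", "aQ252L")
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

#' Run the analysis stack for one scenario
#'
#' Executes, in order: the stability battery (backbone RMSD series, radius
#' of gyration, SASA, intramolecular hydrogen-bond count), water-cluster
#' statistics for every region, the proton-transfer-chain verdict,
#' side-chain SP classification for aN214 when present, and gate-contact
#' statistics.  A failing stage marks the report `partial` and names the
#' stage; later stages still run.
#'
#' @param scenario A [scenario_spec()].
#' @param traj A [trajectory()] resolving against the scenario.
#' @param config Named list of options: `hbond_cutoff` (default 3),
#'   `connectivity_threshold_pct` (5), `absent_threshold_pct` (5),
#'   `sasa_frames` (frames sampled for SASA, default up to 5), `seed` (1),
#'   `sp_residue` (`list(chain=,resseq=)` or `NULL` to autodetect aN214).
#' @return Object of class `"scenario_report"`.
#' @export
run_scenario <- function(scenario, traj, config = list()) {
  defaults <- list(hbond_cutoff = 3.0, connectivity_threshold_pct = 5,
                   absent_threshold_pct = 5, sasa_frames = 5L, seed = 1L,
                   sp_residue = NULL)
  config <- utils::modifyList(defaults, config)
  crit <- hbond_criteria(config$hbond_cutoff)
  top <- traj$topology
  status <- "complete"
  failed_stages <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      status <<- "partial"
      failed_stages <<- c(failed_stages, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }
  stability <- stage("stability", {
    bb <- atom_select(top, name = backbone_atom_names())
    prot <- which(top$atoms$chain_id != "W" &
                  !(top$atoms$res_name %in% top$water_names))
    rmsd <- rmsd_series(traj, bb)
    rg <- mean(vapply(seq_len(traj$n_frames), function(f)
      radius_of_gyration(frame_coords(traj, f), prot,
                         element_masses()[top$atoms$element[prot]]), 0))
    sf <- unique(round(seq(1, traj$n_frames,
                           length.out = min(config$sasa_frames, traj$n_frames))))
    radii <- topology_radii(top)
    sasa_mean <- mean(vapply(sf, function(f) {
      m <- frame_coords(traj, f)
      sasa(m[prot, , drop = FALSE], radii[prot])$total
    }, 0))
    hb <- mean(vapply(seq_len(traj$n_frames), function(f)
      count_intramolecular_hbonds(frame_coords(traj, f), top, crit), 0L))
    list(rmsd_mean_A = rmsd$mean, rg_mean_A = rg,
         sasa_mean_A2 = sasa_mean, hbond_mean = hb)
  })
  clusters <- stage("hydration", {
    st <- lapply(scenario$regions, function(rg) cluster_stats(traj, rg))
    names(st) <- vapply(scenario$regions, `[[`, "", "name")
    st
  })
  verdict <- stage("chain", connectivity_fraction(
    traj, scenario, crit, config$connectivity_threshold_pct))
  sp <- stage("sidechain", {
    spres <- config$sp_residue
    if (is.null(spres)) spres <- list(chain = "A", resseq = 214L)
    term <- atom_select(top, chain = spres$chain, resseq = spres$resseq,
                        role = "polar")
    if (length(term) == 0L || traj$n_frames < 10L) NULL
    else classify_sp(traj, spres, top$atoms$name[term], seed = config$seed)
  })
  contacts <- stage("contacts", {
    gr <- scenario$gate_residues
    if (length(gr) < 2L) NULL
    else {
      out <- list()
      for (i in seq_len(length(gr) - 1L)) for (j in (i + 1L):length(gr)) {
        sa <- list(chain = gr[[i]]$chain, resseq = gr[[i]]$resseq, role = "polar")
        sb <- list(chain = gr[[j]]$chain, resseq = gr[[j]]$resseq, role = "polar")
        if (length(resolve_selection(top, sa)) == 0L ||
            length(resolve_selection(top, sb)) == 0L) next
        lab <- paste0(gr[[i]]$chain, gr[[i]]$resseq, "-",
                      gr[[j]]$chain, gr[[j]]$resseq)
        out[[lab]] <- contact_fraction(traj, sa, sb,
                                       cutoff = config$hbond_cutoff, label = lab)
      }
      out
    }
  })
  structure(list(label = scenario$label,
                 stability = stability, clusters = clusters,
                 verdict = verdict, sp = sp, contacts = contacts,
                 status = status, failed_stages = failed_stages,
                 provenance = list(package_version =
                                     as.character(utils::packageVersion("halfchannel")),
                                   schema_version = 1L,
                                   seed = config$seed,
                                   config_hash = .config_hash(config),
                                   n_frames = traj$n_frames)),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario report:", x$label, "(", x$status, ")\n")
  if (!is.null(x$verdict)) print(x$verdict)
  invisible(x)
}

#' Serialize a scenario report to JSON
#'
#' Deterministic given the report (no timestamps), so identical runs
#' produce byte-identical files.
#'
#' @param report A [run_scenario()] result (or a list of them).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, "cluster_stats"))
      return(list(name = x$name, occupancy_pct = x$occupancy_pct,
                  capacity_pdf = as.list(x$capacity_pdf),
                  count_series = x$count_series))
    if (inherits(x, "chain_verdict"))
      return(list(label = x$label,
                  connectivity_fraction = x$connectivity_fraction,
                  verdict = x$verdict, broken_links = x$broken_links,
                  witness_path = x$witness_path,
                  threshold_pct = x$threshold_pct))
    if (inherits(x, "sp_assignment"))
      return(list(residue = x$residue, k = x$k,
                  occupancy_pct = as.list(x$occupancy_pct)))
    if (inherits(x, "contact_stats"))
      return(list(pair = x$pair,
                  contact_fraction_pct = x$contact_fraction_pct,
                  cutoff = x$cutoff))
    if (is.list(x)) return(lapply(x, to_plain))
    x
  }
  jsonlite::write_json(to_plain(unclass(report)), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Compare scenario reports
#'
#' One row per scenario with the chain verdict, connectivity percentage,
#' per-region occupancy and capacity mode, and absent-cluster flags; rows
#' follow the study's mutant listing order (wild type first).
#'
#' @param reports List of [run_scenario()] results (>= 2, unique labels).
#' @param absent_threshold_pct Occupancy below which a cluster counts as
#'   absent; default 5.
#' @return List with `table` (`data.frame`) and `interrupted` (character
#'   vector of interrupted scenario labels).
#' @export
compare_report <- function(reports, absent_threshold_pct = 5) {
  if (length(reports) < 2L) stop("need at least two reports to compare")
  labels <- vapply(reports, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate scenario labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  ord <- order(match(labels, .study_label_order(), nomatch = 1e6), labels)
  reports <- reports[ord]
  region_names <- sort(unique(unlist(lapply(reports, function(r)
    names(r$clusters)))))
  rows <- lapply(reports, function(r) {
    row <- data.frame(scenario = r$label,
                      verdict = if (is.null(r$verdict)) NA_character_
                                else r$verdict$verdict,
                      connectivity_pct = if (is.null(r$verdict)) NA_real_
                                         else r$verdict$connectivity_fraction,
                      stringsAsFactors = FALSE)
    for (rg in region_names) {
      st <- r$clusters[[rg]]
      safe <- gsub("[^A-Za-z0-9]", "", rg)
      row[[paste0("occupancy_", safe)]] <-
        if (is.null(st)) NA_real_ else st$occupancy_pct
      row[[paste0("capacity_mode_", safe)]] <-
        if (is.null(st)) NA_integer_ else capacity_mode(st)
      row[[paste0("capacity_max_", safe)]] <-
        if (is.null(st)) NA_integer_ else capacity_support_max(st)
      row[[paste0("absent_", safe)]] <-
        if (is.null(st)) NA else st$occupancy_pct < absent_threshold_pct
    }
    row
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table,
       interrupted = table$scenario[!is.na(table$verdict) &
                                    table$verdict == "interrupted"])
}
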