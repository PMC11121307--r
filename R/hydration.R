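## Structural water cluster statistics: per-frame counts inside anchored
## spherical regions, occupancy (percent of frames with at least one
## water), capacity distributions, and cross-scenario comparison.

#' Resolve a region center in one frame
#'
#' The center is the midpoint of the two anchor-group centroids,
#' recomputed per frame so regions track residue motion.
#'
#' @param coords `N x 3` matrix (one frame).
#' @param region A [cluster_region()].
#' @param top The matching [topology()].
#' @return Length-3 numeric point (Angstrom).
#' @export
resolve_region_center <- function(coords, region, top) {
  ia <- resolve_selection(top, region$anchor_a,
                          paste0("region '", region$name, "' anchor_a"))
  ib <- resolve_selection(top, region$anchor_b,
                          paste0("region '", region$name, "' anchor_b"))
  if (length(ia) == 0L)
    stop("unresolvable anchor_a in region '", region$name, "'")
  if (length(ib) == 0L)
    stop("unresolvable anchor_b in region '", region$name, "'")
  (colMeans(coords[ia, , drop = FALSE]) +
   colMeans(coords[ib, , drop = FALSE])) / 2
}

#' Count waters inside a region in one frame
#'
#' Number of `water_oxygen` atoms within the region radius of the frame's
#' resolved region center (boundary inclusive).
#'
#' @inheritParams resolve_region_center
#' @return Integer count.
#' @export
count_waters_in_region <- function(coords, region, top) {
  wat <- which(top$atoms$role == "water_oxygen")
  if (length(wat) == 0L) return(0L)
  ctr <- resolve_region_center(coords, region, top)
  d2 <- rowSums(sweep(coords[wat, , drop = FALSE], 2, ctr)^2)
  sum(d2 <= region$radius^2)
}

#' Water-cluster statistics over a trajectory
#'
#' Computes the per-frame water-count time series for a region and derives
#' the occupancy (percent of frames with >= 1 water; stored at full
#' precision, displayed to 0.1%) and the capacity probability distribution
#' (over all frames, zeros included, so
#' `occupancy_pct == 100 * (1 - capacity_pdf["0"])` exactly).
#'
#' @param traj A [trajectory()].
#' @param region A [cluster_region()].
#' @return Object of class `"cluster_stats"`: list with `name`,
#'   `occupancy_pct`, `capacity_pdf` (named numeric over observed counts
#'   0..max), `count_series`.
#' @export
cluster_stats <- function(traj, region) {
  top <- traj$topology
  series <- vapply(seq_len(traj$n_frames), function(f)
    count_waters_in_region(frame_coords(traj, f), region, top), 0L)
  kmax <- max(series)
  pdf <- tabulate(series + 1L, nbins = kmax + 1L) / length(series)
  names(pdf) <- 0:kmax
  structure(list(name = region$name,
                 occupancy_pct = 100 * mean(series >= 1L),
                 capacity_pdf = pdf,
                 count_series = series),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat("cluster", x$name, ": occupancy", round(x$occupancy_pct, 1),
      "%, capacity support 0..",
      max(as.integer(names(x$capacity_pdf))), "\n", sep = " ")
  invisible(x)
}

#' Most probable nonzero capacity of a cluster
#'
#' Mode of the capacity distribution restricted to counts >= 1; 0 if the
#' region is never occupied.
#'
#' @param stats A [cluster_stats()] result.
#' @return Integer.
#' @export
capacity_mode <- function(stats) {
  pdf <- stats$capacity_pdf
  k <- as.integer(names(pdf))
  nz <- k >= 1L
  if (!any(nz) || all(pdf[nz] == 0)) return(0L)
  k[nz][which.max(pdf[nz])]
}

#' Maximum observed water count of a cluster
#' @param stats A [cluster_stats()] result.
#' @return Integer.
#' @export
capacity_support_max <- function(stats) {
  pdf <- stats$capacity_pdf
  k <- as.integer(names(pdf))
  occupied <- pdf > 0
  if (!any(occupied)) return(0L)
  max(k[occupied])
}

#' Compare cluster statistics across scenarios
#'
#' For every region shared by all scenarios, reports occupancy and its
#' difference from the first (baseline) scenario, the capacity support
#' maximum, and a `cluster_absent` flag for occupancies below the absence
#' threshold.
#'
#' @param stats_by_scenario Named list (scenario label -> named list of
#'   [cluster_stats()] keyed by region name).
#' @param absent_threshold_pct Occupancy (percent) below which a cluster
#'   is flagged absent; default 5.
#' @return `data.frame` sorted by region then scenario with columns
#'   `region`, `scenario`, `occupancy_pct`, `delta_occupancy_pct`,
#'   `capacity_max`, `cluster_absent`.
#' @export
compare_cluster_stats <- function(stats_by_scenario, absent_threshold_pct = 5) {
  if (length(stats_by_scenario) < 2L)
    stop("need at least two scenarios to compare")
  region_sets <- lapply(stats_by_scenario, names)
  if (!all(vapply(region_sets, function(r)
    setequal(r, region_sets[[1]]), TRUE)))
    stop("scenarios have mismatched region sets")
  regions <- sort(region_sets[[1]])
  baseline <- stats_by_scenario[[1]]
  rows <- list()
  for (rg in regions) {
    for (sc in names(stats_by_scenario)) {
      st <- stats_by_scenario[[sc]][[rg]]
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, scenario = sc,
        occupancy_pct = round(st$occupancy_pct, 1),
        delta_occupancy_pct = round(
          st$occupancy_pct - baseline[[rg]]$occupancy_pct, 1),
        capacity_max = capacity_support_max(st),
        cluster_absent = st$occupancy_pct < absent_threshold_pct,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
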