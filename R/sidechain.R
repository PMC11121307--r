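## Side-chain stable spatial positions (SP), gate-contact statistics, and
## C-alpha distance distributions.

#' Classify stable spatial positions of a side chain
#'
#' Per-frame positions of the side chain's terminal-atom centroid are
#' taken after superposing each frame onto the first frame over the local
#' backbone (the residue's own segment, +/- `local_window` residues on the
#' same chain), which isolates side-chain motion from helix drift.  The
#' positions are clustered with k-means; the number of states k <= `k_max`
#' is chosen by average silhouette width (k = 1 when no multi-state split
#' reaches a silhouette of 0.5).  Frames farther than twice the
#' within-state root-mean-square spread from every center are left
#' unassigned.  States are ordered by first appearance (SP1 is the state
#' first visited).
#'
#' @param traj A [trajectory()].
#' @param residue `list(chain =, resseq =)` residue reference.
#' @param terminal_atoms Atom names of the side-chain terminal group.
#' @param k_max Maximum number of states, default 3.
#' @param seed RNG seed for k-means initialization.
#' @param local_window Residues on each side used for the local backbone
#'   fit, default 4.
#' @return Object of class `"sp_assignment"`: list with `residue`,
#'   `states` (per-frame labels `"SP1"`.. or `"unassigned"`),
#'   `occupancy_pct` (named, states plus `unassigned`; sums to 100),
#'   `centers` (k x 3 matrix, Angstrom), `k`.
#' @export
classify_sp <- function(traj, residue, terminal_atoms, k_max = 3L,
                        seed = 1L, local_window = 4L) {
  if (traj$n_frames < 10L) stop("SP classification needs at least 10 frames")
  top <- traj$topology
  term <- atom_select(top, chain = residue$chain, resseq = residue$resseq,
                      name = terminal_atoms)
  if (length(term) == 0L)
    stop("terminal atoms not found for residue ", residue$chain, ":",
         residue$resseq)
  bb <- atom_select(top, chain = residue$chain,
                    resseq = (residue$resseq - local_window):(residue$resseq + local_window),
                    name = backbone_atom_names())
  if (length(bb) < 3L)
    bb <- atom_select(top, name = backbone_atom_names())
  nf <- traj$n_frames
  ref <- frame_coords(traj, 1L)
  feats <- matrix(NA_real_, nf, 3L)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    fitted <- if (length(bb) >= 3L) superpose(m, ref, bb)$fitted else m
    feats[f, ] <- colMeans(fitted[term, , drop = FALSE])
  }
  km <- .select_k_kmeans(feats, k_max, seed)
  lab <- km$cluster
  centers <- km$centers
  ## within-state RMS spread and unassigned cutoff
  spread <- vapply(seq_len(nrow(centers)), function(k) {
    d2 <- rowSums(sweep(feats[lab == k, , drop = FALSE], 2, centers[k, ])^2)
    sqrt(mean(d2))
  }, 0)
  dist_to_own <- sqrt(rowSums((feats - centers[lab, , drop = FALSE])^2))
  cutoff <- pmax(2 * spread[lab], 1e-8)
  unassigned <- dist_to_own > cutoff
  ## order states by first appearance among assigned frames
  appear <- order(vapply(seq_len(nrow(centers)), function(k) {
    w <- which(lab == k & !unassigned)
    if (length(w) == 0L) Inf else min(w)
  }, 0))
  relabel <- match(seq_len(nrow(centers)), appear)
  lab <- relabel[lab]
  centers <- centers[appear, , drop = FALSE]
  states <- ifelse(unassigned, "unassigned", paste0("SP", lab))
  k <- nrow(centers)
  occ <- vapply(c(paste0("SP", seq_len(k)), "unassigned"),
                function(s) 100 * mean(states == s), 0)
  structure(list(residue = residue, states = states,
                 occupancy_pct = occ, centers = centers, k = k),
            class = "sp_assignment")
}

.select_k_kmeans <- function(feats, k_max, seed, min_sil = 0.5) {
  n_unique <- nrow(unique(round(feats, 6)))
  fit1 <- list(cluster = rep(1L, nrow(feats)),
               centers = matrix(colMeans(feats), 1L))
  if (k_max < 2L || n_unique < 3L) return(fit1)
  d <- stats::dist(feats)
  best <- fit1; best_sil <- -Inf
  for (k in 2:min(k_max, n_unique - 1L)) {
    set.seed(seed + k)
    km <- stats::kmeans(feats, centers = k, nstart = 10L, iter.max = 100L)
    sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    if (sil > best_sil) {
      best_sil <- sil
      best <- list(cluster = km$cluster, centers = km$centers)
    }
  }
  if (best_sil < min_sil) fit1 else best
}

#' @export
print.sp_assignment <- function(x, ...) {
  cat("SP assignment for", x$residue$chain, x$residue$resseq, "-",
      x$k, "state(s)\n")
  print(round(x$occupancy_pct, 1))
  invisible(x)
}

#' Contact fraction between two selections
#'
#' Percent of frames in which the minimum cross-pair distance is strictly
#' below the cutoff.
#'
#' @param traj A [trajectory()].
#' @param sel_a,sel_b Selection lists or index vectors.
#' @param cutoff Contact distance, Angstrom; default 3.
#' @param label Optional pair label for reporting.
#' @return Object of class `"contact_stats"`: list with `pair`,
#'   `contact_fraction_pct`, `cutoff`, `series`.
#' @export
contact_fraction <- function(traj, sel_a, sel_b, cutoff = 3.0,
                             label = "contact") {
  dm <- pairwise_min_distance_series(traj, sel_a, sel_b)
  structure(list(pair = label,
                 contact_fraction_pct = 100 * mean(dm$series < cutoff),
                 cutoff = cutoff, series = dm$series),
            class = "contact_stats")
}

#' C-alpha distance probability density
#'
#' Histogram density of the per-frame distance between the CA atoms of two
#' residues; the density integrates to 1 over the bins.
#'
#' @param traj A [trajectory()].
#' @param res_a,res_b `list(chain =, resseq =)` residue references.
#' @param bin_width Bin width in Angstrom, default 0.2.
#' @return `data.frame` with `bin_lo`, `bin_hi`, `bin_center`, `density`.
#' @export
ca_distance_pdf <- function(traj, res_a, res_b, bin_width = 0.2) {
  top <- traj$topology
  ia <- atom_select(top, chain = res_a$chain, resseq = res_a$resseq, name = "CA")
  ib <- atom_select(top, chain = res_b$chain, resseq = res_b$resseq, name = "CA")
  if (length(ia) != 1L || length(ib) != 1L)
    stop("residue lacks a unique CA atom")
  d <- vapply(seq_len(traj$n_frames), function(f) {
    m <- frame_coords(traj, f)
    sqrt(sum((m[ia, ] - m[ib, ])^2))
  }, 0)
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(breaks) < hi) breaks <- c(breaks, max(breaks) + bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = utils::head(h$breaks, -1), bin_hi = h$breaks[-1],
             bin_center = h$mids, density = h$density)
}
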