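## Conformational-stability battery: Kabsch superposition, RMSD series,
## RMSF profiles, radius of gyration, Shrake-Rupley SASA, intramolecular
## hydrogen-bond counts, and stability-table summarization.

#' Backbone atom names
#'
#' The standard protein backbone heavy-atom set used by backbone
#' selections throughout the package.
#' @return `c("N", "CA", "C", "O")`
#' @export
backbone_atom_names <- function() c("N", "CA", "C", "O")

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` over the
#' given atom selection, via singular value decomposition with reflection
#' correction (the returned rotation is always proper, det = +1).
#'
#' @param mobile,reference `N x 3` coordinate matrices.
#' @param selection Atom indices used for the fit (default: all).
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, over the selection), and `fitted` (all mobile coordinates
#'   after the transform).  The transform maps `x` to `x %*% t(R) + t`.
#' @export
superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  if (length(selection) < 3L)
    stop("superposition needs at least 3 selected atoms")
  a <- mobile[selection, , drop = FALSE]
  b <- reference[selection, , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("selection sizes differ between frames")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(a0, b0)                    # 3x3 covariance
  s <- svd(h)
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2L)
    stop("degenerate selection: atoms collinear or coincident")
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  rot <- s$v %*% corr %*% t(s$u)            # maps centered mobile -> centered ref
  fitted_sel <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted_sel - b0)^2)))
  trans <- as.numeric(cb - rot %*% ca)
  fitted <- sweep(mobile %*% t(rot), 2, trans, `+`)
  list(rotation = rot, translation = trans, rmsd = rmsd, fitted = fitted)
}

#' Per-frame RMSD series
#'
#' Each frame is superposed (Kabsch, over `selection`) onto the reference
#' frame and the RMSD over the selection recorded.  The reference is the
#' first frame by default, so the series starts at 0.
#'
#' @param traj A [trajectory()].
#' @param selection Atom indices (e.g. backbone); default all atoms.
#' @param ref_frame Reference frame index, default 1.
#' @return List with `series` (Angstrom per frame) and `mean`.
#' @export
rmsd_series <- function(traj, selection = seq_len(traj$topology$n_atoms),
                        ref_frame = 1L) {
  if (length(selection) == 0L) stop("empty selection")
  ref <- frame_coords(traj, ref_frame)
  series <- vapply(seq_len(traj$n_frames), function(f)
    superpose(frame_coords(traj, f), ref, selection)$rmsd, 0)
  list(series = series, mean = mean(series))
}

#' Per-residue RMSF profile
#'
#' Two-pass procedure: frames are first superposed onto the reference
#' frame, the time-mean structure is computed, every frame is re-superposed
#' onto that mean, and the per-atom root-mean-square fluctuation about the
#' mean position is averaged (RMS) over each residue's selected atoms.
#'
#' @param traj A [trajectory()].
#' @param selection Atom indices (typically backbone atoms).
#' @return `data.frame` with `chain_id`, `res_seq`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = atom_select(traj$topology,
                                                       name = backbone_atom_names())) {
  if (traj$n_frames < 2L) stop("RMSF needs at least 2 frames")
  if (length(selection) == 0L) stop("empty selection")
  nf <- traj$n_frames
  sel_coords <- array(NA_real_, c(nf, length(selection), 3L))
  ref <- frame_coords(traj, 1L)
  for (f in seq_len(nf)) {
    fit <- superpose(frame_coords(traj, f), ref, selection)
    sel_coords[f, , ] <- fit$fitted[selection, , drop = FALSE]
  }
  ## iterate the fit-to-mean pass until the mean structure is stable, so
  ## the profile does not depend on which frame seeded the first pass
  mean_struct <- apply(sel_coords, c(2, 3), mean)
  for (it in seq_len(50L)) {
    for (f in seq_len(nf)) {
      m <- sel_coords[f, , ]; dim(m) <- c(length(selection), 3L)
      sel_coords[f, , ] <- superpose(m, mean_struct)$fitted
    }
    new_mean <- apply(sel_coords, c(2, 3), mean)
    delta <- max(abs(new_mean - mean_struct))
    mean_struct <- new_mean
    if (delta < 1e-12) break
  }
  dev2 <- vapply(seq_along(selection), function(i) {
    d <- sweep(sel_coords[, i, , drop = FALSE], c(2, 3), mean_struct[i, ])
    mean(rowSums(matrix(d, nrow = nf)^2))
  }, 0)
  atoms <- traj$topology$atoms[selection, ]
  key <- paste(atoms$chain_id, atoms$res_seq, sep = ":")
  agg <- tapply(dev2, factor(key, levels = unique(key)), mean)
  out <- unique(atoms[, c("chain_id", "res_seq")])
  out$rmsf <- sqrt(as.numeric(agg))
  rownames(out) <- NULL
  out
}

#' Standard atomic masses (Da) by element
#' @return Named numeric vector.
#' @export
element_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected atoms from
#' their center of mass.
#'
#' @param coords `N x 3` coordinate matrix (one frame).
#' @param selection Atom indices; default all.
#' @param masses Per-atom masses for the selection (recycled defaults to 1,
#'   i.e. geometric RG).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords, selection = seq_len(nrow(coords)),
                               masses = rep(1, length(selection))) {
  m <- coords[selection, , drop = FALSE]
  w <- rep_len(masses, nrow(m))
  if (sum(w) <= 0) stop("total mass must be positive")
  com <- colSums(m * w) / sum(w)
  d2 <- rowSums(sweep(m, 2, com)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Van der Waals radii (Angstrom) bundled for SASA
#' @return Named numeric vector by element symbol.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

## Orient coordinates along their principal axes (deterministic signs) so
## quadrature meshes are anchored to the molecule, making SASA invariant
## under global rotation/translation of the input.
.canonical_orientation <- function(coords) {
  ctr <- colMeans(coords)
  x0 <- sweep(coords, 2, ctr)
  if (nrow(coords) < 2L) return(x0)
  ev <- eigen(crossprod(x0) / nrow(x0), symmetric = TRUE)
  v <- ev$vectors
  for (k in 1:3) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  x0 %*% v
}

## Deterministic quasi-uniform sphere points (golden-section spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is inflated by the probe radius and covered with a
#' deterministic quasi-uniform point mesh; the accessible area is the
#' exposed-point fraction times the inflated-sphere area.  The mesh is
#' anchored to the system's principal axes, so the result is invariant
#' under global rotation and translation of the coordinates.
#'
#' @param coords `N x 3` coordinate matrix (one frame).
#' @param radii Per-atom van der Waals radii (Angstrom).
#' @param probe_radius Solvent probe radius, default 1.4 Angstrom (water).
#' @param n_points Mesh points per atom, default 960 (minimum 96).
#' @return List with `per_atom` (Angstrom^2 per atom) and `total`.
#' @export
sasa <- function(coords, radii, probe_radius = 1.4, n_points = 960L) {
  n <- nrow(coords)
  if (length(radii) != n) stop("need one radius per atom")
  if (any(radii <= 0)) stop("radii must be positive")
  if (probe_radius <= 0) stop("probe radius must be positive")
  if (n_points < 96L) stop("n_points must be at least 96")
  coords <- .canonical_orientation(coords)
  pts <- .sphere_points(n_points)
  rr <- radii + probe_radius
  per_atom <- numeric(n)
  ## neighbor lists via one pairwise distance pass
  d <- as.matrix(stats::dist(coords))
  for (i in seq_len(n)) {
    sph <- sweep(pts * rr[i], 2, coords[i, ], `+`)
    nb <- which(d[i, ] < rr[i] + rr & seq_len(n) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(sph, 2, coords[j, ])^2)
      ## mesh points exactly on a neighbor's inflated sphere (coincident
      ## atoms) are credited to the lower-index atom only, so a fully
      ## coincident pair contributes one sphere's area, not two or zero
      buried <- if (j < i) dj2 <= rr[j]^2 + 1e-9 else dj2 < rr[j]^2 - 1e-9
      exposed <- exposed & !buried
    }
    per_atom[i] <- mean(exposed) * 4 * pi * rr[i]^2
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' SASA radii for a topology
#'
#' @param top A [topology()].
#' @param table Named radius table, by element symbol.
#' @param default Radius used for elements missing from the table.
#' @return Numeric vector, one radius per atom.
#' @export
topology_radii <- function(top, table = vdw_radii(), default = 1.70) {
  r <- unname(table[top$atoms$element])
  r[is.na(r)] <- default
  r
}

#' Count intramolecular hydrogen bonds in one frame
#'
#' Donor/acceptor heavy-atom pairs at distance not exceeding the cutoff,
#' excluding pairs within the same residue and excluding water.  `both`
#' atoms count on either side; donor-donor and acceptor-acceptor pairs do
#' not bond.
#'
#' @param coords `N x 3` matrix (one frame).
#' @param top The matching [topology()].
#' @param criteria An [hbond_criteria()].
#' @return Integer bond count.
#' @export
count_intramolecular_hbonds <- function(coords, top,
                                        criteria = hbond_criteria()) {
  a <- top$atoms
  idx <- which(a$role %in% c("donor", "acceptor", "both"))
  if (length(idx) < 2L) return(0L)
  role <- a$role[idx]
  res <- paste(a$chain_id[idx], a$res_seq[idx], sep = ":")
  m <- coords[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(m))
  n <- length(idx)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (res[i] == res[j]) next
      if (d[i, j] > criteria$max_heavy_distance) next
      ok <- (role[i] %in% c("donor", "both") && role[j] %in% c("acceptor", "both")) ||
            (role[j] %in% c("donor", "both") && role[i] %in% c("acceptor", "both"))
      if (ok) count <- count + 1L
    }
  }
  count
}

#' Build a stability-table row
#'
#' @param label Scenario label.
#' @param rmsd_A,rg_A,sasa_1e4_A2,n_hbond,rmsd_alphafold_A Metric values
#'   (`rmsd_alphafold_A` is imported metadata and may be `NA`).
#' @return One-row `data.frame`.
#' @export
stability_row <- function(label, rmsd_A, rg_A, sasa_1e4_A2, n_hbond,
                          rmsd_alphafold_A = NA_real_) {
  vals <- c(rmsd_A, rg_A, sasa_1e4_A2, n_hbond, rmsd_alphafold_A)
  if (any(vals < 0, na.rm = TRUE)) stop("stability metrics must be nonnegative")
  data.frame(label = label, rmsd_A = rmsd_A, rg_A = rg_A,
             sasa_1e4_A2 = sasa_1e4_A2, n_hbond = n_hbond,
             rmsd_alphafold_A = rmsd_alphafold_A, stringsAsFactors = FALSE)
}

#' Load the packaged a-subunit stability table
#'
#' Published per-system averages (MD RMSD, radius of gyration, SASA,
#' hydrogen-bond count, and the RMSD of structure-prediction models
#' against the reference structure) for the wild type and nine inlet
#' half-channel mutants.
#'
#' @return `data.frame` in [stability_row()] schema, WT first.
#' @export
load_stability_table <- function() {
  path <- system.file("extdata", "stability_table.csv",
                      package = "halfchannel", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## half-up rounding (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize a stability table
#'
#' Mean, min and max per metric, overall and for the mutants-only subgroup
#' (every row whose label is not `"WT"`).
#'
#' @param rows `data.frame` in [stability_row()] schema.
#' @param digits If non-NULL, summaries are rounded half-up to this many
#'   decimals (printed-table precision).
#' @return `data.frame` with columns `metric`, `subgroup`
#'   (`"all"`/`"mutants"`), `mean`, `min`, `max`, `n`.
#' @export
summarize_stability_table <- function(rows, digits = NULL) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("stability table must have at least one row")
  metrics <- setdiff(names(rows), "label")
  groups <- list(all = rows, mutants = rows[rows$label != "WT", , drop = FALSE])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(metrics, function(m) {
      v <- df[[m]][!is.na(df[[m]])]
      if (length(v) == 0L) return(NULL)
      s <- data.frame(metric = m, subgroup = g, mean = mean(v),
                      min = min(v), max = max(v), n = length(v),
                      stringsAsFactors = FALSE)
      if (!is.null(digits))
        s[c("mean", "min", "max")] <- lapply(s[c("mean", "min", "max")],
                                             round_half_up, digits = digits)
      s
    }))
  }))
  rownames(out) <- NULL
  out
}
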