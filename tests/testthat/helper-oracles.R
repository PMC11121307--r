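## Independent oracles and small constructors shared across tests.

## Horn's quaternion method for optimal-superposition RMSD; independent of
## the package's SVD-based Kabsch path.
quaternion_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  m <- crossprod(a0, b0)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(a0^2) + sum(b0^2)
  sqrt(max(0, (g - 2 * lambda) / nrow(a)))
}

## Exhaustive recursive path enumeration on an adjacency matrix.
enum_path_exists <- function(adj, from, to, visited = rep(FALSE, nrow(adj))) {
  if (from %in% to) return(TRUE)
  visited[from] <- TRUE
  for (v in which(adj[from, ] & !visited)) {
    if (enum_path_exists(adj, v, to, visited)) return(TRUE)
  }
  FALSE
}

## Analytic total SASA of two equal spheres of inflated radius rr at
## center separation d (each loses a spherical cap of height rr - d/2).
two_sphere_sasa <- function(rr, d) {
  if (d >= 2 * rr) return(2 * 4 * pi * rr^2)
  cap <- 2 * pi * rr * (rr - d / 2)
  2 * (4 * pi * rr^2 - cap)
}

## Topology of n isolated water oxygens (chain W).
water_only_topology <- function(n) {
  topology(data.frame(
    serial = seq_len(n), name = "O", element = "O", res_name = "HOH",
    res_seq = seq_len(n), chain_id = "W", stringsAsFactors = FALSE))
}

## Minimal protein-like topology: one named polar atom per residue.
polar_atom_topology <- function(resnames, atoms, chain = "A") {
  n <- length(resnames)
  topology(data.frame(
    serial = seq_len(n), name = atoms, element = substr(atoms, 1, 1),
    res_name = resnames, res_seq = seq_len(n), chain_id = chain,
    stringsAsFactors = FALSE))
}

## A 20-residue synthetic peptide (glycine backbone only) with
## deterministic coordinates; used for write/read round trips.
synthetic_peptide <- function(n_res = 20L) {
  rows <- list()
  serial <- 0L
  coords <- list()
  for (r in seq_len(n_res)) {
    for (at in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = at, element = substr(at, 1, 1),
        res_name = "GLY", res_seq = r, chain_id = "A",
        stringsAsFactors = FALSE)
      coords[[serial]] <- c(3.8 * r + 0.3 * serial %% 2, 1.5 * (at == "CA"),
                            0.25 * serial %% 3)
    }
  }
  list(top = topology(do.call(rbind, rows)),
       coords = do.call(rbind, coords))
}

## Fraction of ground-truth mode labels recovered by an SP assignment,
## maximized over label permutations; unassigned frames count as misses.
best_label_agreement <- function(truth, states) {
  assigned <- states != "unassigned"
  got <- as.integer(sub("SP", "", states[assigned]))
  tru <- truth[assigned]
  perms <- combinat_perms(sort(unique(tru)))
  best <- 0
  for (p in perms) best <- max(best, mean(p[tru] == got))
  best * mean(assigned)
}

## tiny permutation enumerator (avoids extra dependencies)
combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

## Trajectory with pure Gaussian jitter around a fixed base structure.
jitter_trajectory <- function(base, n_frames, sigma, seed = 42L,
                              jitter_atoms = seq_len(nrow(base$coords))) {
  set.seed(seed)
  nf <- n_frames
  n <- nrow(base$coords)
  arr <- array(rep(base$coords, each = nf), c(nf, n, 3L))
  for (i in jitter_atoms)
    arr[, i, ] <- arr[, i, ] + matrix(rnorm(nf * 3, 0, sigma), nf, 3L)
  trajectory(base$top, arr)
}
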