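## Synthetic toy half-channel systems with known ground truth.
##
## The toy geometry places the canonical chain sites on a line:
## aE219 (x=0) - aD119 (2.7) - aH245 (5.4) - [W2/W3 at 7.9] - aN214 (10.4)
## - [W1 at 12.9] - cD61 (15.4), with aR140 and aQ252 off-axis.  Gate
## spacings of 2.7 A are direct hydrogen-bond contacts; the 5.0 A gaps
## flanking each water region are bridged if and only if a water is
## present there: waters are placed uniformly within 0.5 A of the region
## center, so every present water is within 3.0 A of both flanking sites,
## while sites across an empty region are 5.0 A apart.  An always-present
## "gate water" between aD119 and aH245 models the hydrated aqueous-cavity
## exit (it bridges that segment when the aH245 side chain cannot accept).
## Waters scheduled absent in a frame are parked in a distant reservoir so
## the atom count stays constant across frames.

.toy_sidechain_atom <- c(GLU = "OE1", ASP = "OD1", HIS = "NE2", ASN = "ND2",
                         GLN = "NE2", ARG = "NH1", SER = "OG", TYR = "OH",
                         LYS = "NZ", THR = "OG1")

.toy_base_residues <- function() {
  data.frame(
    chain = c("A", "A", "A", "A", "A", "A", "C"),
    resseq = c(219L, 119L, 140L, 245L, 214L, 252L, 61L),
    resname = c("GLU", "ASP", "ARG", "HIS", "ASN", "GLN", "ASP"),
    x = c(0, 2.7, 2.7, 5.4, 10.4, 11.9, 15.4),
    y = c(0, 0, 2.5, 0, 0, 2.0, 0),
    z = c(0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Site layout of the toy half-channel
#'
#' Builds the pseudo-residue table: four backbone atoms per residue (fixed
#' offsets below the side-chain site) plus one polar terminal atom for
#' polar residue types.  Substitutions swap the residue type; nonpolar
#' replacements (Gly, Leu, ...) carry no side-chain polar atom.
#'
#' @param substitutions `data.frame` with `chain_id`, `res_seq`,
#'   `from_res`, `to_res`, or `NULL` for wild type.
#' @return `data.frame` with `chain`, `resseq`, `resname`, `atom`, `kind`
#'   (`"backbone"`/`"sidechain"`), `x`, `y`, `z`.
#' @export
toy_site_layout <- function(substitutions = NULL) {
  res <- .toy_base_residues()
  if (!is.null(substitutions) && nrow(substitutions) > 0L) {
    for (i in seq_len(nrow(substitutions))) {
      hit <- which(res$chain == substitutions$chain_id[i] &
                   res$resseq == substitutions$res_seq[i])
      if (length(hit) != 1L)
        stop("substitution targets unknown toy residue ",
             substitutions$chain_id[i], ":", substitutions$res_seq[i])
      if (res$resname[hit] != substitutions$from_res[i])
        stop("substitution from_res mismatch at ",
             substitutions$chain_id[i], ":", substitutions$res_seq[i])
      res$resname[hit] <- substitutions$to_res[i]
    }
  }
  rows <- list()
  for (i in seq_len(nrow(res))) {
    bx <- res$x[i]; by <- res$y[i]; bz <- res$z[i]
    bb <- data.frame(
      chain = res$chain[i], resseq = res$resseq[i], resname = res$resname[i],
      atom = c("N", "CA", "C", "O"), kind = "backbone",
      x = bx + c(-0.7, 0, 0.7, 0.7), y = by + c(0.8, 0, 0.8, 1.9),
      z = bz - 1.5, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- bb
    sc_atom <- .toy_sidechain_atom[res$resname[i]]
    if (!is.na(sc_atom))
      rows[[length(rows) + 1L]] <- data.frame(
        chain = res$chain[i], resseq = res$resseq[i],
        resname = res$resname[i], atom = unname(sc_atom), kind = "sidechain",
        x = bx, y = by, z = bz, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Water-cluster model for the toy generator
#'
#' @param name Region name.
#' @param presence_prob Probability a frame has at least one water.
#' @param capacity_dist Named numeric distribution over integer counts
#'   (must sum to 1); conditional on presence the count is drawn from its
#'   restriction to counts >= 1.
#' @param center Length-3 placement center (Angstrom).
#' @param placement_radius Waters are placed uniformly within this radius
#'   of the center; default 0.5.
#' @return List describing the model.
#' @export
toy_cluster_model <- function(name, presence_prob, capacity_dist, center,
                              placement_radius = 0.5) {
  if (presence_prob < 0 || presence_prob > 1)
    stop("presence_prob must be in [0, 1]")
  if (abs(sum(capacity_dist) - 1) > 1e-9)
    stop("capacity distribution must sum to 1")
  if (is.null(names(capacity_dist)))
    names(capacity_dist) <- seq_along(capacity_dist) - 1L
  list(name = name, presence_prob = presence_prob,
       capacity_dist = capacity_dist, center = center,
       placement_radius = placement_radius)
}

#' Side-chain spatial-mode model for the toy generator
#'
#' @param chain,resseq Residue reference.
#' @param mode_centers `k x 3` matrix of stable positions (pairwise
#'   separation at least 2 Angstrom when k > 1).
#' @param switch_prob Per-frame probability of jumping to another mode.
#' @param sigma Isotropic Gaussian noise around the current mode center.
#' @return List describing the model.
#' @export
toy_sp_model <- function(chain, resseq, mode_centers, switch_prob = 0.02,
                         sigma = 0.08) {
  mode_centers <- matrix(mode_centers, ncol = 3)
  if (nrow(mode_centers) > 1L) {
    d <- as.matrix(stats::dist(mode_centers))
    if (min(d[upper.tri(d)]) < 2)
      stop("mode centers must be pairwise >= 2 Angstrom apart")
  }
  if (switch_prob < 0 || switch_prob > 1) stop("switch_prob must be in [0, 1]")
  list(chain = chain, resseq = resseq, mode_centers = mode_centers,
       switch_prob = switch_prob, sigma = sigma)
}

#' Toy-system specification
#'
#' @param label Scenario label.
#' @param substitutions Substitution table (see [toy_site_layout()]).
#' @param cluster_models List of [toy_cluster_model()].
#' @param sp_models List of [toy_sp_model()]; residues without a model
#'   keep their layout position with `default_sidechain_sigma` noise.
#' @param n_frames Number of frames, default 150.
#' @param frame_interval_ps Frame spacing, default 2 ps.
#' @param backbone_jitter Per-residue Gaussian sigma on backbone atoms,
#'   Angstrom; default 0.05.
#' @param default_sidechain_sigma Noise for unmodeled side chains.
#' @param seed Integer seed; one RNG stream per trajectory.
#' @return Object of class `"toy_system_spec"`.
#' @export
toy_system_spec <- function(label, substitutions = NULL,
                            cluster_models = list(), sp_models = list(),
                            n_frames = 150L, frame_interval_ps = 2,
                            backbone_jitter = 0.05,
                            default_sidechain_sigma = 0.08, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  layout <- toy_site_layout(substitutions)
  ## warn on overlapping placement regions
  if (length(cluster_models) > 1L) {
    ctrs <- t(vapply(cluster_models, `[[`, numeric(3), "center"))
    rads <- vapply(cluster_models, `[[`, 0, "placement_radius")
    for (i in seq_len(length(cluster_models) - 1L))
      for (j in (i + 1L):length(cluster_models))
        if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) < rads[i] + rads[j])
          warning("placement regions '", cluster_models[[i]]$name, "' and '",
                  cluster_models[[j]]$name, "' overlap")
  }
  structure(list(label = label,
                 substitutions = if (is.null(substitutions))
                   data.frame() else substitutions,
                 site_layout = layout,
                 cluster_models = cluster_models, sp_models = sp_models,
                 n_frames = as.integer(n_frames),
                 frame_interval_ps = frame_interval_ps,
                 backbone_jitter = backbone_jitter,
                 default_sidechain_sigma = default_sidechain_sigma,
                 seed = as.integer(seed)),
            class = "toy_system_spec")
}

#' Generate a per-frame water-count schedule
#'
#' Frames carry 0 waters with probability `1 - p`; conditional on
#' presence, the count is drawn from the capacity distribution restricted
#' to counts >= 1.
#'
#' @param p Presence probability.
#' @param capacity_dist Named numeric distribution over integer counts
#'   summing to 1.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return Integer vector of length `n_frames`.
#' @export
generate_water_schedule <- function(p, capacity_dist, n_frames, seed) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (abs(sum(capacity_dist) - 1) > 1e-9)
    stop("capacity distribution must sum to 1")
  if (is.null(names(capacity_dist)))
    names(capacity_dist) <- seq_along(capacity_dist) - 1L
  counts <- as.integer(names(capacity_dist))
  pos <- counts >= 1L & capacity_dist > 0
  set.seed(seed)
  present <- stats::runif(n_frames) < p
  out <- integer(n_frames)
  if (any(present)) {
    if (!any(pos))
      stop("capacity distribution has no mass on counts >= 1")
    w <- capacity_dist[pos] / sum(capacity_dist[pos])
    pick <- sample.int(length(w), sum(present), replace = TRUE, prob = w)
    out[present] <- counts[pos][pick]
  }
  out
}

## Independent exhaustive depth-first path search used for ground-truth
## connectivity (deliberately not igraph; see hbond_chain for the
## analyzer's implementation).
.dfs_connected <- function(adj, sources, sinks) {
  n <- nrow(adj)
  visited <- logical(n)
  stack <- sources
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (visited[v]) next
    visited[v] <- TRUE
    if (v %in% sinks) return(TRUE)
    stack <- c(stack, which(adj[v, ] & !visited))
  }
  FALSE
}

#' Generate a toy trajectory with ground truth
#'
#' Builds the topology from the spec's site layout plus fixed water pools
#' (one per cluster model, sized to the capacity support maximum), then
#' simulates frames: backbone atoms get per-residue Gaussian jitter,
#' side-chain terminal atoms follow their spatial-mode model, and waters
#' are placed uniformly inside their placement sphere on frames where the
#' schedule says present (parked in a distant reservoir otherwise).
#' Ground-truth source-to-sink connectivity is computed per frame by an
#' exhaustive depth-first search over the generated geometry, independent
#' of the analyzer's graph machinery.
#'
#' @param spec A [toy_system_spec()].
#' @param hbond_cutoff Distance criterion used for the ground-truth
#'   connectivity flag, Angstrom; default 3.
#' @return List with `trajectory` (a [trajectory()]), `truth` (list:
#'   `region_counts` frame x region matrix, `sp_modes` named list of
#'   per-frame mode labels, `connected` logical per frame), and `spec`.
#' @export
generate_toy_trajectory <- function(spec, hbond_cutoff = 3.0) {
  stopifnot(inherits(spec, "toy_system_spec"))
  lay <- spec$site_layout
  nf <- spec$n_frames
  ## water schedules, one derived seed per region (single base seed)
  nreg <- length(spec$cluster_models)
  schedules <- matrix(0L, nf, max(nreg, 1L))
  pool_sizes <- integer(nreg)
  if (nreg > 0L) {
    colnames(schedules) <- vapply(spec$cluster_models, `[[`, "", "name")
    for (r in seq_len(nreg)) {
      cm <- spec$cluster_models[[r]]
      schedules[, r] <- generate_water_schedule(
        cm$presence_prob, cm$capacity_dist, nf, spec$seed + 7919L * r)
      support <- as.integer(names(cm$capacity_dist))[cm$capacity_dist > 0]
      pool_sizes[r] <- max(support, 0L)
    }
  }
  ## sp mode label chains
  sp_modes <- list()
  if (length(spec$sp_models) > 0L) {
    for (j in seq_along(spec$sp_models)) {
      sp <- spec$sp_models[[j]]
      k <- nrow(sp$mode_centers)
      set.seed(spec$seed + 104729L * j)
      lab <- integer(nf)
      lab[1] <- 1L
      if (nf > 1L) for (f in 2:nf) {
        lab[f] <- lab[f - 1L]
        if (k > 1L && stats::runif(1) < sp$switch_prob)
          lab[f] <- sample(setdiff(seq_len(k), lab[f - 1L]), 1L)
      }
      sp_modes[[paste0(sp$chain, ":", sp$resseq)]] <- lab
    }
  }
  ## topology: layout atoms then water pools
  atoms <- data.frame(
    serial = seq_len(nrow(lay)),
    name = lay$atom,
    element = substr(gsub("^[0-9]+", "", lay$atom), 1, 1),
    res_name = lay$resname, res_seq = lay$resseq, chain_id = lay$chain,
    stringsAsFactors = FALSE)
  wat_rows <- list()
  wat_index <- vector("list", nreg)    # topology indices of each pool
  serial <- nrow(lay)
  wi <- 0L
  for (r in seq_len(nreg)) {
    idx <- integer(pool_sizes[r])
    for (q in seq_len(pool_sizes[r])) {
      wi <- wi + 1L; serial <- serial + 1L
      wat_rows[[wi]] <- data.frame(
        serial = serial, name = "O", element = "O", res_name = "TIP3",
        res_seq = wi, chain_id = "W", stringsAsFactors = FALSE)
      idx[q] <- serial
    }
    wat_index[[r]] <- idx
  }
  if (wi > 0L) atoms <- rbind(atoms, do.call(rbind, wat_rows))
  top <- topology(atoms)
  n <- top$n_atoms
  ## reservoir positions for parked waters
  park <- cbind(200 + 10 * seq_len(max(wi, 1L)), 0, 0)
  sp_key <- paste(lay$chain, lay$resseq, sep = ":")
  sp_lookup <- setNames(seq_along(spec$sp_models),
                        vapply(spec$sp_models, function(s)
                          paste0(s$chain, ":", s$resseq), ""))
  set.seed(spec$seed + 999983L)
  coords <- array(NA_real_, c(nf, n, 3L))
  for (f in seq_len(nf)) {
    m <- matrix(NA_real_, n, 3L)
    for (i in seq_len(nrow(lay))) {
      base <- c(lay$x[i], lay$y[i], lay$z[i])
      if (lay$kind[i] == "backbone") {
        m[i, ] <- base + stats::rnorm(3, 0, spec$backbone_jitter)
      } else {
        smi <- sp_lookup[sp_key[i]]
        if (!is.na(smi)) {
          sp <- spec$sp_models[[smi]]
          ctr <- sp$mode_centers[sp_modes[[sp_key[i]]][f], ]
          m[i, ] <- ctr + stats::rnorm(3, 0, sp$sigma)
        } else {
          m[i, ] <- base + stats::rnorm(3, 0, spec$default_sidechain_sigma)
        }
      }
    }
    for (r in seq_len(nreg)) {
      cm <- spec$cluster_models[[r]]
      cnt <- schedules[f, r]
      pool <- wat_index[[r]]
      for (q in seq_along(pool)) {
        if (q <= cnt) {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          rad <- cm$placement_radius * stats::runif(1)^(1 / 3)
          m[pool[q], ] <- cm$center + rad * dir
        } else {
          m[pool[q], ] <- park[pool[q] - nrow(lay), ]
        }
      }
    }
    coords[f, , ] <- m
  }
  traj <- trajectory(top, coords, frame_interval_ps = spec$frame_interval_ps)
  ## ground-truth connectivity by exhaustive DFS on the generated geometry
  src <- atom_select(top, chain = "A", resseq = c(219L, 119L), role = "polar")
  snk <- atom_select(top, chain = "C", resseq = 61L, role = "polar")
  nodes <- which(top$atoms$role != "none")
  roles <- top$atoms$role[nodes]
  connected <- logical(nf)
  if (length(src) > 0L && length(snk) > 0L) {
    s_pos <- match(src, nodes); k_pos <- match(snk, nodes)
    for (f in seq_len(nf)) {
      mm <- coords[f, nodes, , drop = FALSE]
      dim(mm) <- c(length(nodes), 3L)
      d <- as.matrix(stats::dist(mm))
      adj <- d <= hbond_cutoff & outer(seq_along(nodes), seq_along(nodes), `!=`)
      compat <- outer(roles, roles, .hb_compatible)
      adj <- adj & compat
      connected[f] <- .dfs_connected(adj, s_pos, k_pos)
    }
  }
  truth <- list(region_counts = schedules[, seq_len(nreg), drop = FALSE],
                sp_modes = sp_modes, connected = connected)
  list(trajectory = traj, truth = truth, spec = spec)
}

#' Scenario specification matching the toy geometry
#'
#' Source is the gate polar atoms (aE219/aD119), sink the cD61
#' carboxylate; regions are W1 (anchored aN214/cD61) and the joint W2/W3
#' (anchored aH245/aN214), radius 3.5 Angstrom.
#'
#' @param label Scenario label.
#' @param substitutions Substitution table, or `NULL`.
#' @return A [scenario_spec()].
#' @export
toy_scenario <- function(label, substitutions = NULL) {
  ca <- function(ch, rs) list(chain = ch, resseq = rs, name = "CA")
  scenario_spec(
    label = label, substitutions = substitutions,
    source_selection = list(chain = "A", resseq = c(219L, 119L), role = "polar"),
    sink_selection = list(chain = "C", resseq = 61L, role = "polar"),
    regions = list(cluster_region("W1", ca("A", 214), ca("C", 61), 3.5),
                   cluster_region("W2/W3", ca("A", 245), ca("A", 214), 3.5)),
    gate_residues = list(list(chain = "A", resseq = 140L),
                         list(chain = "A", resseq = 119L)),
    md_metadata = list(temperature_K = 310, ensemble = "NPT",
                       production_ns = 150, engine = "NAMD 2.14",
                       force_field = "CHARMM36"),
    membrane = reference_membrane())
}

## Cluster-model centers of the toy geometry.
.toy_region_centers <- function() {
  list(GATE = c(4.05, 0, 0), `W2/W3` = c(7.9, 0, 0), W1 = c(12.9, 0, 0))
}

#' Per-mutant toy-system fixtures
#'
#' Ten named specs (wild type plus nine inlet half-channel mutants) whose
#' cluster models qualitatively encode the reported per-mutant hydration
#' outcomes: high W1 presence in the wild type; loss of W2/W3 in aH245G;
#' loss of W1 in aH245Y; strongly reduced W1 presence in aN214L; elevated
#' W2/W3 capacity (up to four waters) in aQ252L; the wild-type W2/W3
#' capacity support tops out at two.  Presence probabilities for W1 follow
#' the reported occupancies where stated (0.92 wild type, 0.44 aH245G,
#' 0.36 aN214L).
#'
#' @param n_frames Frames per fixture, default 150.
#' @param seed Base seed; each fixture derives its own stream.
#' @return Named list of [toy_system_spec()], in the study's listing order.
#' @export
make_paper_scenario_fixtures <- function(n_frames = 150L, seed = 1L) {
  ctr <- .toy_region_centers()
  gate <- function() toy_cluster_model("GATE", 1.0, c(`1` = 1), ctr$GATE,
                                       placement_radius = 0.3)
  w23 <- function(p, dist) toy_cluster_model("W2/W3", p, dist, ctr$`W2/W3`)
  w1 <- function(p, dist) toy_cluster_model("W1", p, dist, ctr$W1)
  cap12 <- c(`1` = 0.60, `2` = 0.40)                       # WT-like, max 2
  cap123 <- c(`1` = 0.45, `2` = 0.45, `3` = 0.10)          # slightly elevated
  cap23 <- c(`2` = 0.50, `3` = 0.50)                       # two-to-three chain
  cap1234 <- c(`1` = 0.25, `2` = 0.35, `3` = 0.25, `4` = 0.15)  # up to four
  w1cap <- c(`1` = 0.55, `2` = 0.35, `3` = 0.10)
  w1low <- c(`1` = 0.80, `2` = 0.20)                       # reduced capacity
  sub <- function(ch, rs, from, to)
    data.frame(chain_id = ch, res_seq = rs, from_res = from, to_res = to,
               stringsAsFactors = FALSE)
  defs <- list(
    WT = list(sub = NULL,
              w1 = w1(0.92, w1cap), w23 = w23(0.85, cap12)),
    aE219G = list(sub = sub("A", 219L, "GLU", "GLY"),
                  w1 = w1(0.80, w1cap), w23 = w23(0.85, cap123)),
    aE219Q = list(sub = sub("A", 219L, "GLU", "GLN"),
                  w1 = w1(0.82, w1cap), w23 = w23(0.85, cap123)),
    aH245G = list(sub = sub("A", 245L, "HIS", "GLY"),
                  w1 = w1(0.44, w1cap), w23 = w23(0.0, cap12)),
    aH245S = list(sub = sub("A", 245L, "HIS", "SER"),
                  w1 = w1(0.92, w1cap), w23 = w23(0.90, cap23)),
    aH245Y = list(sub = sub("A", 245L, "HIS", "TYR"),
                  w1 = w1(0.0, w1cap), w23 = w23(0.85, cap12)),
    `aE219H/aH245E` = list(sub = rbind(sub("A", 219L, "GLU", "HIS"),
                                       sub("A", 245L, "HIS", "GLU")),
                           w1 = w1(0.95, w1cap), w23 = w23(0.90, cap123)),
    aN214L = list(sub = sub("A", 214L, "ASN", "LEU"),
                  w1 = w1(0.36, c(`1` = 1)), w23 = w23(0.85, cap12)),
    aN214H = list(sub = sub("A", 214L, "ASN", "HIS"),
                  w1 = w1(0.90, w1low), w23 = w23(0.85, cap12)),
    aQ252L = list(sub = sub("A", 252L, "GLN", "LEU"),
                  w1 = w1(0.92, w1cap), w23 = w23(0.95, cap1234)))
  out <- list()
  for (i in seq_along(defs)) {
    d <- defs[[i]]
    lay <- toy_site_layout(d$sub)
    sp <- list()
    ## single-mode SP model for the aN214 side chain when present
    n214 <- lay[lay$chain == "A" & lay$resseq == 214L & lay$kind == "sidechain", ]
    if (nrow(n214) == 1L)
      sp <- list(toy_sp_model("A", 214L,
                              matrix(c(n214$x, n214$y, n214$z), 1L),
                              switch_prob = 0, sigma = 0.08))
    out[[names(defs)[i]]] <- toy_system_spec(
      label = names(defs)[i], substitutions = d$sub,
      cluster_models = list(gate(), d$w23, d$w1), sp_models = sp,
      n_frames = n_frames, seed = seed + 17L * i)
  }
  out
}
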