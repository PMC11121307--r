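## Per-frame hydrogen-bond graph over polar chain-residue atoms and water
## oxygens, and source-to-sink proton-transfer-chain continuity.

#' Hydrogen-bond criteria
#'
#' The chain criterion is a donor/acceptor heavy-atom distance of at most
#' 3 Angstrom (the approximate length of a hydrogen bond).  An optional
#' donor-H-acceptor angle filter exists but is off by default, since the
#' criterion is defined on heavy atoms only.
#'
#' @param max_heavy_distance Heavy-atom distance cutoff, Angstrom.
#' @param angle_min Optional minimum D-H...A angle in degrees, or `NULL`.
#' @return Object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_heavy_distance = 3.0, angle_min = NULL) {
  if (!is.numeric(max_heavy_distance) || max_heavy_distance <= 0)
    stop("max_heavy_distance must be positive")
  structure(list(max_heavy_distance = max_heavy_distance,
                 angle_min = angle_min),
            class = "hbond_criteria")
}

## Can atoms with roles ri, rj form a donor->acceptor pair (either way)?
.hb_compatible <- function(ri, rj) {
  donor_i <- ri %in% c("donor", "both", "water_oxygen")
  donor_j <- rj %in% c("donor", "both", "water_oxygen")
  acc_i <- ri %in% c("acceptor", "both", "water_oxygen")
  acc_j <- rj %in% c("acceptor", "both", "water_oxygen")
  (donor_i & acc_j) | (donor_j & acc_i)
}

#' Node set of the chain graph for one frame
#'
#' Protein atoms with a donor/acceptor role plus water oxygens inside the
#' analysis zone: the union of the cluster-region spheres and a corridor
#' around the polar chain atoms.
#'
#' @param coords `N x 3` matrix (one frame).
#' @param top A [topology()].
#' @param regions List of [cluster_region()] (may be empty).
#' @param corridor_radius Corridor radius around polar chain atoms,
#'   Angstrom; default 6.
#' @return Integer vector of topology atom indices.
#' @export
chain_nodes <- function(coords, top, regions = list(), corridor_radius = 6) {
  polar <- which(top$atoms$role %in% c("donor", "acceptor", "both"))
  wat <- which(top$atoms$role == "water_oxygen")
  keep_wat <- logical(length(wat))
  if (length(wat) > 0L && length(polar) > 0L) {
    wm <- coords[wat, , drop = FALSE]
    for (i in polar) {
      d2 <- rowSums(sweep(wm, 2, coords[i, ])^2)
      keep_wat <- keep_wat | d2 <= corridor_radius^2
    }
    for (rg in regions) {
      ctr <- resolve_region_center(coords, rg, top)
      d2 <- rowSums(sweep(wm, 2, ctr)^2)
      keep_wat <- keep_wat | d2 <= rg$radius^2
    }
  }
  sort(c(polar, wat[keep_wat]))
}

#' Detect hydrogen-bond edges in one frame
#'
#' An edge joins two nodes when their heavy-atom distance does not exceed
#' the cutoff and one side is donor-capable while the other is
#' acceptor-capable (water oxygens count as both).
#'
#' @param coords `N x 3` matrix (one frame).
#' @param nodes Topology atom indices forming the graph nodes.
#' @param top A [topology()].
#' @param criteria An [hbond_criteria()].
#' @return Two-column integer matrix of node pairs (topology indices,
#'   `from < to`); zero rows when no edges.
#' @export
detect_hbond_edges <- function(coords, nodes, top, criteria = hbond_criteria()) {
  n <- length(nodes)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (n < 2L) return(empty)
  roles <- top$atoms$role[nodes]
  m <- coords[nodes, , drop = FALSE]
  d <- as.matrix(stats::dist(m))
  pairs <- which(upper.tri(d) & d <= criteria$max_heavy_distance, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(empty)
  ok <- .hb_compatible(roles[pairs[, 1]], roles[pairs[, 2]])
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  out <- cbind(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Source-to-sink connectivity in one frame
#'
#' Builds the hydrogen-bond graph over `nodes` and asks whether any path
#' joins a source node to a sink node.  When connected, a witness path
#' (shortest by hop count) is returned as topology atom indices.
#'
#' @param coords `N x 3` matrix (one frame).
#' @param top A [topology()].
#' @param source_nodes,sink_nodes Disjoint, non-empty topology index sets.
#' @param criteria An [hbond_criteria()].
#' @param nodes Graph node set; defaults to source, sink, and all
#'   polar/water atoms via [chain_nodes()].
#' @param regions Regions forwarded to [chain_nodes()].
#' @return List with `connected` (logical) and `path` (integer vector of
#'   topology indices, empty when disconnected).
#' @export
frame_connected <- function(coords, top, source_nodes, sink_nodes,
                            criteria = hbond_criteria(), nodes = NULL,
                            regions = list()) {
  if (length(source_nodes) == 0L || length(sink_nodes) == 0L)
    stop("source and sink node sets must be non-empty")
  if (length(intersect(source_nodes, sink_nodes)) > 0L)
    stop("source and sink node sets overlap")
  if (is.null(nodes))
    nodes <- union(chain_nodes(coords, top, regions), c(source_nodes, sink_nodes))
  nodes <- sort(nodes)
  edges <- detect_hbond_edges(coords, nodes, top, criteria)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  src <- as.character(intersect(source_nodes, nodes))
  snk <- as.character(intersect(sink_nodes, nodes))
  if (length(src) == 0L || length(snk) == 0L)
    return(list(connected = FALSE, path = integer(0)))
  dmat <- igraph::distances(g, v = src, to = snk)
  if (!any(is.finite(dmat)))
    return(list(connected = FALSE, path = integer(0)))
  hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
  sp <- igraph::shortest_paths(g, from = src[hit[1]], to = snk[hit[2]])
  path <- as.integer(names(sp$vpath[[1]]))
  list(connected = TRUE, path = path)
}

## Resolve one canonical chain element to topology atom indices for a
## frame: residues -> their polar side-chain atoms; regions -> the water
## oxygens currently inside the matching scenario region(s).
.canonical_groups <- function(coords, top, scenario) {
  regions_by_label <- function(lbl) {
    if (lbl == "W2/W3")
      Filter(function(r) r$name %in% c("W2/W3", "W2", "W3"), scenario$regions)
    else
      Filter(function(r) r$name == lbl, scenario$regions)
  }
  wat <- which(top$atoms$role == "water_oxygen")
  lapply(canonical_chain(), function(el) {
    if (el$kind == "residue") {
      atom_select(top, chain = el$chain, resseq = el$resseq, role = "polar")
    } else {
      idx <- integer(0)
      for (rg in regions_by_label(el$label)) {
        ctr <- resolve_region_center(coords, rg, top)
        d2 <- rowSums(sweep(coords[wat, , drop = FALSE], 2, ctr)^2)
        idx <- union(idx, wat[d2 <= rg$radius^2])
      }
      idx
    }
  })
}

#' Proton-transfer-chain verdict over a trajectory
#'
#' Aggregates per-frame source-to-sink connectivity into a percentage and
#' a preserved/interrupted verdict, and reports which adjacent segments of
#' the canonical chain (aE219 - aD119 - aH245 - W2/W3 - aN214 - W1 - cD61)
#' were never bridged in any frame.
#'
#' @param traj A [trajectory()].
#' @param scenario A [scenario_spec()].
#' @param criteria An [hbond_criteria()].
#' @param threshold_pct Connectivity percentage below which the verdict is
#'   `"interrupted"`; default 5.
#' @return Object of class `"chain_verdict"`: list with `label`,
#'   `connectivity_fraction` (percent), `verdict`, `per_frame` (logical),
#'   `broken_links` (character vector of `"X->Y"` labels), and
#'   `witness_path` (topology serials from the first connected frame).
#' @export
connectivity_fraction <- function(traj, scenario,
                                  criteria = hbond_criteria(),
                                  threshold_pct = 5) {
  if (traj$n_frames < 1L) stop("empty trajectory")
  top <- traj$topology
  src <- resolve_selection(top, scenario$source_selection, "source")
  snk <- resolve_selection(top, scenario$sink_selection, "sink")
  if (length(src) == 0L) stop("source selection resolves to no atoms")
  if (length(snk) == 0L) stop("sink selection resolves to no atoms")
  chain <- canonical_chain()
  n_links <- length(chain) - 1L
  link_seen <- rep(FALSE, n_links)
  connected <- logical(traj$n_frames)
  witness <- integer(0)
  for (f in seq_len(traj$n_frames)) {
    m <- frame_coords(traj, f)
    res <- frame_connected(m, top, src, snk, criteria,
                           regions = scenario$regions)
    connected[f] <- res$connected
    if (res$connected && length(witness) == 0L)
      witness <- top$atoms$serial[res$path]
    groups <- .canonical_groups(m, top, scenario)
    for (l in seq_len(n_links)) {
      if (link_seen[l]) next
      ga <- groups[[l]]; gb <- groups[[l + 1L]]
      if (length(ga) == 0L || length(gb) == 0L) next
      d <- .cross_min_distance(m, ga, gb)
      if (d <= criteria$max_heavy_distance) link_seen[l] <- TRUE
    }
  }
  frac <- 100 * mean(connected)
  labels <- vapply(chain, `[[`, "", "label")
  broken <- paste(labels[-length(labels)][!link_seen],
                  labels[-1][!link_seen], sep = "->")
  structure(list(label = scenario$label,
                 connectivity_fraction = frac,
                 verdict = if (frac < threshold_pct) "interrupted" else "preserved",
                 per_frame = connected,
                 broken_links = broken,
                 witness_path = witness,
                 threshold_pct = threshold_pct),
            class = "chain_verdict")
}

#' @export
print.chain_verdict <- function(x, ...) {
  cat(sprintf("%s: %s (%.1f%% of frames connected)\n",
              x$label, x$verdict, x$connectivity_fraction))
  if (length(x$broken_links) > 0L)
    cat("  never bridged:", paste(x$broken_links, collapse = ", "), "\n")
  invisible(x)
}

.cross_min_distance <- function(coords, ia, ib) {
  a <- coords[ia, , drop = FALSE]
  b <- coords[ib, , drop = FALSE]
  min(vapply(seq_len(nrow(a)), function(i)
    min(sqrt(rowSums(sweep(b, 2, a[i, ])^2))), 0))
}

#' Per-frame minimum cross-pair distance between two selections
#'
#' @param traj A [trajectory()].
#' @param sel_a,sel_b Selection lists or index vectors.
#' @return List with `series` (Angstrom per frame), `mean`, `min`.
#' @export
pairwise_min_distance_series <- function(traj, sel_a, sel_b) {
  top <- traj$topology
  ia <- resolve_selection(top, sel_a, "sel_a")
  ib <- resolve_selection(top, sel_b, "sel_b")
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  series <- vapply(seq_len(traj$n_frames), function(f)
    .cross_min_distance(frame_coords(traj, f), ia, ib), 0)
  list(series = series, mean = mean(series), min = min(series))
}
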