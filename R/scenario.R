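#' Define a water-cluster region
#'
#' A region is a sphere whose center follows the structure: it is the
#' midpoint of the centroids of two anchor atom groups, recomputed every
#' frame so the region tracks residue motion.
#'
#' @param name Region name (`"W1"`, `"W2"`, `"W3"`, `"W2/W3"` or custom).
#' @param anchor_a,anchor_b Selection lists (see [resolve_selection()]).
#' @param radius Sphere radius in Angstrom; default 3.5.
#' @return Object of class `"cluster_region"`.
#' @export
cluster_region <- function(name, anchor_a, anchor_b, radius = 3.5) {
  if (!is.numeric(radius) || radius <= 0) stop("region radius must be > 0")
  structure(list(name = name, anchor_a = anchor_a, anchor_b = anchor_b,
                 radius = radius),
            class = "cluster_region")
}

## Canonical half-channel chain, periplasmic source to cD61 sink.  Region
## entries are bridged by structural waters; residue entries by side-chain
## polar atoms.  Used for default regions and broken-link reporting.
canonical_chain <- function() {
  list(
    list(kind = "residue", label = "aE219", chain = "A", resseq = 219L),
    list(kind = "residue", label = "aD119", chain = "A", resseq = 119L),
    list(kind = "residue", label = "aH245", chain = "A", resseq = 245L),
    list(kind = "region",  label = "W2/W3"),
    list(kind = "residue", label = "aN214", chain = "A", resseq = 214L),
    list(kind = "region",  label = "W1"),
    list(kind = "residue", label = "cD61",  chain = "C", resseq = 61L))
}

.default_regions <- function(radius = 3.5) {
  ca <- function(ch, rs) list(chain = ch, resseq = rs, name = "CA")
  list(cluster_region("W1", ca("A", 214), ca("C", 61), radius),
       cluster_region("W2", ca("A", 245), ca("A", 214), radius),
       cluster_region("W3", ca("A", 245), ca("A", 214), radius))
}

#' Construct a scenario specification
#'
#' A scenario describes one mutant system: the substitutions applied, the
#' proton source and sink selections, the water-cluster regions, the gate
#' residues to monitor, and free-form MD metadata.
#'
#' @param label Scenario label, e.g. `"aH245G"`.
#' @param substitutions `data.frame` with columns `chain_id`, `res_seq`,
#'   `from_res`, `to_res` (zero rows for wild type).
#' @param source_selection,sink_selection Selection lists.
#' @param regions List of [cluster_region()]; defaults to W1/W2/W3 anchored
#'   on the canonical chain residues.
#' @param gate_residues List of `list(chain=, resseq=)` residue references.
#' @param md_metadata Free-form named list (temperature, ensemble, ...).
#' @param membrane Optional [membrane_composition()] block.
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(label, substitutions = NULL,
                          source_selection, sink_selection,
                          regions = NULL, gate_residues = list(),
                          md_metadata = list(), membrane = NULL) {
  missing_keys <- character(0)
  if (is.null(label) || !nzchar(label)) missing_keys <- c(missing_keys, "label")
  if (missing(sink_selection) || is.null(sink_selection))
    missing_keys <- c(missing_keys, "sink")
  if (missing(source_selection) || is.null(source_selection))
    missing_keys <- c(missing_keys, "source")
  if (length(missing_keys) > 0L)
    stop("scenario is missing required keys: ",
         paste(missing_keys, collapse = ", "))
  if (is.null(substitutions))
    substitutions <- data.frame(chain_id = character(), res_seq = integer(),
                                from_res = character(), to_res = character(),
                                stringsAsFactors = FALSE)
  if (is.null(regions)) regions <- .default_regions()
  nms <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate region names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  structure(list(label = label, substitutions = substitutions,
                 source_selection = source_selection,
                 sink_selection = sink_selection,
                 regions = regions, gate_residues = gate_residues,
                 md_metadata = md_metadata, membrane = membrane),
            class = "scenario_spec")
}

#' Load a scenario configuration file
#'
#' YAML layout (all selection values are mappings understood by
#' [resolve_selection()]):
#' ```yaml
#' label: aH245G
#' substitutions:
#'   - {chain: A, resseq: 245, from: HIS, to: GLY}
#' source: {chain: A, resseq: [219, 119], role: polar}
#' sink:   {chain: C, resseq: 61, role: polar}
#' regions:
#'   - {name: "W2/W3",
#'      anchor_a: {chain: A, resseq: 245, name: CA},
#'      anchor_b: {chain: A, resseq: 214, name: CA}, radius: 3.5}
#' gate_residues: [{chain: A, resseq: 140}, {chain: A, resseq: 119}]
#' md_metadata: {temperature_K: 310, ensemble: NPT, production_ns: 150}
#' ```
#' Omitted `regions` default to W1, W2 and W3 anchored on the canonical
#' chain residues (aN214/cD61 and aH245/aN214 CA atoms).
#'
#' @param path YAML file path.
#' @return A [scenario_spec()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  subs <- NULL
  if (!is.null(cfg$substitutions) && length(cfg$substitutions) > 0L) {
    subs <- do.call(rbind, lapply(cfg$substitutions, function(s)
      data.frame(chain_id = as.character(s$chain),
                 res_seq = as.integer(s$resseq),
                 from_res = toupper(s$from), to_res = toupper(s$to),
                 stringsAsFactors = FALSE)))
  }
  regions <- NULL
  if (!is.null(cfg$regions)) {
    regions <- lapply(cfg$regions, function(r) {
      if (is.null(r$name)) stop("region without a name in ", path)
      cluster_region(r$name, r$anchor_a, r$anchor_b,
                     radius = if (is.null(r$radius)) 3.5 else r$radius)
    })
  }
  membrane <- if (!is.null(cfg$membrane)) do.call(membrane_composition,
                                                  cfg$membrane) else NULL
  scenario_spec(label = cfg$label, substitutions = subs,
                source_selection = cfg$source, sink_selection = cfg$sink,
                regions = regions,
                gate_residues = if (is.null(cfg$gate_residues)) list()
                                else cfg$gate_residues,
                md_metadata = if (is.null(cfg$md_metadata)) list()
                              else cfg$md_metadata,
                membrane = membrane)
}

#' Write a scenario specification to YAML
#'
#' @param spec A [scenario_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(spec, path) {
  cfg <- list(label = spec$label)
  if (nrow(spec$substitutions) > 0L)
    cfg$substitutions <- lapply(seq_len(nrow(spec$substitutions)), function(i)
      list(chain = spec$substitutions$chain_id[i],
           resseq = spec$substitutions$res_seq[i],
           from = spec$substitutions$from_res[i],
           to = spec$substitutions$to_res[i]))
  cfg$source <- spec$source_selection
  cfg$sink <- spec$sink_selection
  cfg$regions <- lapply(spec$regions, function(r)
    list(name = r$name, anchor_a = r$anchor_a, anchor_b = r$anchor_b,
         radius = r$radius))
  cfg$gate_residues <- spec$gate_residues
  cfg$md_metadata <- spec$md_metadata
  yaml::write_yaml(cfg, path)
  invisible(path)
}
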