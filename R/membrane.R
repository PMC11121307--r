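## Membrane-composition bookkeeping: lipid class percentages and system
## net-charge validation.  Metadata only; no coordinates are built.

#' Membrane composition metadata
#'
#' @param species_counts Named integer vector: lipid species code ->
#'   molecule count (all positive).
#' @param class_map Named character vector: species code -> lipid class
#'   (e.g. `"PE"`, `"CL"`); every species must be mapped.
#' @param waters Number of water molecules (metadata).
#' @param salt_mM Salt concentration in mM (metadata).
#' @param species_charges Named numeric vector of formal charges per
#'   species (unlisted species are neutral); cardiolipins are typically -2.
#' @return Object of class `"membrane_composition"`.
#' @export
membrane_composition <- function(species_counts, class_map,
                                 waters = NA_integer_, salt_mM = NA_real_,
                                 species_charges = NULL) {
  species_counts <- unlist(species_counts)
  class_map <- unlist(class_map)
  if (any(species_counts <= 0) || any(species_counts != round(species_counts)))
    stop("species counts must be positive integers")
  unmapped <- setdiff(names(species_counts), names(class_map))
  if (length(unmapped) > 0L)
    stop("species not mapped to a lipid class: ",
         paste(unmapped, collapse = ", "))
  if (is.null(species_charges)) species_charges <- numeric(0)
  structure(list(species_counts = species_counts, class_map = class_map,
                 waters = waters, salt_mM = salt_mM,
                 species_charges = unlist(species_charges)),
            class = "membrane_composition")
}

#' Lipid class percentages
#'
#' Per-class share of the total lipid molecule count, rounded half-up to
#' integers with a largest-remainder reconciliation so the rounded shares
#' always sum to exactly 100.
#'
#' @param comp A [membrane_composition()].
#' @return Named integer vector of percentages per class.
#' @export
class_percentages <- function(comp) {
  cls <- comp$class_map[names(comp$species_counts)]
  totals <- tapply(comp$species_counts, cls, sum)
  shares <- 100 * as.numeric(totals) / sum(totals)
  names(shares) <- names(totals)
  rounded <- floor(shares + 0.5)                    # half-up
  deficit <- 100L - as.integer(sum(rounded))
  if (deficit != 0L) {
    remainder <- shares - floor(shares)
    ord <- order(if (deficit > 0L) -remainder else remainder,
                 names(shares))                     # deterministic ties
    bump <- ord[seq_len(abs(deficit))]
    rounded[bump] <- rounded[bump] + sign(deficit)
  }
  out <- as.integer(rounded)
  names(out) <- names(shares)
  out
}

#' System net-charge residual
#'
#' Sums lipid formal charges, ion charges and the protein charge; a zero
#' residual means the system is electroneutral.
#'
#' @param comp A [membrane_composition()] carrying `species_charges`.
#' @param ion_counts Named integer vector of ion counts, e.g.
#'   `c(K = 288, CL = 0)`.
#' @param ion_charges Named charges per ion species; defaults cover
#'   K (+1), NA (+1), CL (-1).
#' @param protein_charge Protein formal charge, default 0.
#' @return Signed integer residual charge.
#' @export
net_charge_check <- function(comp, ion_counts = integer(0),
                             ion_charges = c(K = 1, NA. = 1, CL = -1),
                             protein_charge = 0) {
  lipid_q <- 0
  if (length(comp$species_charges) > 0L) {
    sp <- intersect(names(comp$species_charges), names(comp$species_counts))
    lipid_q <- sum(comp$species_charges[sp] * comp$species_counts[sp])
  }
  ion_q <- 0
  if (length(ion_counts) > 0L) {
    unknown <- setdiff(names(ion_counts), names(ion_charges))
    if (length(unknown) > 0L)
      stop("no charge configured for ion(s): ", paste(unknown, collapse = ", "))
    ion_q <- sum(ion_charges[names(ion_counts)] * ion_counts)
  }
  as.integer(round(lipid_q + ion_q + protein_charge))
}

#' Inner-bacterial-membrane composition used by the study systems
#'
#' The five-species lipid mixture (three phosphatidylethanolamines, two
#' dianionic cardiolipins) the simulated bilayer was built from.
#'
#' @return A [membrane_composition()].
#' @export
reference_membrane <- function() {
  membrane_composition(
    species_counts = c(DYPE = 206L, DPPE = 96L, PMPE = 96L,
                       PMCL = 108L, TYCL = 36L),
    class_map = c(DYPE = "PE", DPPE = "PE", PMPE = "PE",
                  PMCL = "CL", TYCL = "CL"),
    waters = 36785L, salt_mM = 150,
    species_charges = c(PMCL = -2, TYCL = -2))
}
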