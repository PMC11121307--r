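#' @importFrom stats setNames
NULL

## Donor/acceptor role lookup for protein side-chain polar heavy atoms.
## Keys are "RESNAME|ATOMNAME"; anything not listed gets role "none"
## (water oxygens are handled separately via the water residue-name set).
.polar_role_table <- c(
  "ASP|OD1" = "acceptor", "ASP|OD2" = "acceptor",
  "GLU|OE1" = "acceptor", "GLU|OE2" = "acceptor",
  "HIS|ND1" = "both",     "HIS|NE2" = "both",
  "HSD|ND1" = "both",     "HSD|NE2" = "both",
  "HSE|ND1" = "both",     "HSE|NE2" = "both",
  "HSP|ND1" = "both",     "HSP|NE2" = "both",
  "SER|OG"  = "both",
  "THR|OG1" = "both",
  "TYR|OH"  = "both",
  "ASN|OD1" = "acceptor", "ASN|ND2" = "donor",
  "GLN|OE1" = "acceptor", "GLN|NE2" = "donor",
  "ARG|NE"  = "donor",    "ARG|NH1" = "donor", "ARG|NH2" = "donor",
  "LYS|NZ"  = "donor"
)

#' Default water residue names
#'
#' Residue codes recognized as water.  Covers crystallographic (`HOH`),
#' CHARMM (`TIP3`), AMBER (`WAT`) and GROMACS (`SOL`) naming conventions.
#' Every water-related operation accepts a `water_names` argument to
#' override this set.
#'
#' @return Character vector of residue codes.
#' @export
default_water_names <- function() c("HOH", "TIP3", "WAT", "SOL")

## Water oxygen atom names across the same force-field conventions.
.water_oxygen_names <- c("O", "OH2", "OW")

#' Assign a hydrogen-bonding role to an atom
#'
#' Pure lookup on `(res_name, atom_name)`: protein side-chain polar heavy
#' atoms get `donor`, `acceptor` or `both`; oxygen atoms of water residues
#' get `water_oxygen`; everything else `none`.
#'
#' @param res_name 3-letter residue code(s).
#' @param atom_name Atom name(s), e.g. `"OD1"`.
#' @param water_names Residue codes treated as water.
#' @return Character vector of roles, one per input atom.
#' @export
assign_role <- function(res_name, atom_name,
                        water_names = default_water_names()) {
  res_name <- toupper(trimws(res_name))
  atom_name <- toupper(trimws(atom_name))
  role <- unname(.polar_role_table[paste(res_name, atom_name, sep = "|")])
  role[is.na(role)] <- "none"
  is_wat_o <- res_name %in% water_names & atom_name %in% .water_oxygen_names
  role[is_wat_o] <- "water_oxygen"
  role
}

#' Construct a topology
#'
#' A topology is the static atom table of a system: one row per atom with
#' residue identity and a hydrogen-bonding role flag.  Roles are always
#' (re-)assigned here from the `(res_name, name)` lookup, so re-reading a
#' file can never change them.
#'
#' @param atoms `data.frame` with columns `serial`, `name`, `element`,
#'   `res_name`, `res_seq`, `chain_id`.
#' @param water_names Residue codes treated as water.
#' @return Object of class `"topology"`: a list with `atoms` (the table,
#'   with a `role` column added) and `n_atoms`.
#' @export
topology <- function(atoms, water_names = default_water_names()) {
  req <- c("serial", "name", "element", "res_name", "res_seq", "chain_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty topology: no atoms")
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serial numbers: ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
  atoms <- atoms[, req, drop = FALSE]
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$role <- assign_role(atoms$res_name, atoms$name, water_names)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_atoms = nrow(atoms),
                 water_names = water_names),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,",
      nrow(unique(x$atoms[, c("chain_id", "res_seq")])), "residues,",
      sum(x$atoms$role == "water_oxygen"), "water oxygens\n")
  invisible(x)
}

#' Residue index of a topology
#'
#' @param top A [topology()].
#' @return Named list mapping `"<chain>:<res_seq>"` to the integer atom
#'   indices of that residue; covers every atom exactly once.
#' @export
residue_index <- function(top) {
  key <- paste(top$atoms$chain_id, top$atoms$res_seq, sep = ":")
  split(seq_len(top$n_atoms), factor(key, levels = unique(key)))
}

#' Select atoms from a topology
#'
#' Structured selection: each non-NULL argument restricts the match.
#' `role = "polar"` is shorthand for any of `donor`, `acceptor`, `both`.
#'
#' @param top A [topology()].
#' @param chain,resseq,resname,name,role Optional filters (vectors allowed).
#' @return Integer vector of matching atom indices (possibly empty).
#' @export
atom_select <- function(top, chain = NULL, resseq = NULL, resname = NULL,
                        name = NULL, role = NULL) {
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain_id %in% chain
  if (!is.null(resseq))  keep <- keep & a$res_seq %in% as.integer(resseq)
  if (!is.null(resname)) keep <- keep & a$res_name %in% toupper(resname)
  if (!is.null(name))    keep <- keep & a$name %in% toupper(name)
  if (!is.null(role)) {
    role <- if (identical(role, "polar")) c("donor", "acceptor", "both") else role
    keep <- keep & a$role %in% role
  }
  which(keep)
}

#' Resolve a selection specification against a topology
#'
#' Selections are named lists (as loaded from scenario YAML), e.g.
#' `list(chain = "A", resseq = c(219, 119), role = "polar")`.
#'
#' @param top A [topology()].
#' @param sel Named list with any of `chain`, `resseq`, `resname`, `name`,
#'   `role`; an integer vector is passed through as explicit indices.
#' @param what Label used in error messages.
#' @return Integer vector of atom indices.
#' @export
resolve_selection <- function(top, sel, what = "selection") {
  if (is.numeric(sel)) return(as.integer(sel))
  if (!is.list(sel))
    stop(what, " must be a named list or integer indices")
  unknown <- setdiff(names(sel), c("chain", "resseq", "resname", "name", "role"))
  if (length(unknown) > 0L)
    stop(what, " has unknown selection keys: ", paste(unknown, collapse = ", "))
  idx <- atom_select(top,
                     chain = sel$chain, resseq = sel$resseq,
                     resname = sel$resname, name = sel$name, role = sel$role)
  idx
}
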