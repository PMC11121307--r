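## Structure and trajectory I/O.  Parsing of PDB (single and multi-model)
## and CHARMM DCD files is delegated to bio3d; this layer adds the
## validation contract (insertion codes, duplicate serials, altloc
## resolution, per-model atom-count checks) and the writers, which bio3d
## does not provide for multi-model PDB or DCD.

#' Read a structure file into a topology
#'
#' Accepts PDB `ATOM`/`HETATM` records.  Insertion codes are rejected
#' (author residue numbering is used verbatim and must be unambiguous).
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer, with a warning.
#'
#' @param path Path to a PDB file.
#' @param dialect Only `"pdb"` is supported for structures.
#' @param water_names Residue codes treated as water.
#' @return A [topology()].
#' @export
read_structure <- function(path, dialect = "pdb",
                           water_names = default_water_names()) {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty input: no ATOM/HETATM records in ", path)
  if (any(!is.na(at$insert)))
    stop("insertion codes are not supported (found at residue ",
         at$resno[which(!is.na(at$insert))[1]], ")")
  at <- .resolve_altloc(at)
  if (anyDuplicated(at$eleno))
    stop("parse error: duplicate atom serial numbers in ", path)
  atoms <- data.frame(
    serial = at$eleno,
    name = toupper(at$elety),
    element = .element_of(at),
    res_name = toupper(at$resid),
    res_seq = at$resno,
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    stringsAsFactors = FALSE)
  topology(atoms, water_names = water_names)
}

## Light pre-scan: every ATOM/HETATM line must carry parseable coordinates.
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed PDB record at line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

.resolve_altloc <- function(at) {
  has_alt <- !is.na(at$alt) & at$alt != ""
  if (!any(has_alt)) return(at)
  warning("alternate locations present; keeping highest-occupancy conformer")
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) > 1L) keep[idx[-which.max(occ[idx])]] <- FALSE
  }
  at[keep, , drop = FALSE]
}

.element_of <- function(at) {
  el <- toupper(trimws(at$elesy))
  miss <- is.na(el) | el == ""
  ## fall back on the first letter of the atom name (skipping digits)
  el[miss] <- toupper(substr(gsub("^[0-9]+", "", trimws(at$elety[miss])), 1, 1))
  el
}

#' Construct a trajectory
#'
#' @param top A [topology()].
#' @param coords Numeric array of dimension `F x N x 3` (frames, atoms,
#'   xyz) in Angstrom, or an `N x 3` matrix for a single frame.
#' @param frame_interval_ps Time between recorded frames, picoseconds.
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(top, coords, frame_interval_ps = 2) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an F x N x 3 array")
  if (dim(coords)[2] != top$n_atoms)
    stop("coordinate atom count (", dim(coords)[2],
         ") does not match topology (", top$n_atoms, ")")
  if (dim(coords)[1] < 1L) stop("trajectory must have at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0)
    stop("frame_interval_ps must be positive")
  structure(list(topology = top, coords = coords,
                 n_frames = dim(coords)[1],
                 frame_interval_ps = frame_interval_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$n_frames, "frames x", x$topology$n_atoms,
      "atoms, dt =", x$frame_interval_ps, "ps\n")
  invisible(x)
}

#' Coordinates of one frame
#'
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return `N x 3` numeric matrix in Angstrom.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > traj$n_frames) stop("frame index out of range: ", i)
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Read a trajectory
#'
#' @param top Topology the frames must match.
#' @param path Multi-model PDB or CHARMM DCD file.
#' @param dialect `"pdb"` (multi-model, mandatory dialect) or `"dcd"`.
#' @param frame_interval_ps Frame spacing metadata (ps); not stored in
#'   either file format.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(top, path, dialect = c("pdb", "dcd"),
                            frame_interval_ps = 2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "pdb") {
    .check_model_counts(path, top$n_atoms)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  } else {
    xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    if (ncol(xyz) != 3L * top$n_atoms)
      stop("DCD atom count (", ncol(xyz) / 3,
           ") does not match topology (", top$n_atoms, ")")
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, top$n_atoms, 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  trajectory(top, coords, frame_interval_ps = frame_interval_ps)
}

.check_model_counts <- function(path, n_expected) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    n <- sum(is_atom)
    if (n != n_expected)
      stop("atom count mismatch: file has ", n, ", topology has ", n_expected)
    return(invisible(1L))
  }
  model_id <- cumsum(grepl("^MODEL", lines))
  counts <- tapply(is_atom[model_id > 0], model_id[model_id > 0], sum)
  if (any(counts != n_expected))
    stop("atom count mismatch between MODEL blocks and topology (",
         paste(unique(counts), collapse = "/"), " vs ", n_expected, ")")
  invisible(length(counts))
}

#' Write a trajectory (or single structure)
#'
#' PDB output uses one `MODEL`/`ENDMDL` block per frame (plain records for
#' a single frame); coordinates are written at the format's 3-decimal
#' precision.  DCD output is CHARMM-style single precision.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @param dialect `"pdb"` or `"dcd"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("pdb", "dcd")) {
  dialect <- match.arg(dialect)
  if (dialect == "pdb") .write_pdb_frames(traj, path) else .write_dcd(traj, path)
  invisible(path)
}

#' Write a topology with one set of coordinates as a PDB file
#'
#' @param top A [topology()].
#' @param coords `N x 3` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, coords, path) {
  write_trajectory(trajectory(top, coords), path, dialect = "pdb")
}

.pdb_atom_lines <- function(atoms, m) {
  nm <- atoms$name
  nm4 <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, nm4, atoms$res_name,
          substr(atoms$chain_id, 1, 1), atoms$res_seq,
          m[, 1], m[, 2], m[, 3], 1, 0, atoms$element)
}

.write_pdb_frames <- function(traj, path) {
  atoms <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- traj$n_frames > 1L
  for (f in seq_len(traj$n_frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(.pdb_atom_lines(atoms, frame_coords(traj, f)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

## Minimal CHARMM-format DCD writer (32-bit Fortran record markers,
## little-endian, single-precision coordinates, no unit cell).
.write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- traj$n_frames       # NSET
  icntrl[2] <- 1L                  # ISTART
  icntrl[3] <- 1L                  # NSAVC
  icntrl[4] <- traj$n_frames
  icntrl[10] <- 981668463L         # AKMA timestep bit pattern (2 fs), metadata only
  icntrl[20] <- 24L                # CHARMM version flag
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- sprintf("%-80s", "written by halfchannel")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(traj$topology$n_atoms), con,
                          size = 4, endian = "little"), 4)
  nb <- 4L * traj$topology$n_atoms
  for (f in seq_len(traj$n_frames)) {
    m <- frame_coords(traj, f)
    for (k in 1:3)
      rec(function() writeBin(as.numeric(m[, k]), con, size = 4,
                              endian = "little"), nb)
  }
}
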