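#' @importFrom stats approx coef median rnorm runif sd setNames uniroot var
#' @importFrom utils read.csv write.csv head tail
NULL

#' Construct a structure model
#'
#' A `structure_model` is the atomic substrate for all geometry operations:
#' an atom table (one row per atom, in file order) carrying PDB-style atom
#' and residue identities, plus Cartesian coordinates in Angstrom. Residue
#' numbers are taken verbatim from the source and never renumbered, so
#' positional claims about residues (e.g. an arginine at position 86 bridging
#' tryptophans 21 and 94) survive round trips.
#'
#' @param atoms data.frame with columns `serial` (integer), `atom_name`
#'   (PDB atom naming, e.g. `"CA"`, `"CZ"`, `"CE2"`), `residue_name`
#'   (3-letter code), `chain_id` (single character), `residue_number`
#'   (integer, as printed in the file), `element`, and coordinates
#'   `x`, `y`, `z` in Angstrom.
#' @param model_id integer model identifier (PDB MODEL number).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  needed <- c("serial", "atom_name", "residue_name", "chain_id",
              "residue_number", "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty-input error: structure model must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$atom_name)))
    stop("atom_name must be non-empty")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_number, atom_name) within model: ",
         key[which(duplicated(key))[1L]])
  atoms$residue_number <- as.integer(atoms$residue_number)
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues, model %d\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_number))),
              x$model_id))
  invisible(x)
}

#' Construct a trajectory ensemble
#'
#' Ordered conformational frames over one atom table (fixed atom ordering),
#' with strictly increasing time stamps in picoseconds. Multi-model PDB files
#' are the canonical text exchange format; any source that yields a
#' `(times, frames)` pair with fixed atom ordering can be adapted.
#'
#' @param reference a [structure_model()]; its atom table defines atom
#'   identities and ordering for every frame.
#' @param frames list of numeric `n_atoms x 3` coordinate matrices (Angstrom).
#' @param times numeric vector of frame times in ps, strictly increasing.
#'   Default `0, 1, 2, ...`.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(reference, frames,
                                times = seq_along(frames) - 1) {
  stopifnot(inherits(reference, "structure_model"))
  n_at <- nrow(reference$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_at &&
                 ncol(f) == 3L, logical(1))
  if (!all(ok))
    stop("every frame must be an n_atoms x 3 matrix matching the reference (",
         n_at, " atoms)")
  if (length(times) != length(frames))
    stop("times and frames lengths differ")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(reference = reference, frames = frames,
                 times = as.numeric(times)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d frames x %d atoms, t = %g..%g ps\n",
              length(x$frames), nrow(x$reference$atoms),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory_ensemble()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  bad <- which(is_atom & nchar(lines) < 54L)
  if (length(bad))
    stop(sprintf("parse error at line %d: ATOM/HETATM record shorter than 54 columns",
                 bad[1L]))
  for (i in which(is_atom)) {
    for (cols in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
      field <- substr(lines[i], cols[1L], cols[2L])
      if (is.na(suppressWarnings(as.numeric(field))))
        stop(sprintf("parse error at line %d: non-numeric coordinate field '%s'",
                     i, field))
    }
  }
  invisible(sum(is_atom))
}

#' Read a PDB structure or multi-model ensemble
#'
#' Parses ATOM/HETATM records (fixed-column PDB layout, coordinates in
#' Angstrom). A file with a single model returns a [structure_model()]; a
#' multi-model file (MODEL/ENDMDL) returns a [trajectory_ensemble()] whose
#' frame times default to `0, 1, 2, ...` ps (override via `frame_dt`).
#' Hydrogens are read if present and never added.
#'
#' @param path path to a PDB file.
#' @param frame_dt time spacing in ps between successive MODEL records
#'   (default 1 ps).
#' @return A [structure_model()] (single model) or [trajectory_ensemble()].
#' @export
read_pdb <- function(path, frame_dt = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n_atom_lines <- validate_pdb_lines(lines)
  if (n_atom_lines == 0L)
    stop("empty-input error: no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    chain_id = ifelse(is.na(a$chain), " ", a$chain),
    residue_number = as.integer(a$resno),
    element = ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                     guess_element(trimws(a$elety)), trimws(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  ref <- structure_model(atoms, model_id = 1L)
  nm <- nrow(pdb$xyz)
  if (nm <= 1L) return(ref)
  frames <- lapply(seq_len(nm), function(i)
    matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE))
  ref$atoms[, c("x", "y", "z")] <- frames[[1L]]
  trajectory_ensemble(ref, frames, times = (seq_len(nm) - 1) * frame_dt)
}

guess_element <- function(atom_name) {
  # strip leading digits (e.g. "1HB"), element = first letter
  substr(sub("^[0-9]*", "", atom_name), 1L, 1L)
}

format_pdb_atom <- function(serial, name, resname, chain, resno, x, y, z,
                            element) {
  # PDB v3 atom-name justification: names of <4 chars start in column 14
  nm <- ifelse(nchar(name) >= 4L, substr(name, 1L, 4L),
               sprintf(" %-3s", name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, resname, chain, resno, x, y, z, 1, 0, element)
}

#' Write a structure or trajectory to a PDB file
#'
#' Emits fixed-column ATOM records; a [trajectory_ensemble()] is written as a
#' multi-model file (MODEL/ENDMDL per frame). Coordinates carry the PDB's
#' native 1e-3 Angstrom precision; atom names, residue names and residue
#' numbers round-trip exactly.
#'
#' @param x a [structure_model()] or [trajectory_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure_model")) {
    a <- x$atoms
    lines <- c(format_pdb_atom(a$serial, a$atom_name, a$residue_name,
                               a$chain_id, a$residue_number,
                               a$x, a$y, a$z, a$element), "END")
  } else if (inherits(x, "trajectory_ensemble")) {
    a <- x$reference$atoms
    lines <- unlist(lapply(seq_along(x$frames), function(i) {
      f <- x$frames[[i]]
      c(sprintf("MODEL     %4d", i),
        format_pdb_atom(a$serial, a$atom_name, a$residue_name, a$chain_id,
                        a$residue_number, f[, 1L], f[, 2L], f[, 3L],
                        a$element),
        "ENDMDL")
    }))
    lines <- c(lines, "END")
  } else stop("x must be a structure_model or trajectory_ensemble")
  writeLines(lines, path)
  invisible(path)
}

#' Select atoms by chain, residue and atom name
#'
#' A pure filter over the atom table: the result is a subset of the input in
#' file order. An empty result is valid; callers decide whether that is an
#' error.
#'
#' @param model a [structure_model()].
#' @param chain chain identifier, or `NULL` to match any chain.
#' @param residue_number integer residue number, or `NULL` for any.
#' @param atom_names character vector of atom names, or `NULL` for any.
#' @return data.frame of matching atom rows (possibly zero rows).
#' @export
select_atoms <- function(model, chain = NULL, residue_number = NULL,
                         atom_names = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id == chain
  if (!is.null(residue_number)) keep <- keep & a$residue_number == residue_number
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  a[keep, , drop = FALSE]
}

atom_xyz <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Coordinates of a frame
#'
#' @param traj a [trajectory_ensemble()].
#' @param i frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) traj$frames[[i]]
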