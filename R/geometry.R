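#' Ring atom definitions for aromatic side chains
#'
#' Atom-name sets defining the aromatic plane and its ring hydrogens, per
#' residue type. For tryptophan the default plane is the six-membered benzene
#' ring of the indole (`CD2, CE2, CE3, CZ2, CZ3, CH2`), which has the four
#' benzo hydrogens; alternatives are the five-membered pyrrole ring or all
#' nine heavy atoms of the indole. Phenylalanine and tyrosine use the
#' standard six-membered ring.
#'
#' @param residue_name 3-letter residue code (`"TRP"`, `"PHE"`, `"TYR"`).
#' @param trp_ring for tryptophan, which atom set defines the plane:
#'   `"six"` (default), `"five"`, or `"all"`.
#' @return list with `ring_atom_names` and `hydrogen_atom_names`.
#' @export
ring_atom_names <- function(residue_name, trp_ring = c("six", "five", "all")) {
  trp_ring <- match.arg(trp_ring)
  switch(toupper(residue_name),
    TRP = switch(trp_ring,
      six = list(ring_atom_names = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                 hydrogen_atom_names = c("HE3", "HZ2", "HZ3", "HH2")),
      five = list(ring_atom_names = c("CG", "CD1", "CD2", "CE2", "NE1"),
                  hydrogen_atom_names = c("HD1", "HE1")),
      all = list(ring_atom_names = c("CG", "CD1", "CD2", "CE2", "CE3",
                                     "NE1", "CZ2", "CZ3", "CH2"),
                 hydrogen_atom_names = c("HD1", "HE1", "HE3", "HZ2",
                                         "HZ3", "HH2"))),
    PHE = list(ring_atom_names = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               hydrogen_atom_names = c("HD1", "HD2", "HE1", "HE2", "HZ")),
    TYR = list(ring_atom_names = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               hydrogen_atom_names = c("HD1", "HD2", "HE1", "HE2")),
    # synthetic benzene-like rings written by the generators
    BNZ = list(ring_atom_names = c("C1", "C2", "C3", "C4", "C5", "C6"),
               hydrogen_atom_names = c("H1", "H2", "H3", "H4", "H5", "H6")),
    stop("no ring definition for residue type ", residue_name)
  )
}

#' Ring specification
#'
#' Identifies one aromatic ring in a structure: a residue reference plus the
#' atom names spanning its plane and its ring hydrogens (may be absent in
#' heavy-atom models; then the approach angle phi is reported missing).
#'
#' @param chain chain identifier.
#' @param residue_number integer residue number.
#' @param residue_name 3-letter code; used to look up default atom sets.
#' @param ring_atoms,hydrogen_atoms optional explicit atom-name overrides.
#' @param trp_ring tryptophan plane choice, see [ring_atom_names()].
#' @return object of class `ring_spec`.
#' @export
ring_spec <- function(chain, residue_number, residue_name,
                      ring_atoms = NULL, hydrogen_atoms = NULL,
                      trp_ring = "six") {
  if (is.null(ring_atoms)) {
    def <- ring_atom_names(residue_name, trp_ring)
    ring_atoms <- def$ring_atom_names
    if (is.null(hydrogen_atoms)) hydrogen_atoms <- def$hydrogen_atom_names
  }
  if (length(ring_atoms) < 3L) stop("a ring needs at least 3 atoms")
  structure(list(chain = chain, residue_number = as.integer(residue_number),
                 residue_name = residue_name, ring_atom_names = ring_atoms,
                 hydrogen_atom_names = hydrogen_atoms %||% character(0)),
            class = "ring_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_ring <- function(model, spec) {
  ring <- select_atoms(model, spec$chain, spec$residue_number,
                       spec$ring_atom_names)
  if (nrow(ring) < 3L)
    stop(sprintf("degenerate-ring error: %s %s:%d resolves %d ring atoms (need >= 3)",
                 spec$residue_name, spec$chain, spec$residue_number, nrow(ring)))
  hyd <- select_atoms(model, spec$chain, spec$residue_number,
                      spec$hydrogen_atom_names)
  list(ring = atom_xyz(ring), hydrogens = atom_xyz(hyd))
}

#' Centroid of a ring
#'
#' Arithmetic mean of the ring-atom positions ("the center of the aromatic
#' ring").
#'
#' @param ring_xyz numeric `n x 3` matrix of ring-atom coordinates (Angstrom),
#'   n >= 3.
#' @return length-3 numeric vector.
#' @export
ring_centroid <- function(ring_xyz) {
  ring_xyz <- as_xyz_matrix(ring_xyz)
  if (nrow(ring_xyz) < 3L)
    stop("degenerate-ring error: need at least 3 ring atoms")
  colMeans(ring_xyz)
}

as_xyz_matrix <- function(x) {
  if (is.data.frame(x)) x <- atom_xyz(x)
  if (!is.matrix(x) || ncol(x) != 3L) stop("expected an n x 3 matrix")
  x
}

#' Unit normal of the best-fit ring plane
#'
#' Total-least-squares plane through the atoms: the normal is the direction
#' of least orthogonal variance (smallest principal axis of the centered
#' coordinates). The sign is fixed so that the z-component is >= 0 (ties
#' broken by x >= 0, then y >= 0); the fold of theta to \[0, 90\] makes the
#' sign physically irrelevant.
#'
#' @param ring_xyz numeric `n x 3` matrix, n >= 3, atoms not collinear.
#' @return unit length-3 numeric vector.
#' @export
ring_plane_normal <- function(ring_xyz) {
  ring_xyz <- as_xyz_matrix(ring_xyz)
  if (nrow(ring_xyz) < 3L)
    stop("degenerate-plane error: need at least 3 atoms")
  centered <- sweep(ring_xyz, 2L, colMeans(ring_xyz))
  s <- svd(centered)
  if (s$d[2L] < 1e-9 * max(s$d[1L], 1e-300))
    stop("degenerate-plane error: ring atoms are collinear")
  n <- s$v[, 3L]
  n <- n / sqrt(sum(n^2))
  flip <- if (abs(n[3L]) > 1e-12) n[3L] < 0
          else if (abs(n[1L]) > 1e-12) n[1L] < 0
          else n[2L] < 0
  if (flip) n <- -n
  n
}

angle_deg <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) stop("coincident-point error: zero-length vector")
  c_ang <- sum(u * v) / (cu * cv)
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

#' Cation-pi geometry of one ring/cation pair
#'
#' Computes the descriptor triple (theta, phi, d) for a cation approaching an
#' aromatic ring:
#' * `distance` — Angstrom from ring centroid to the cation point;
#' * `theta` — angle between the ring-plane *normal* and the
#'   centroid-to-cation vector, folded to \[0, 90\] degrees, so theta = 0 is
#'   an axial (on-axis, stacked) approach and theta = 90 an in-plane,
#'   lateral approach. Set `theta_from_plane = TRUE` to report the
#'   complementary angle measured from the plane itself;
#' * `phi` — the minimum, over the ring hydrogens, of the angle
#'   cation-centroid-H; phi near 0 means the cation points straight at a
#'   ring hydrogen. `NA` (missing) when the model has no ring hydrogens.
#'
#' @param ring_xyz `n x 3` matrix of ring atoms (or a data.frame of atom
#'   rows), n >= 3.
#' @param cation_point length-3 numeric vector (Angstrom).
#' @param hydrogen_xyz optional `m x 3` matrix of ring-hydrogen coordinates.
#' @param frame_index integer bookkeeping index (default 1).
#' @param theta_from_plane report theta measured from the plane rather than
#'   the normal (complement; default `FALSE`).
#' @return list of class `cation_pi_geometry` with fields `theta`, `phi`,
#'   `distance`, `frame_index` (and `label = NA` until classified).
#' @export
cation_pi_geometry <- function(ring_xyz, cation_point, hydrogen_xyz = NULL,
                               frame_index = 1L, theta_from_plane = FALSE) {
  ring_xyz <- as_xyz_matrix(ring_xyz)
  cen <- ring_centroid(ring_xyz)
  nrm <- ring_plane_normal(ring_xyz)
  v <- as.numeric(cation_point) - cen
  d <- sqrt(sum(v^2))
  if (d < 1e-9) stop("coincident-point error: cation at ring centroid")
  theta <- angle_deg(nrm, v)
  if (theta > 90) theta <- 180 - theta     # fold: normal sign irrelevant
  if (theta_from_plane) theta <- 90 - theta
  phi <- NA_real_
  if (!is.null(hydrogen_xyz)) {
    hydrogen_xyz <- as_xyz_matrix(hydrogen_xyz)
    if (nrow(hydrogen_xyz) > 0L)
      phi <- min(apply(hydrogen_xyz, 1L, function(h) angle_deg(h - cen, v)))
  }
  structure(list(theta = theta, phi = phi, distance = d,
                 frame_index = as.integer(frame_index), label = NA_character_),
            class = "cation_pi_geometry")
}

#' @export
print.cation_pi_geometry <- function(x, ...) {
  cat(sprintf("<cation_pi_geometry> theta = %.2f deg, phi = %s, d = %.3f A%s\n",
              x$theta,
              if (is.na(x$phi)) "missing" else sprintf("%.2f deg", x$phi),
              x$distance,
              if (is.na(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Classify a cation-pi geometry as axial, lateral or none
#'
#' Applies the geometric window used to call an interaction: beyond `d_max`
#' there is no interaction; within range, a near-in-plane approach aimed at
#' a ring hydrogen (theta above `theta_lateral_min`, phi at most `phi_max`)
#' is *lateral*; a near-on-axis approach (theta at most `theta_axial_max`)
#' is *axial*; anything else is none. When phi is missing (no hydrogens in
#' the model) the lateral call uses theta and d only, with a warning.
#'
#' @param g a [cation_pi_geometry()], or a numeric theta (with `phi`, `d`
#'   supplied).
#' @param phi,d numeric, used when `g` is given as a bare theta.
#' @param d_max maximum centroid-cation distance, Angstrom (default 6.0).
#' @param phi_max maximum hydrogen-approach angle for a lateral call,
#'   degrees (default 30).
#' @param theta_lateral_min lateral window lower bound, degrees (default 60,
#'   the reported window being 60 < theta <= 90).
#' @param theta_axial_max axial window upper bound, degrees (default 30).
#' @return character label: `"axial"`, `"lateral"` or `"none"`.
#' @export
classify_cation_pi <- function(g, phi = NULL, d = NULL, d_max = 6.0,
                               phi_max = 30, theta_lateral_min = 60,
                               theta_axial_max = 30) {
  if (inherits(g, "cation_pi_geometry")) {
    theta <- g$theta; phi <- g$phi; d <- g$distance
  } else theta <- g
  stopifnot(d_max > 0, phi_max > 0, theta_lateral_min > 0,
            theta_axial_max > 0, theta_axial_max < theta_lateral_min)
  if (d > d_max) return("none")
  phi_ok <- if (is.na(phi)) {
    warning("phi missing (no ring hydrogens); lateral call uses theta and d only")
    TRUE
  } else phi <= phi_max
  if (theta > theta_lateral_min && theta <= 90 && phi_ok) return("lateral")
  if (theta <= theta_axial_max) return("axial")
  "none"
}

#' Scan a structure for cation-pi bridges
#'
#' Evaluates every cation against every listed aromatic ring and reports the
#' triples in which one cation simultaneously classifies (non-"none")
#' against two distinct rings — the double cation-pi "bridge" motif in which,
#' e.g., an arginine guanidinium locks two tryptophan side chains from the
#' side.
#'
#' @param model a [structure_model()].
#' @param cations list of cation references, each
#'   `list(chain=, residue_number=, atom = "CZ")` (for arginine, CZ
#'   approximates the guanidinium charge centroid; use
#'   `atom = c("NH1","NH2","NE")` to take the mean of those atoms instead).
#' @param rings list of [ring_spec()] objects.
#' @param d_max,phi_max,theta_lateral_min,theta_axial_max classification
#'   thresholds, see [classify_cation_pi()].
#' @return data.frame with one row per bridge: cation and ring identifiers
#'   plus (theta, phi, d, label) for each of the two contacts. Zero rows if
#'   no bridge is present.
#' @export
bridge_scan <- function(model, cations, rings, d_max = 6.0, phi_max = 30,
                        theta_lateral_min = 60, theta_axial_max = 30) {
  contacts_of <- function(cat_ref) {
    at <- select_atoms(model, cat_ref$chain, cat_ref$residue_number,
                       cat_ref$atom %||% "CZ")
    if (nrow(at) == 0L)
      stop(sprintf("selection error: cation %s:%d (%s) not found",
                   cat_ref$chain, cat_ref$residue_number,
                   paste(cat_ref$atom %||% "CZ", collapse = "/")))
    cat_pt <- colMeans(atom_xyz(at))
    lapply(rings, function(rs) {
      res <- resolve_ring(model, rs)
      g <- cation_pi_geometry(res$ring, cat_pt,
                              hydrogen_xyz = if (nrow(res$hydrogens)) res$hydrogens)
      g$label <- suppressWarnings(
        classify_cation_pi(g, d_max = d_max, phi_max = phi_max,
                           theta_lateral_min = theta_lateral_min,
                           theta_axial_max = theta_axial_max))
      g
    })
  }
  out <- list()
  for (cat_ref in cations) {
    geoms <- contacts_of(cat_ref)
    hit <- which(vapply(geoms, function(g) g$label != "none", logical(1)))
    if (length(hit) < 2L) next
    for (pair in utils::combn(hit, 2L, simplify = FALSE)) {
      i <- pair[1L]; j <- pair[2L]
      gi <- geoms[[i]]; gj <- geoms[[j]]
      out[[length(out) + 1L]] <- data.frame(
        cation = sprintf("%s:%d", cat_ref$chain, cat_ref$residue_number),
        ring_a = sprintf("%s:%d", rings[[i]]$chain, rings[[i]]$residue_number),
        ring_b = sprintf("%s:%d", rings[[j]]$chain, rings[[j]]$residue_number),
        theta_a = gi$theta, phi_a = gi$phi, d_a = gi$distance,
        label_a = gi$label,
        theta_b = gj$theta, phi_b = gj$phi, d_b = gj$distance,
        label_b = gj$label,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cation = character(0), ring_a = character(0),
                      ring_b = character(0), theta_a = numeric(0),
                      phi_a = numeric(0), d_a = numeric(0),
                      label_a = character(0), theta_b = numeric(0),
                      phi_b = numeric(0), d_b = numeric(0),
                      label_b = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
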