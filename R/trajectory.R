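#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimising the RMSD
#' of the fit selection of `mobile` onto `reference`, via SVD of the
#' cross-covariance matrix.
#'
#' @param mobile,reference `n x 3` coordinate matrices with matching atom
#'   ordering.
#' @param fit_selection integer atom indices used to compute the fit
#'   (default: all atoms). At least 3 non-collinear atoms.
#' @return list with `rotation` (3x3, applied on the right of centered
#'   coordinates), `translation`, `rmsd` (post-fit, over the fit selection)
#'   and `coords` (all mobile atoms transformed).
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  mobile <- as_xyz_matrix(mobile); reference <- as_xyz_matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference atom counts differ")
  sel <- fit_selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3L)
    stop("degenerate-fit error: need at least 3 fit atoms")
  mob_s <- mobile[sel, , drop = FALSE]
  ref_s <- reference[sel, , drop = FALSE]
  mc <- colMeans(mob_s); rc <- colMeans(ref_s)
  a <- sweep(mob_s, 2L, mc); b <- sweep(ref_s, 2L, rc)
  if (svd(a)$d[2L] < 1e-9 * max(svd(a)$d[1L], 1e-300))
    stop("degenerate-fit error: fit selection is collinear")
  h <- crossprod(a, b)
  s <- svd(h)
  d_sign <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d_sign)) %*% t(s$u)   # maps centered mobile rows
  fitted_sel <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted_sel - b)^2)))
  coords <- sweep(sweep(mobile, 2L, mc) %*% t(rot), 2L, rc, `+`)
  list(rotation = rot, translation = rc - as.numeric(mc %*% t(rot)),
       rmsd = rmsd, coords = coords)
}

mean_structure <- function(frames) {
  Reduce(`+`, frames) / length(frames)
}

#' Per-atom root-mean-square fluctuation
#'
#' Each frame is rigid-body superposed (on the selection) onto a reference,
#' and RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2) is computed about the
#' time-averaged position. With `ref = "mean"` (default) the reference is
#' the iteratively refined mean structure (two refinement passes: fit to the
#' first frame, average, re-fit to that average, re-average); `ref = "first"`
#' fits every frame to the first frame.
#'
#' @param traj a [trajectory_ensemble()] with at least 2 frames.
#' @param selection integer indices of the atoms to superpose on and report
#'   (canonically the C-alpha set); default all atoms.
#' @param ref `"mean"` or `"first"`.
#' @return list of class `rmsf_profile`: `residue_numbers`, `atom_names`,
#'   `rmsf` (Angstrom, one value per selected atom).
#' @export
rmsf <- function(traj, selection = NULL, ref = c("mean", "first")) {
  ref <- match.arg(ref)
  if (n_frames(traj) < 2L)
    stop("insufficient-frames error: RMSF needs at least 2 frames")
  sel <- selection %||% seq_len(nrow(traj$reference$atoms))
  sub <- lapply(traj$frames, function(f) f[sel, , drop = FALSE])
  target <- sub[[1L]]
  passes <- if (ref == "first") 1L else 3L   # 1 initial fit + 2 refinements
  fitted <- sub
  for (p in seq_len(passes)) {
    fitted <- lapply(sub, function(f) superpose(f, target)$coords)
    if (ref == "first" || p == passes) break
    target <- mean_structure(fitted)
  }
  avg <- mean_structure(fitted)
  sq <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - avg)^2))) /
    length(fitted)
  a <- traj$reference$atoms[sel, , drop = FALSE]
  structure(list(residue_numbers = a$residue_number,
                 atom_names = a$atom_name, rmsf = sqrt(sq)),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("<rmsf_profile> %d atoms, RMSF %.3f-%.3f A\n",
              length(x$rmsf), min(x$rmsf), max(x$rmsf)))
  invisible(x)
}

#' Point specification for distance series
#'
#' Names one geometric point per frame: a single named atom, an aromatic
#' ring centroid, or a residue-type-dependent side-chain reference point
#' (ring centroid for TRP/PHE/TYR, CZ for ARG, CA otherwise — the glycine
#' fallback keeps a wild-type G86 comparable with an R86 variant).
#'
#' @param chain chain identifier.
#' @param residue_number integer residue number.
#' @param type `"atom"`, `"ring"`, or `"sidechain"`.
#' @param atom atom name when `type = "atom"` (default `"CA"`).
#' @return object of class `point_spec`.
#' @export
point_spec <- function(chain, residue_number, type = c("atom", "ring",
                                                       "sidechain"),
                       atom = "CA") {
  type <- match.arg(type)
  structure(list(chain = chain, residue_number = as.integer(residue_number),
                 type = type, atom = atom), class = "point_spec")
}

resolve_point_indices <- function(model, spec) {
  describe <- sprintf("%s:%d:%s", spec$chain, spec$residue_number,
                      if (spec$type == "atom") spec$atom else spec$type)
  res <- select_atoms(model, spec$chain, spec$residue_number)
  if (nrow(res) == 0L)
    stop("selection error: no atoms for point spec ", describe)
  type <- spec$type
  if (type == "sidechain") {
    rn <- toupper(res$residue_name[1L])
    type <- if (rn %in% c("TRP", "PHE", "TYR", "BNZ")) "ring"
            else if (rn == "ARG") { spec$atom <- "CZ"; "atom" }
            else { spec$atom <- "CA"; "atom" }
  }
  names_wanted <- if (type == "ring") {
    rn <- toupper(res$residue_name[1L])
    ring_atom_names(rn)$ring_atom_names
  } else spec$atom
  idx <- which(model$atoms$chain_id == spec$chain &
                 model$atoms$residue_number == spec$residue_number &
                 model$atoms$atom_name %in% names_wanted)
  need <- if (type == "ring") 3L else 1L
  if (length(idx) < need)
    stop("selection error: cannot resolve point spec ", describe)
  idx
}

point_position <- function(coords, idx) {
  if (length(idx) == 1L) coords[idx, ] else colMeans(coords[idx, , drop = FALSE])
}

#' Inter-point distance time series
#'
#' Per-frame Euclidean distance (Angstrom) between two resolved points, with
#' running-average smoothing attached (see [running_stats()]).
#'
#' @param traj a [trajectory_ensemble()].
#' @param point_a,point_b [point_spec()] objects.
#' @param window smoothing window in frames (default 100; clamped to the
#'   series length).
#' @return list of class `distance_series`: `labels`, `times` (ps), `values`
#'   (Angstrom), `smoothed_mean`, `smoothed_sd`, `window`.
#' @export
distance_series <- function(traj, point_a, point_b, window = 100L) {
  ia <- resolve_point_indices(traj$reference, point_a)
  ib <- resolve_point_indices(traj$reference, point_b)
  vals <- vapply(traj$frames, function(f) {
    sqrt(sum((point_position(f, ia) - point_position(f, ib))^2))
  }, numeric(1))
  window <- min(as.integer(window), length(vals))
  rs <- running_stats(vals, window)
  structure(list(
    labels = c(sprintf("%s:%d:%s", point_a$chain, point_a$residue_number,
                       if (point_a$type == "atom") point_a$atom else point_a$type),
               sprintf("%s:%d:%s", point_b$chain, point_b$residue_number,
                       if (point_b$type == "atom") point_b$atom else point_b$type)),
    times = traj$times, values = vals,
    smoothed_mean = rs$means, smoothed_sd = rs$sds, window = window),
    class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s -- %s, %d frames, mean %.3f A (window %d)\n",
              x$labels[1L], x$labels[2L], length(x$values),
              mean(x$values), x$window))
  invisible(x)
}

#' Centered running mean and standard deviation
#'
#' Moving statistics over a centered window of `window` frames (for even
#' windows, `floor((w-1)/2)` frames before and `floor(w/2)` after the center).
#' Edges use the truncated window — all available points within the
#' half-window — rather than padding. The SD is the population SD, matching
#' a plain moving-moment computation.
#'
#' @param series numeric vector.
#' @param window integer >= 1, at most `length(series)`.
#' @return list with `means` and `sds`, each the length of `series`.
#' @export
running_stats <- function(series, window) {
  n <- length(series)
  window <- as.integer(window)
  if (window < 1L) stop("window error: window must be >= 1")
  if (window > n) stop("window error: window (", window,
                       ") exceeds series length (", n, ")")
  lo_off <- (window - 1L) %/% 2L
  hi_off <- window %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - lo_off)
  hi <- pmin(n, i + hi_off)
  cnt <- hi - lo + 1L
  cs <- cumsum(c(0, series))
  m <- (cs[hi + 1L] - cs[lo]) / cnt
  # two-pass SD about the window mean: exact agreement with a direct
  # windowed computation (a cumsum-of-squares shortcut cancels badly)
  v <- vapply(i, function(k)
    sum((series[lo[k]:hi[k]] - m[k])^2) / cnt[k], numeric(1))
  list(means = m, sds = sqrt(v))
}

#' Hinge-opening descriptor: the D168-R178 C-alpha distance
#'
#' The distance between the C-alpha atoms of residues 168 and 178 tracks the
#' "twisted accordion" conformational transition of the EF-hand sensor
#' between its signaling states; it shortens in the inhibitor state.
#' Returns the per-frame distance with 100-frame running statistics
#' (1 ns of smoothing at a 10 ps frame spacing).
#'
#' @param traj a [trajectory_ensemble()] containing residues 168 and 178
#'   with C-alpha atoms.
#' @param chain chain identifier (default `"A"`).
#' @param window smoothing window in frames (default 100).
#' @return a [distance_series()].
#' @export
twisted_accordion <- function(traj, chain = "A", window = 100L) {
  distance_series(traj,
                  point_spec(chain, 168L, "atom", "CA"),
                  point_spec(chain, 178L, "atom", "CA"),
                  window = window)
}
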