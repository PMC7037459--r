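#' @title Seeded synthetic-data generators
#' @description Every generator is a deterministic function of its arguments
#'   (including `seed`), and every generator has an analysis-side inverse or
#'   closed-form expectation: planted cation-pi geometries are recovered
#'   exactly by [cation_pi_geometry()], planted per-atom amplitudes equal
#'   the expected RMSF, planted binding/melt parameters are recovered by the
#'   fitters.
#' @name synthetic-data
NULL

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

RING_RADIUS <- 1.40   # Angstrom, aromatic C-C hexagon
H_RADIUS <- 2.48      # Angstrom, ring H distance from centroid

hexagon_xyz <- function(azimuths_deg, radius) {
  a <- azimuths_deg * pi / 180
  cbind(radius * cos(a), radius * sin(a), 0)
}

# Azimuth (deg, from the reference-H azimuth) of a cation at polar angle
# theta whose angle to the in-plane reference H is phi. Infeasible when
# |cos(phi)| > sin(theta): with an in-plane H, the attainable phi given
# theta is [90 - theta, 90 + theta].
cation_azimuth_offset <- function(theta, phi) {
  s <- sin(theta * pi / 180)
  c_phi <- cos(phi * pi / 180)
  if (s < 1e-12) {
    if (abs(phi - 90) > 1e-9)
      stop("infeasibility error: theta = 0 forces phi = 90 with in-plane hydrogens")
    return(0)
  }
  ratio <- c_phi / s
  if (abs(ratio) > 1 + 1e-9)
    stop(sprintf(paste0("infeasibility error: phi = %g unattainable at theta = %g ",
                        "(in-plane hydrogens allow phi in [%g, %g])"),
                 phi, theta, 90 - theta, 90 + theta))
  acos(min(1, max(-1, ratio))) * 180 / pi
}

#' Construct a ring + cation fixture with exact planted geometry
#'
#' Builds a benzene-like hexagonal ring (radius 1.40 Angstrom, plane z = 0,
#' centroid at the origin) with ring hydrogens at radius 2.48 Angstrom, and
#' places a cation pseudo-atom so that [cation_pi_geometry()] returns
#' exactly the planted (theta, phi, d) — the generator is the analytical
#' inverse of the analysis.
#'
#' Because ring hydrogens lie in the ring plane, a cation at polar angle
#' theta from the normal can form an angle phi with an in-plane hydrogen
#' direction only for phi in `[90 - theta, 90 + theta]`; outside that set
#' the construction raises an infeasibility error. With
#' `hydrogens = "full"` (all six H), the *reported* phi is the minimum over
#' hydrogens and equals the planted value only while the reference H stays
#' nearest (azimuth offset <= 30 degrees); `"single"` (default) keeps one
#' reference hydrogen and is exact over the whole feasible set.
#'
#' @param theta planted polar angle, degrees in \[0, 90\].
#' @param phi planted hydrogen-approach angle, degrees in \[0, 180\].
#' @param d planted centroid-cation distance, Angstrom, > 0.
#' @param hydrogens `"single"` or `"full"`.
#' @param chain,ring_residue_number,cation_residue_number identifiers for
#'   the emitted atoms (defaults chain A, ring 94, cation 86).
#' @return a [structure_model()] with ring atoms `C1..C6` (residue `BNZ`),
#'   hydrogens `H1` (or `H1..H6`) and a cation atom `CZ` (residue `ARG`).
#' @export
make_ring_cation <- function(theta, phi, d, hydrogens = c("single", "full"),
                             chain = "A", ring_residue_number = 94L,
                             cation_residue_number = 86L) {
  hydrogens <- match.arg(hydrogens)
  if (theta < 0 || theta > 90) stop("parameter error: theta must be in [0, 90]")
  if (phi < 0 || phi > 180) stop("parameter error: phi must be in [0, 180]")
  if (d <= 0) stop("parameter error: d must be > 0")
  psi <- cation_azimuth_offset(theta, phi)
  if (hydrogens == "full" && psi > 30 + 1e-9)
    warning("with full hydrogens the reported phi (minimum over H) will be ",
            "smaller than the planted value; use hydrogens = 'single'")
  az_c <- seq(0, 300, by = 60)
  ring <- hexagon_xyz(az_c, RING_RADIUS)
  h_az <- if (hydrogens == "full") az_c else 0
  hyd <- hexagon_xyz(h_az, H_RADIUS)
  th <- theta * pi / 180; ps <- psi * pi / 180
  cation <- d * c(sin(th) * cos(ps), sin(th) * sin(ps), cos(th))
  atoms <- data.frame(
    serial = seq_len(6L + nrow(hyd) + 1L),
    atom_name = c(paste0("C", 1:6), paste0("H", seq_along(h_az)), "CZ"),
    residue_name = c(rep("BNZ", 6L + nrow(hyd)), "ARG"),
    chain_id = chain,
    residue_number = c(rep(ring_residue_number, 6L + nrow(hyd)),
                       cation_residue_number),
    element = c(rep("C", 6L), rep("H", nrow(hyd)), "C"),
    x = c(ring[, 1L], hyd[, 1L], cation[1L]),
    y = c(ring[, 2L], hyd[, 2L], cation[2L]),
    z = c(ring[, 3L], hyd[, 3L], cation[3L]),
    stringsAsFactors = FALSE)
  structure_model(atoms)
}

# TRP-like six-ring in canonical frame: carbons at fixed azimuths, the four
# benzo hydrogens radially outward. The reference hydrogen for phi planting
# is HE3 at azimuth 60.
trp_ring_unit <- function(theta, phi, d, chain, resno) {
  psi <- cation_azimuth_offset(theta, phi)
  if (psi > 90 + 1e-9)
    stop("infeasibility error: planted phi > 90 degrees would not survive the ",
         "minimum over tryptophan ring hydrogens")
  az_c <- c(0, 60, 120, 180, 240, 300)
  c_names <- c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2")
  az_h <- c(60, 120, 180, 240)
  h_names <- c("HE3", "HZ3", "HH2", "HZ2")
  ring <- hexagon_xyz(az_c, RING_RADIUS)
  hyd <- hexagon_xyz(az_h, H_RADIUS)
  th <- theta * pi / 180
  ps <- (60 - psi) * pi / 180     # step from the reference H toward azimuth 0
  cation <- d * c(sin(th) * cos(ps), sin(th) * sin(ps), cos(th))
  atoms <- data.frame(
    serial = seq_len(10L),
    atom_name = c(c_names, h_names),
    residue_name = "TRP", chain_id = chain, residue_number = resno,
    element = c(rep("C", 6L), rep("H", 4L)),
    x = c(ring[, 1L], hyd[, 1L]), y = c(ring[, 2L], hyd[, 2L]),
    z = c(ring[, 3L], hyd[, 3L]),
    stringsAsFactors = FALSE)
  list(atoms = atoms, cation = cation)
}

apply_rigid <- function(xyz, rot, trans) {
  sweep(xyz %*% t(rot), 2L, trans, `+`)
}

#' Write a synthetic double cation-pi bridge fixture
#'
#' Emits a PDB file containing one arginine-like cation (CZ pseudo-atom,
#' residue 86) that simultaneously satisfies two planted cation-pi
#' geometries against two tryptophan-like rings (residues 21 and 94, placed
#' on opposite sides of the cation), plus optional non-interacting decoy
#' rings at least 12 Angstrom away. Residue numbering mirrors the
#' calcium-sensor motif (W21 / R86 / W94) so scans of the fixture read like
#' a real case.
#'
#' @param path output PDB path.
#' @param geom_a,geom_b planted geometries for rings 21 and 94, each a
#'   numeric `c(theta, phi, d)`.
#' @param decoys number of decoy phenylalanine-like rings (default 0).
#' @param seed integer seed controlling decoy placement (default 1).
#' @param chain chain identifier (default `"A"`).
#' @return the written [structure_model()], invisibly; the file at `path`
#'   is the primary product.
#' @export
make_bridge_pdb <- function(path, geom_a = c(85, 10, 4.0),
                            geom_b = c(85, 10, 4.0), decoys = 0L, seed = 1L,
                            chain = "A") {
  unit_a <- trp_ring_unit(geom_a[1L], geom_a[2L], geom_a[3L], chain, 21L)
  unit_b <- trp_ring_unit(geom_b[1L], geom_b[2L], geom_b[3L], chain, 94L)
  # flip unit B through the x-axis (y,z negated) and translate so its cation
  # lands on unit A's cation; the rings then sit on opposite sides
  rot <- diag(c(1, -1, -1))
  trans <- unit_a$cation - as.numeric(rot %*% unit_b$cation)
  b_xyz <- apply_rigid(atom_xyz(unit_b$atoms), rot, trans)
  unit_b$atoms[, c("x", "y", "z")] <- b_xyz
  min_sep <- min(as.matrix(stats::dist(rbind(atom_xyz(unit_a$atoms),
                                             b_xyz)))[seq_len(10L),
                                                      10L + seq_len(10L)])
  if (min_sep < 2.0)
    stop("infeasibility error: planted geometries place the two rings ",
         sprintf("%.2f", min_sep), " Angstrom apart (steric clash)")
  cat_atoms <- data.frame(
    serial = 1L, atom_name = "CZ", residue_name = "ARG", chain_id = chain,
    residue_number = 86L, element = "C",
    x = unit_a$cation[1L], y = unit_a$cation[2L], z = unit_a$cation[3L],
    stringsAsFactors = FALSE)
  decoy_atoms <- NULL
  if (decoys > 0L) {
    decoy_atoms <- with_seed(seed, {
      out <- vector("list", decoys)
      for (i in seq_len(decoys)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        center <- u * (15 + 3 * (i - 1))       # >= 12 A from everything
        ring <- sweep(hexagon_xyz(seq(0, 300, by = 60), RING_RADIUS),
                      2L, center, `+`)
        out[[i]] <- data.frame(
          serial = seq_len(6L),
          atom_name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
          residue_name = "PHE", chain_id = chain,
          residue_number = 200L + i, element = "C",
          x = ring[, 1L], y = ring[, 2L], z = ring[, 3L],
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
  }
  atoms <- rbind(unit_a$atoms, cat_atoms, unit_b$atoms, decoy_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms)
  write_pdb(model, path)
  invisible(model)
}

#' Ring specs and cation reference for a bridge fixture
#'
#' Convenience accessors matching [make_bridge_pdb()]'s numbering: rings at
#' residues 21 and 94 plus any decoy PHE residues, cation at residue 86.
#'
#' @param model a [structure_model()] read back from a bridge fixture.
#' @param chain chain identifier (default `"A"`).
#' @return list with `rings` (list of [ring_spec()]) and `cations`.
#' @export
bridge_fixture_specs <- function(model, chain = "A") {
  a <- model$atoms
  aro <- unique(a[a$residue_name %in% c("TRP", "PHE", "TYR"),
                  c("residue_number", "residue_name")])
  rings <- lapply(seq_len(nrow(aro)), function(i)
    ring_spec(chain, aro$residue_number[i], aro$residue_name[i]))
  list(rings = rings,
       cations = list(list(chain = chain, residue_number = 86L,
                           atom = "CZ")))
}

#' Generate a Gaussian-fluctuation trajectory with planted RMSF
#'
#' Frames are the base coordinates plus independent isotropic Gaussian
#' displacements with per-coordinate sigma = amplitude / sqrt(3), so the
#' expected RMSF of each atom equals its planted amplitude exactly.
#' Optionally, one atom's mean position jumps deterministically at a given
#' frame so that its distance to a partner atom switches between two planted
#' values (a two-state conformational switch).
#'
#' @param base a [structure_model()].
#' @param amplitudes planted per-atom RMSF amplitudes, Angstrom (recycled).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param times frame times in ps (default `0, 1, 2, ...`).
#' @param pair_switch optional
#'   `list(pair = c(i_fixed, i_moving), d1 =, d2 =, switch_frame =)`: the
#'   moving atom's mean position sits on the fixed-to-moving axis at
#'   distance `d1` up to `switch_frame` (inclusive) and `d2` after it.
#' @return a [trajectory_ensemble()].
#' @export
make_trajectory <- function(base, amplitudes, n_frames, seed = 1L,
                            times = seq_len(n_frames) - 1,
                            pair_switch = NULL) {
  n_at <- nrow(base$atoms)
  amplitudes <- rep_len(amplitudes, n_at)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  sigma <- amplitudes / sqrt(3)
  base_xyz <- atom_xyz(base$atoms)
  mean_pos <- function(frame_i) {
    m <- base_xyz
    if (!is.null(pair_switch)) {
      i_fix <- pair_switch$pair[1L]; i_mov <- pair_switch$pair[2L]
      axis <- base_xyz[i_mov, ] - base_xyz[i_fix, ]
      axis <- axis / sqrt(sum(axis^2))
      d_now <- if (frame_i <= pair_switch$switch_frame) pair_switch$d1
               else pair_switch$d2
      m[i_mov, ] <- base_xyz[i_fix, ] + axis * d_now
    }
    m
  }
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      noise <- matrix(rnorm(3L * n_at, sd = rep(sigma, 3L)), ncol = 3L)
      mean_pos(i) + noise
    })
  })
  trajectory_ensemble(base, frames, times = times)
}

#' Generate a noisy synthetic thermogram
#'
#' Forward-modelled injection heats ([predict_heats()]) plus iid Gaussian
#' noise; optionally a constant-dilution blank column and a CSV file.
#'
#' @param model an [itc_model()].
#' @param schedule an [itc_schedule()].
#' @param sigma_ucal Gaussian noise SD on each injection heat, microcalories.
#' @param seed integer seed.
#' @param blank_heat constant reference (no-protein) heat per injection,
#'   microcalories; included as a `blank_heats` field (and CSV column) and
#'   added to the observed heats, so that subtracting it recovers the
#'   binding signal (default `NULL`, no blank).
#' @param path optional CSV output path (columns `injection_index`,
#'   `injection_volume_uL`, `heat_ucal`\[, `blank_heat_ucal`\]).
#' @return a `thermogram` (see [predict_heats()]).
#' @export
make_itc <- function(model, schedule, sigma_ucal = 0, seed = 1L,
                     blank_heat = NULL, path = NULL) {
  stopifnot(sigma_ucal >= 0)
  tg <- predict_heats(model, schedule)
  noise <- with_seed(seed, rnorm(length(tg$heats), sd = sigma_ucal))
  tg$heats <- tg$heats + noise
  if (!is.null(blank_heat)) {
    tg$blank_heats <- rep(blank_heat, length(tg$heats))
    tg$heats <- tg$heats + tg$blank_heats
  }
  if (!is.null(path)) {
    d <- data.frame(injection_index = seq_along(tg$heats),
                    injection_volume_uL = schedule$injection_volumes * 1e6,
                    heat_ucal = tg$heats)
    if (!is.null(blank_heat)) d$blank_heat_ucal <- tg$blank_heats
    write.csv(d, path, row.names = FALSE)
  }
  tg
}

#' Generate a noisy synthetic melt curve
#'
#' Hill-sigmoid thermal denaturation profile plus iid Gaussian noise on the
#' standard 20-96 degrees C scan grid.
#'
#' @param tm planted melting temperature, degrees C.
#' @param h Hill exponent (default 25).
#' @param theta_folded,theta_unfolded baseline ellipticities, mdeg
#'   (defaults -20 and -5).
#' @param sigma_mdeg Gaussian noise SD, mdeg.
#' @param seed integer seed.
#' @param scan `c(from, to, step)` in degrees C (default `c(20, 96, 0.5)`).
#' @param path optional CSV output path (columns `temperature_C`,
#'   `ellipticity_mdeg`).
#' @return a [melt_curve()].
#' @export
make_melt <- function(tm, h = 25, theta_folded = -20, theta_unfolded = -5,
                      sigma_mdeg = 0, seed = 1L, scan = c(20, 96, 0.5),
                      path = NULL) {
  stopifnot(sigma_mdeg >= 0, tm > 0, h > 0)
  temp <- seq(scan[1L], scan[2L], by = scan[3L])
  y <- hill_theta(temp, theta_folded, theta_unfolded, tm, h)
  y <- y + with_seed(seed, rnorm(length(y), sd = sigma_mdeg))
  if (!is.null(path))
    write.csv(data.frame(temperature_C = temp, ellipticity_mdeg = y), path,
              row.names = FALSE)
  melt_curve(temp, y)
}

#' Generate a closed-form far-UV CD spectrum with planted 222/208 values
#'
#' Two-Gaussian negative-band alpha-helix-like shape whose amplitudes are
#' solved so that the ellipticity at exactly 208.0 and 222.0 nm equals the
#' planted values; [theta_ratio()] on the result returns
#' `theta222 / theta208` exactly (up to interpolation of the smooth shape).
#'
#' @param theta222,theta208 planted ellipticities, mdeg (e.g. -17.6 and
#'   -20 give the 0.88 ratio typical of an ion-free all-alpha sensor).
#' @param wavelengths sampling grid, nm (default 200-250 by 0.5).
#' @param widths Gaussian SDs of the 208 and 222 nm bands, nm (default
#'   c(9, 11)).
#' @return a [cd_spectrum()].
#' @export
make_cd_spectrum <- function(theta222, theta208,
                             wavelengths = seq(200, 250, by = 0.5),
                             widths = c(9, 11)) {
  g1 <- function(wl) exp(-(wl - 208)^2 / (2 * widths[1L]^2))
  g2 <- function(wl) exp(-(wl - 222)^2 / (2 * widths[2L]^2))
  amp <- solve(rbind(c(g1(208), g2(208)), c(g1(222), g2(222))),
               c(theta208, theta222))
  cd_spectrum(wavelengths, amp[1L] * g1(wavelengths) + amp[2L] * g2(wavelengths))
}

#' Generate a near-UV CD spectrum with a known baseline offset
#'
#' Flat-baseline near-UV shape (250-320 nm) with small aromatic bands below
#' 300 nm plus a constant offset; the 310-320 nm band carries only the
#' offset, so [normalize_near_uv()] removes it exactly.
#'
#' @param offset constant baseline offset, mdeg.
#' @param scale amplitude of the aromatic bands, mdeg (default 1).
#' @param wavelengths sampling grid, nm (default 250-320 by 0.5).
#' @return a [cd_spectrum()].
#' @export
make_near_uv_spectrum <- function(offset = 0, scale = 1,
                                  wavelengths = seq(250, 320, by = 0.5)) {
  bands <- scale * (0.6 * exp(-(wavelengths - 262)^2 / (2 * 4^2)) -
                    0.8 * exp(-(wavelengths - 283)^2 / (2 * 4^2)) +
                    0.5 * exp(-(wavelengths - 291)^2 / (2 * 3^2)))
  cd_spectrum(wavelengths, bands + offset)
}
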