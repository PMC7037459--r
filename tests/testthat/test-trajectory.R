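random_coords <- function(n) cbind(runif(n, -10, 10), runif(n, -10, 10),
                                   runif(n, -10, 10))

test_that("superposition recovers exact rigid motions and matches the quaternion oracle", {
  set.seed(51)
  ref <- random_coords(12)
  same <- superpose(ref, ref)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$coords, ref, tolerance = 1e-12)

  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mobile <- sweep(ref %*% t(rz), 2, c(5, -2, 7), `+`)
  fit <- superpose(mobile, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$coords, ref, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # noisy copy: RMSD agrees with an independent quaternion-based solution
  for (rep in 1:5) {
    noisy <- sweep(ref %*% t(random_rotation()), 2, runif(3, -5, 5), `+`) +
      matrix(rnorm(36, sd = 0.1), 12, 3)
    expect_equal(superpose(noisy, ref)$rmsd,
                 quaternion_superpose_rmsd(noisy, ref), tolerance = 1e-8)
  }
  expect_error(superpose(cbind(1:5, 1:5, 1:5), random_coords(5)),
               "degenerate-fit")
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "degenerate-fit")
})

make_ca_chain <- function(n) {
  set.seed(61)
  structure_model(data.frame(
    serial = seq_len(n), atom_name = "CA", residue_name = "ALA",
    chain_id = "A", residue_number = seq_len(n), element = "C",
    x = cumsum(runif(n, 2, 4)), y = runif(n, -5, 5), z = runif(n, -5, 5),
    stringsAsFactors = FALSE))
}

test_that("RMSF vanishes for static and rigidly moving trajectories", {
  base <- make_ca_chain(10)
  static <- make_trajectory(base, amplitudes = 0, n_frames = 5, seed = 1)
  expect_true(all(rmsf(static)$rmsf < 1e-12))

  set.seed(71)
  frames <- lapply(1:6, function(i)
    sweep(atom_xyz(base$atoms) %*% t(random_rotation()), 2,
          runif(3, -10, 10), `+`))
  rigid <- trajectory_ensemble(base, frames)
  expect_true(all(rmsf(rigid)$rmsf <= 1e-8))
  expect_true(all(rmsf(rigid, ref = "first")$rmsf <= 1e-8))
  expect_error(rmsf(trajectory_ensemble(base, frames[1])),
               "insufficient-frames")
})

test_that("RMSF is invariant under per-frame rigid motion of the whole system", {
  base <- make_ca_chain(8)
  traj <- make_trajectory(base, amplitudes = 0.4, n_frames = 60, seed = 5)
  r0 <- rmsf(traj)$rmsf
  set.seed(81)
  moved <- trajectory_ensemble(base, lapply(traj$frames, function(f)
    sweep(f %*% t(random_rotation()), 2, runif(3, -30, 30), `+`)))
  expect_equal(rmsf(moved)$rmsf, r0, tolerance = 1e-8)
})

test_that("recovered RMSF preserves the planted amplitude rank order", {
  n <- 40
  base <- make_ca_chain(n)
  set.seed(91)
  amplitudes <- runif(n, 0.1, 1.2)
  traj <- make_trajectory(base, amplitudes, n_frames = 2000, seed = 9)
  prof <- rmsf(traj)
  expect_gt(cor(prof$rmsf, amplitudes, method = "spearman"), 0.95)
})

test_that("distance series reproduce fixed and planted distances", {
  base <- two_atom_model(d = 5)
  static <- make_trajectory(base, amplitudes = 0, n_frames = 10, seed = 1)
  ds <- distance_series(static, point_spec("A", 168), point_spec("A", 178),
                        window = 3)
  expect_equal(ds$values, rep(5, 10))
  expect_equal(ds$smoothed_mean, rep(5, 10))
  expect_equal(ds$smoothed_sd, rep(0, 10))

  # moving point: distances 3, 4, 5
  frames <- lapply(c(3, 4, 5), function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  mv <- trajectory_ensemble(base, frames)
  expect_equal(distance_series(mv, point_spec("A", 168),
                               point_spec("A", 178), window = 1)$values,
               c(3, 4, 5))

  # symmetry in the two endpoints
  expect_equal(distance_series(mv, point_spec("A", 178),
                               point_spec("A", 168), window = 1)$values,
               c(3, 4, 5))
  expect_error(distance_series(static, point_spec("A", 168),
                               point_spec("B", 178)), "selection error")
})

test_that("ring-centroid distance on a bridge fixture equals the planted d", {
  path <- withr::local_tempfile(fileext = ".pdb")
  # the in-memory model is exact; the PDB file itself is quantised to 1e-3 A
  m <- make_bridge_pdb(path, geom_a = c(85, 10, 4.2), geom_b = c(85, 10, 5.1))
  m_file <- read_pdb(path)
  expect_true(max(abs(atom_xyz(m_file$atoms) - atom_xyz(m$atoms))) <= 1e-3)
  traj <- trajectory_ensemble(m, list(atom_xyz(m$atoms),
                                      atom_xyz(m$atoms) + 0), times = 0:1)
  d21 <- distance_series(traj, point_spec("A", 21, "ring"),
                         point_spec("A", 86, "atom", "CZ"), window = 1)
  expect_equal(d21$values, rep(4.2, 2), tolerance = 1e-6)
  d94 <- distance_series(traj, point_spec("A", 94, "sidechain"),
                         point_spec("A", 86, "sidechain"), window = 1)
  expect_equal(d94$values, rep(5.1, 2), tolerance = 1e-6)
})

test_that("running stats match brute-force windowed statistics everywhere", {
  expect_equal(running_stats(rep(3.5, 20), 7),
               list(means = rep(3.5, 20), sds = rep(0, 20)))
  x <- c(2, 9, 4, 4, 8, 1)
  expect_equal(running_stats(x, 1), list(means = x, sds = rep(0, 6)))
  set.seed(101)
  for (n in c(5, 50, 500)) {
    series <- rnorm(n)
    for (w in unique(c(1, 2, 3, 10, n %/% 2, n))) {
      if (w < 1 || w > n) next
      got <- running_stats(series, w)
      want <- brute_running_stats(series, w)
      expect_equal(got$means, want$means, tolerance = 1e-12)
      expect_equal(got$sds, want$sds, tolerance = 1e-10)
    }
  }
  ramp <- as.numeric(1:200)
  expect_equal(running_stats(ramp, 100)$means[100], mean(ramp[51:150]))
  expect_error(running_stats(1:5, 6), "window")
  expect_error(running_stats(1:5, 0), "window")
})

test_that("the hinge descriptor detects a planted two-state switch", {
  base <- two_atom_model(d = 12)
  traj <- make_trajectory(base, amplitudes = 0.3, n_frames = 300, seed = 13,
                          pair_switch = list(pair = c(1L, 2L), d1 = 12,
                                             d2 = 8, switch_frame = 150L))
  ds <- twisted_accordion(traj)
  expect_equal(ds$window, 100)
  crossing <- which(ds$smoothed_mean < 10)[1]
  expect_gt(crossing, 151 - 50)
  expect_lt(crossing, 151 + 50)
  expect_equal(mean(ds$values[1:140]), 12, tolerance = 0.1)
  expect_equal(mean(ds$values[160:300]), 8, tolerance = 0.1)

  static <- make_trajectory(two_atom_model(d = 9), amplitudes = 0,
                            n_frames = 120, seed = 1)
  expect_equal(twisted_accordion(static)$smoothed_mean, rep(9, 120))

  renumbered <- two_atom_model(d = 9, res_b = 179L)
  tr <- make_trajectory(renumbered, amplitudes = 0, n_frames = 5, seed = 1)
  expect_error(twisted_accordion(tr), "selection error")
})
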