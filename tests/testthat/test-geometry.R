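hexagon <- function(radius = 1.4, center = c(0, 0, 0)) {
  a <- seq(0, 300, by = 60) * pi / 180
  sweep(cbind(radius * cos(a), radius * sin(a), 0), 2L, center, `+`)
}

test_that("ring centroid is the coordinate-wise mean", {
  expect_equal(ring_centroid(hexagon()), c(0, 0, 0))
  expect_equal(ring_centroid(hexagon(center = c(1, 2, 3))), c(1, 2, 3))
  set.seed(11)
  pent <- cbind(runif(5, -3, 3), runif(5, -3, 3), 0.2)
  expect_equal(ring_centroid(pent),
               c(mean(pent[, 1]), mean(pent[, 2]), mean(pent[, 3])))
  expect_error(ring_centroid(pent[1:2, ]), "degenerate-ring")
})

test_that("plane normal is the least-orthogonal-variance direction with sign rule", {
  expect_equal(ring_plane_normal(hexagon()), c(0, 0, 1))
  # rotation about x by 30 degrees: normal must co-rotate (up to sign rule)
  rx <- matrix(c(1, 0, 0,
                 0, cos(pi / 6), -sin(pi / 6),
                 0, sin(pi / 6), cos(pi / 6)), 3, 3, byrow = TRUE)
  n <- ring_plane_normal(hexagon() %*% t(rx))
  expect_equal(n, c(0, -sin(pi / 6), cos(pi / 6)), tolerance = 1e-12)
  expect_true(n[3] >= 0)
  # noisy ring: normal within 5 degrees of z, matching a coarse grid search
  set.seed(21)
  noisy <- hexagon()
  noisy[, 3] <- rnorm(6, sd = 0.05)
  n2 <- ring_plane_normal(noisy)
  expect_lt(acos(abs(n2[3])) * 180 / pi, 5)
  # grid-search oracle: direction minimising orthogonal variance
  grid <- expand.grid(th = seq(0, 20, by = 0.25) * pi / 180,
                      ph = seq(0, 359, by = 1) * pi / 180)
  dirs <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
                cos(grid$th))
  centered <- sweep(noisy, 2L, colMeans(noisy))
  ssq <- rowSums((dirs %*% t(centered))^2)
  best <- dirs[which.min(ssq), ]
  expect_lt(angle_between <- acos(abs(sum(best * n2))) * 180 / pi, 0.5)
  expect_error(ring_plane_normal(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

test_that("axial, lateral and oblique cation geometries are computed exactly", {
  ring <- hexagon()
  h_in_plane <- matrix(c(2.4, 0, 0), 1, 3)
  ax <- cation_pi_geometry(ring, c(0, 0, 4), h_in_plane)
  expect_equal(ax$distance, 4)
  expect_equal(ax$theta, 0)
  expect_equal(ax$phi, 90)
  lat <- cation_pi_geometry(ring, c(4, 0, 0), h_in_plane)
  expect_equal(lat$theta, 90)
  expect_equal(lat$phi, 0)
  expect_equal(lat$distance, 4)
  ob <- cation_pi_geometry(ring, c(2, 0, 2), h_in_plane)
  expect_equal(ob$distance, 2 * sqrt(2))
  expect_equal(ob$theta, 45)
  expect_equal(ob$phi,
               three_point_angle(c(2, 0, 2), c(0, 0, 0), c(2.4, 0, 0)))
  # phi is a minimum over hydrogens
  h2 <- rbind(h_in_plane, c(0, 2.4, 0))
  expect_equal(cation_pi_geometry(ring, c(2, 0, 2), h2)$phi, ob$phi)
  # missing hydrogens -> phi NA
  expect_true(is.na(cation_pi_geometry(ring, c(2, 0, 2))$phi))
  expect_error(cation_pi_geometry(ring, c(0, 0, 0)), "coincident")
  # complementary convention
  expect_equal(cation_pi_geometry(ring, c(2, 0, 2), theta_from_plane = TRUE)$theta,
               45)
  expect_equal(cation_pi_geometry(ring, c(4, 0, 0), theta_from_plane = TRUE)$theta,
               0)
})

test_that("geometry descriptors are invariant under joint rigid motion", {
  set.seed(31)
  for (rep in 1:20) {
    theta <- runif(1, 5, 90)
    phi <- runif(1, 90 - theta + 1, 90 + theta - 1)
    d <- runif(1, 2, 8)
    m <- make_ring_cation(theta, phi, d)
    ring <- atom_xyz(select_atoms(m, "A", 94, paste0("C", 1:6)))
    h <- atom_xyz(select_atoms(m, "A", 94, "H1"))
    cat_pt <- unlist(select_atoms(m, "A", 86, "CZ")[, c("x", "y", "z")])
    rot <- random_rotation()
    trans <- runif(3, -20, 20)
    g0 <- cation_pi_geometry(ring, cat_pt, h)
    g1 <- cation_pi_geometry(sweep(ring %*% t(rot), 2, trans, `+`),
                             as.numeric(rot %*% cat_pt) + trans,
                             sweep(h %*% t(rot), 2, trans, `+`))
    expect_equal(g1$theta, g0$theta, tolerance = 1e-9)
    expect_equal(g1$phi, g0$phi, tolerance = 1e-9)
    expect_equal(g1$distance, g0$distance, tolerance = 1e-9)
  }
})

test_that("theta is unchanged when the plane normal flips sign", {
  ring <- hexagon()
  v <- c(1.5, 0.5, 3)
  theta_from <- function(nrm) {
    ang <- acos(sum(nrm * v) / sqrt(sum(nrm^2) * sum(v^2))) * 180 / pi
    if (ang > 90) 180 - ang else ang
  }
  expect_equal(theta_from(c(0, 0, 1)), theta_from(c(0, 0, -1)))
  g <- cation_pi_geometry(ring, v)
  expect_equal(g$theta, theta_from(c(0, 0, 1)), tolerance = 1e-12)
})

test_that("classification honours the lateral window, distance gate and axial branch", {
  expect_equal(classify_cation_pi(75, 5, 4.5), "lateral")
  expect_equal(classify_cation_pi(75, 5, 12), "none")
  expect_equal(classify_cation_pi(10, 85, 4), "axial")
  expect_equal(classify_cation_pi(45, 5, 4), "none")      # between windows
  expect_equal(classify_cation_pi(75, 60, 4), "none")     # phi too large
  expect_equal(classify_cation_pi(90, 30, 6), "lateral")  # boundary inclusive
  expect_equal(classify_cation_pi(60, 5, 4), "none")      # theta > 60 strict
  expect_warning(lab <- classify_cation_pi(75, NA, 4), "phi missing")
  expect_equal(lab, "lateral")
  expect_error(classify_cation_pi(75, 5, 4, theta_axial_max = 70))
})

test_that("classification is monotone in d: shrinking d never loses a call", {
  set.seed(41)
  for (rep in 1:200) {
    theta <- runif(1, 0, 90); phi <- runif(1, 0, 180); d <- runif(1, 0.5, 12)
    lab <- classify_cation_pi(theta, phi, d)
    if (lab != "none")
      expect_equal(classify_cation_pi(theta, phi, d * runif(1, 0.05, 1)), lab)
  }
})

test_that("bridge_scan finds planted bridges and only planted bridges", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_bridge_pdb(path, geom_a = c(85, 10, 4.0), geom_b = c(80, 15, 4.5))
  m <- read_pdb(path)
  specs <- bridge_fixture_specs(m)
  hits <- bridge_scan(m, specs$cations, specs$rings)
  expect_equal(nrow(hits), 1)
  expect_setequal(c(hits$ring_a, hits$ring_b), c("A:21", "A:94"))
  expect_equal(hits$label_a, "lateral")
  expect_equal(hits$label_b, "lateral")
  # the scan ran on the file-backed model: PDB precision is 1e-3 A
  expect_equal(sort(c(hits$d_a, hits$d_b)), c(4.0, 4.5), tolerance = 1e-3)

  # decoys do not create extra bridges
  make_bridge_pdb(path, geom_a = c(85, 10, 4.0), geom_b = c(80, 15, 4.5),
                  decoys = 5, seed = 3)
  m5 <- read_pdb(path)
  specs5 <- bridge_fixture_specs(m5)
  expect_equal(length(specs5$rings), 7)
  expect_equal(nrow(bridge_scan(m5, specs5$cations, specs5$rings)), 1)

  # displaced second ring -> no bridge
  make_bridge_pdb(path, geom_a = c(85, 10, 4.0), geom_b = c(80, 15, 15))
  mfar <- read_pdb(path)
  specsf <- bridge_fixture_specs(mfar)
  expect_equal(nrow(bridge_scan(mfar, specsf$cations, specsf$rings)), 0)

  # mixed lateral + axial contact still bridges, with mixed labels
  make_bridge_pdb(path, geom_a = c(85, 10, 4.0), geom_b = c(10, 85, 4.0))
  mmix <- read_pdb(path)
  specsm <- bridge_fixture_specs(mmix)
  mix <- bridge_scan(mmix, specsm$cations, specsm$rings)
  expect_equal(nrow(mix), 1)
  expect_setequal(c(mix$label_a, mix$label_b), c("lateral", "axial"))
})
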