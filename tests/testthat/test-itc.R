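# scalar high-precision root by uniroot, independent of the package solver
one_site_free_root_multi <- function(xt, mt, kd) {
  f <- function(x) x + mt * sum(x / (kd + x)) - xt
  uniroot(function(x) vapply(x, f, numeric(1)), c(0, xt),
          tol = 1e-18)$root
}

test_that("free-ligand solver matches limits and the one-site closed form", {
  m <- itc_model(1e-6, -4)
  expect_equal(solve_free_ligand(10e-6, 0, m), 10e-6)
  expect_equal(solve_free_ligand(0, 20e-6, m), 0)
  expect_equal(solve_free_ligand(10e-6, 20e-6, m),
               one_site_free_ligand(10e-6, 20e-6, 1e-6), tolerance = 1e-10)
  set.seed(111)
  for (rep in 1:50) {
    kd <- 10^runif(1, -9, -3)
    xt <- 10^runif(1, -7, -3); mt <- 10^runif(1, -6, -4)
    expect_equal(solve_free_ligand(xt, mt, itc_model(kd, 1)),
                 one_site_free_ligand(xt, mt, kd), tolerance = 1e-9)
  }
})

test_that("mass balance is conserved to 1e-10 relative at the returned root", {
  set.seed(121)
  for (rep in 1:50) {
    n_cls <- sample(1:3, 1)
    m <- itc_model(10^runif(n_cls, -9, -3), runif(n_cls, -10, 10))
    xt <- 10^runif(20, -8, -3)
    mt <- 10^runif(1, -6, -4)
    x <- solve_free_ligand(xt, mt, m)
    bound <- rowSums(vapply(m$kd, function(k) x / (k + x),
                            numeric(length(x))))
    expect_true(all(abs(x + mt * bound - xt) <= 1e-10 * xt))
    expect_true(all(x >= 0 & x <= xt))
  }
})

test_that("predicted heats honour zero-enthalpy, saturation and permutation invariance", {
  sch <- itc_schedule()
  zero <- predict_heats(itc_model(c(1e-8, 1e-6), c(0, 0)), sch)
  expect_equal(zero$heats, rep(0, 55))

  one <- predict_heats(itc_model(1e-7, -5), sch)
  expect_lt(abs(one$heats[55]), 0.01 * abs(one$heats[1]))

  m123 <- itc_model(c(16.3e-9, 36e-9, 0.25e-6), c(-4.2, -5, 1.2))
  perm <- itc_model(c(0.25e-6, 16.3e-9, 36e-9), c(1.2, -4.2, -5))
  expect_equal(predict_heats(m123, sch)$heats, predict_heats(perm, sch)$heats)
})

test_that("per-injection heats equal differenced cumulative heats plus displaced-volume term", {
  sch <- itc_schedule(injection_volumes = rep(5e-6, 30))
  m <- table1_wt_ca()
  tg <- predict_heats(m, sch)
  # independent recomputation: sequential dilution, then cumulative Q
  v0 <- sch$cell_volume
  mt <- numeric(30); xt <- numeric(30)
  mp <- sch$cell_concentration; xp <- 0
  for (i in 1:30) {
    f <- 1 - 5e-6 / v0
    mt[i] <- mp * f
    xt[i] <- xp * f + sch$syringe_concentration * 5e-6 / v0
    mp <- mt[i]; xp <- xt[i]
  }
  q <- vapply(1:30, function(i) {
    x <- one_site_free_root_multi(xt[i], mt[i], m$kd)
    v0 * mt[i] * sum(m$dh * x / (m$kd + x)) * 1e9
  }, numeric(1))
  dq <- q - c(0, q[-30]) + (5e-6 / v0) * (q + c(0, q[-30])) / 2
  expect_equal(tg$heats, dq, tolerance = 1e-9)
})

test_that("noiseless thermograms are recovered to within 0.5 percent", {
  m <- table1_wt_ca()
  sch <- itc_schedule()
  fit <- fit_itc(predict_heats(m, sch), n_classes = 3, n_starts = 8,
                 seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$model$kd, m$kd, tolerance = 5e-3)
  expect_equal(fit$model$dh, m$dh, tolerance = 5e-3)
})

test_that("over-parameterised fits are flagged as unidentifiable", {
  one_site <- itc_model(1e-6, -5)
  sch <- itc_schedule()
  tg <- make_itc(one_site, sch, sigma_ucal = 0.01, seed = 3)
  fit <- fit_itc(tg, n_classes = 2, n_starts = 16, seed = 3)
  expect_true(fit$unidentifiable)
})

test_that("recovery error grows with noise", {
  m <- itc_model(1e-6, -5)
  sch <- itc_schedule()
  sigmas <- c(0, 0.05, 0.1, 0.5)
  med_err <- vapply(sigmas, function(s) {
    errs <- vapply(1:20, function(seed) {
      tg <- make_itc(m, sch, sigma_ucal = s, seed = seed)
      fit <- fit_itc(tg, n_classes = 1, n_starts = 6, seed = seed)
      abs(log10(fit$model$kd) - log10(m$kd))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) >= -1e-12))
})

test_that("apparent KD is the geometric mean, idempotent and scale-equivariant", {
  expect_equal(kd_apparent(c(2e-9, 2e-9, 2e-9)), 2e-9)
  expect_equal(kd_apparent(c(16.3e-9, 36e-9, 0.25e-6)),
               (16.3e-9 * 36e-9 * 0.25e-6)^(1 / 3))
  set.seed(131)
  kd <- 10^runif(3, -9, -4)
  expect_equal(kd_apparent(7 * kd), 7 * kd_apparent(kd), tolerance = 1e-12)
  expect_equal(kd_apparent(itc_model(kd, c(1, 2, 3))), kd_apparent(kd))
})

test_that("ITC CSV round trip preserves heats and applies the blank", {
  m <- itc_model(c(5e-7, 1e-5), c(-6, 3))
  sch <- itc_schedule(syringe_concentration = 2e-3,
                      injection_volumes = rep(5e-6, 25))
  path <- withr::local_tempfile(fileext = ".csv")
  tg <- make_itc(m, sch, sigma_ucal = 0.05, seed = 17, blank_heat = -0.4,
                 path = path)
  back <- read_itc_csv(path, syringe_concentration = 2e-3)
  expect_equal(back$heats, tg$heats)
  expect_equal(back$blank_heats, rep(-0.4, 25))
  fit <- fit_itc(back, n_classes = 2, n_starts = 8, seed = 17)
  expect_equal(fit$model$kd, m$kd, tolerance = 0.25)
})
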