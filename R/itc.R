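#' ITC titration schedule
#'
#' Instrument and sample parameters for a sequential-injection isothermal
#' titration calorimetry experiment on a perfusion (overflow) cell: each
#' injection displaces its own volume of cell content.
#'
#' @param cell_concentration protein concentration in the cell, molar
#'   (default 20e-6 M).
#' @param syringe_concentration titrant concentration in the syringe, molar
#'   (e.g. 0.5e-3 M CaCl2 or 10e-3 M MgCl2).
#' @param injection_volumes vector of injection volumes in litres (default
#'   55 injections of 5e-6 L).
#' @param cell_volume active cell volume in litres (default 1.4e-3 L,
#'   VP-ITC class instrument).
#' @param temperature cell temperature, degrees C (default 25).
#' @return object of class `itc_schedule`.
#' @export
itc_schedule <- function(cell_concentration = 20e-6,
                         syringe_concentration = 0.5e-3,
                         injection_volumes = rep(5e-6, 55L),
                         cell_volume = 1.4e-3,
                         temperature = 25) {
  stopifnot(cell_concentration > 0, syringe_concentration > 0,
            cell_volume > 0, length(injection_volumes) > 0,
            all(injection_volumes > 0))
  structure(list(cell_concentration = cell_concentration,
                 syringe_concentration = syringe_concentration,
                 injection_volumes = injection_volumes,
                 cell_volume = cell_volume,
                 temperature = temperature),
            class = "itc_schedule")
}

#' Independent-site-class ITC binding model
#'
#' Per-site-class dissociation constants and binding enthalpies under the
#' independent-sites assumption, one site of each class per protein (the
#' three functional EF-hands of the calcium sensor motivate the 3-class
#' calcium model; magnesium titrations use 2 classes). Classes are stored
#' sorted ascending by K_D (canonical order).
#'
#' @param kd numeric vector of dissociation constants, molar.
#' @param dh numeric vector of binding enthalpies, kcal/mol, same length.
#' @return object of class `itc_model`.
#' @export
itc_model <- function(kd, dh) {
  stopifnot(length(kd) == length(dh), all(kd > 0), all(is.finite(dh)))
  ord <- order(kd)
  structure(list(kd = as.numeric(kd[ord]), dh = as.numeric(dh[ord]),
                 n_classes = length(kd)),
            class = "itc_model")
}

#' @export
print.itc_model <- function(x, ...) {
  cat(sprintf("<itc_model> %d site classes\n", x$n_classes))
  for (i in seq_len(x$n_classes))
    cat(sprintf("  site %d: K_D = %s, dH = %.2f kcal/mol\n",
                i, format_kd(x$kd[i]), x$dh[i]))
  invisible(x)
}

format_kd <- function(kd) {
  if (kd < 1e-6) sprintf("%.1f nM", kd * 1e9) else sprintf("%.2f uM", kd * 1e6)
}

#' Free-ligand concentration under independent-site mass balance
#'
#' Solves X_total = X + M_total * sum_i X / (K_Di + X) for the free ligand
#' concentration X. The left side minus the right is strictly monotone in X,
#' so the root in \[0, X_total\] is unique; it is bracketed by bisection and
#' polished by Newton steps to 1e-12 relative tolerance. Vectorised over
#' titration points.
#'
#' @param x_total total ligand concentration(s), molar (vector ok).
#' @param m_total total protein concentration(s), molar (scalar or vector).
#' @param model an [itc_model()] (or numeric vector of K_Ds).
#' @return free ligand concentration(s), molar.
#' @export
solve_free_ligand <- function(x_total, m_total, model) {
  kd <- if (inherits(model, "itc_model")) model$kd else as.numeric(model)
  stopifnot(all(x_total >= 0), all(m_total >= 0))
  n <- max(length(x_total), length(m_total))
  x_total <- rep_len(x_total, n); m_total <- rep_len(m_total, n)
  bound_frac <- function(x) {   # sum_i x/(kd_i + x), vectorised over x
    s <- 0
    for (k in kd) s <- s + x / (k + x)
    s
  }
  f <- function(x) x + m_total * bound_frac(x) - x_total
  lo <- rep(0, n); hi <- x_total
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    hi[pos] <- mid[pos]; lo[!pos] <- mid[!pos]
  }
  x <- (lo + hi) / 2
  # Newton polish; derivative of f is 1 + m_total * sum_i kd_i/(kd_i + x)^2
  for (it in 1:4) {
    dfdx <- 1
    for (k in kd) dfdx <- dfdx + m_total * k / (k + x)^2
    step <- f(x) / dfdx
    x <- pmin(pmax(x - step, 0), x_total)
  }
  x
}

dilution_schedule <- function(schedule) {
  v0 <- schedule$cell_volume
  dv <- schedule$injection_volumes
  k <- length(dv)
  m <- numeric(k); x <- numeric(k)
  m_prev <- schedule$cell_concentration; x_prev <- 0
  for (i in seq_len(k)) {
    f <- 1 - dv[i] / v0
    m[i] <- m_prev * f
    x[i] <- x_prev * f + schedule$syringe_concentration * dv[i] / v0
    m_prev <- m[i]; x_prev <- x[i]
  }
  list(m_total = m, x_total = x)
}

KCAL_TO_UCAL <- 1e9

#' Forward model of injection heats
#'
#' Predicts the reference-subtracted heat of each injection from an
#' independent-site-class model and a titration schedule. The cumulative
#' heat after injection k is `Q_k = V0 * M_k * sum_i dH_i * X / (K_Di + X)`
#' evaluated at the post-injection cell concentrations (sequential perfusion
#' dilution), and the observed per-injection heat includes the
#' displaced-volume correction
#' `dQ_k = Q_k - Q_{k-1} + (dV_k / V0) * (Q_k + Q_{k-1}) / 2`.
#'
#' @param model an [itc_model()].
#' @param schedule an [itc_schedule()].
#' @return list of class `thermogram`: `heats` (microcalories per
#'   injection), `x_total`, `m_total` (post-injection molar concentrations
#'   in the cell), `schedule`.
#' @export
predict_heats <- function(model, schedule) {
  dil <- dilution_schedule(schedule)
  x_free <- solve_free_ligand(dil$x_total, dil$m_total, model)
  v0 <- schedule$cell_volume
  q <- numeric(length(x_free))
  for (i in seq_along(model$kd))
    q <- q + model$dh[i] * x_free / (model$kd[i] + x_free)
  q <- v0 * dil$m_total * q * KCAL_TO_UCAL      # cumulative, ucal
  q_prev <- c(0, q[-length(q)])
  dv <- schedule$injection_volumes
  heats <- q - q_prev + (dv / v0) * (q + q_prev) / 2
  structure(list(heats = heats, x_total = dil$x_total,
                 m_total = dil$m_total, schedule = schedule),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d injections, heats %.2f..%.2f ucal\n",
              length(x$heats), min(x$heats), max(x$heats)))
  invisible(x)
}

#' Fit an independent-site-class model to a thermogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the per-injection heats,
#' parameterised as (log10 K_D, dH) per class to keep K_D positive and
#' multi-start label switching under control. `n_starts` seeded random
#' starts (K_D log-uniform in \[1e-9, 1e-2\] M, dH uniform in \[-20, 25\]
#' kcal/mol) are run and the best objective wins; classes are returned
#' sorted ascending by K_D. Parameter uncertainties come from the local
#' quadratic approximation at the optimum.
#'
#' @param thermogram a `thermogram` (from [predict_heats()], [make_itc()]
#'   or [read_itc_csv()]); its `heats` may include noise. If a
#'   `blank_heats` field is present it is subtracted first.
#' @param schedule an [itc_schedule()]; defaults to the one carried by the
#'   thermogram.
#' @param n_classes number of site classes (2 or 3).
#' @param n_starts number of random starts (default 32).
#' @param seed integer seed for the random starts (default 1).
#' @return list of class `itc_fit`: `model` (the fitted [itc_model()]),
#'   `kd_se`, `dh_se` (standard errors, same class order), `rss`,
#'   `converged`, `n_starts_converged`, `unidentifiable` (TRUE when a class
#'   hits the K_D search bound or has a confidence interval overlapping
#'   another class within noise).
#' @export
fit_itc <- function(thermogram, schedule = NULL, n_classes = 3L,
                    n_starts = 32L, seed = 1L) {
  schedule <- schedule %||% thermogram$schedule
  stopifnot(n_classes %in% c(1L, 2L, 3L))
  heats <- thermogram$heats
  if (!is.null(thermogram$blank_heats))
    heats <- heats - thermogram$blank_heats
  if (length(heats) < 2L * n_classes + 2L)
    stop("need at least ", 2L * n_classes + 2L, " injections to fit ",
         n_classes, " site classes")
  dil <- dilution_schedule(schedule)
  v0 <- schedule$cell_volume
  dv <- schedule$injection_volumes
  log_kd_lo <- -9; log_kd_hi <- -2
  resid_fun <- function(par) {
    kd <- 10^par[seq_len(n_classes)]
    dh <- par[n_classes + seq_len(n_classes)]
    x_free <- solve_free_ligand(dil$x_total, dil$m_total, kd)
    q <- numeric(length(x_free))
    for (i in seq_len(n_classes)) q <- q + dh[i] * x_free / (kd[i] + x_free)
    q <- v0 * dil$m_total * q * KCAL_TO_UCAL
    q_prev <- c(0, q[-length(q)])
    (q - q_prev + (dv / v0) * (q + q_prev) / 2) - heats
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i)
    c(sort(runif(n_classes, log_kd_lo, log_kd_hi)),
      runif(n_classes, -20, 25)))
  best <- NULL; n_conv <- 0L
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         lower = c(rep(log_kd_lo, n_classes),
                                   rep(-50, n_classes)),
                         upper = c(rep(log_kd_hi, n_classes),
                                   rep(50, n_classes)),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit-failure: no start converged for ", n_classes, "-class model")
  par <- best$par
  kd <- 10^par[seq_len(n_classes)]
  dh <- par[n_classes + seq_len(n_classes)]
  ord <- order(kd)
  # covariance from the local quadratic approximation (J'J scaled by MSE)
  dof <- max(length(heats) - length(par), 1L)
  sigma2 <- best$deviance / dof
  cov <- tryCatch(solve(best$hessian) * sigma2,
                  error = function(e) matrix(NA_real_, length(par),
                                             length(par)))
  se <- sqrt(pmax(diag(cov), 0))
  kd_se <- kd * log(10) * se[seq_len(n_classes)]    # delta method
  dh_se <- se[n_classes + seq_len(n_classes)]
  at_bound <- par[seq_len(n_classes)] <= log_kd_lo + 0.01 |
    par[seq_len(n_classes)] >= log_kd_hi - 0.01
  overlap <- FALSE
  if (n_classes > 1L) {
    ks <- kd[ord]; kse <- kd_se[ord]
    for (i in seq_len(n_classes - 1L))
      if (is.finite(kse[i]) && is.finite(kse[i + 1L]) &&
          ks[i] + kse[i] >= ks[i + 1L] - kse[i + 1L]) overlap <- TRUE
  }
  structure(list(model = itc_model(kd, dh),
                 kd_se = kd_se[ord], dh_se = dh_se[ord],
                 rss = best$deviance,
                 converged = best$info %in% 1:4,
                 n_starts_converged = n_conv,
                 unidentifiable = any(at_bound) || overlap),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  RSS = %.4g ucal^2; %d starts converged%s\n", x$rss,
              x$n_starts_converged,
              if (x$unidentifiable) "; WARNING: some class unidentifiable"
              else ""))
  invisible(x)
}

#' Overall apparent dissociation constant
#'
#' Summarises the per-class dissociation constants of a multi-site model as
#' their geometric mean, `(prod_i K_Di)^(1/n)` — a single apparent-affinity
#' figure for comparing variants and ionic conditions.
#'
#' @param model an [itc_model()], or a numeric vector of K_Ds (molar).
#' @return apparent K_D, molar.
#' @export
kd_apparent <- function(model) {
  kd <- if (inherits(model, "itc_model")) model$kd else as.numeric(model)
  stopifnot(length(kd) >= 1L, all(kd > 0))
  exp(mean(log(kd)))
}

#' Read an ITC thermogram from CSV
#'
#' Expected columns: `injection_index`, `injection_volume_uL`, `heat_ucal`,
#' and optionally `blank_heat_ucal` (a reference titration without protein,
#' subtracted at fit time).
#'
#' @param path CSV file path.
#' @param cell_concentration,syringe_concentration,cell_volume,temperature
#'   schedule parameters, see [itc_schedule()].
#' @return a `thermogram` with its [itc_schedule()] attached.
#' @export
read_itc_csv <- function(path, cell_concentration = 20e-6,
                         syringe_concentration = 0.5e-3,
                         cell_volume = 1.4e-3, temperature = 25) {
  d <- read.csv(path)
  need <- c("injection_index", "injection_volume_uL", "heat_ucal")
  if (!all(need %in% names(d)))
    stop("ITC CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$injection_index), ]
  sched <- itc_schedule(cell_concentration, syringe_concentration,
                        injection_volumes = d$injection_volume_uL * 1e-6,
                        cell_volume = cell_volume, temperature = temperature)
  dil <- dilution_schedule(sched)
  structure(list(heats = d$heat_ucal,
                 blank_heats = d$blank_heat_ucal,
                 x_total = dil$x_total, m_total = dil$m_total,
                 schedule = sched),
            class = "thermogram")
}
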