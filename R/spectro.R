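#' CD spectrum container
#'
#' Wavelength-indexed ellipticity. Wavelengths must be strictly monotone.
#'
#' @param wavelengths nm.
#' @param ellipticity mdeg, same length.
#' @return object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, ellipticity) {
  stopifnot(length(wavelengths) == length(ellipticity))
  d <- diff(wavelengths)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavelengths must be strictly monotone")
  structure(list(wavelengths = as.numeric(wavelengths),
                 ellipticity = as.numeric(ellipticity)),
            class = "cd_spectrum")
}

#' Melt curve container
#'
#' Temperature-indexed ellipticity at 222 nm from a thermal scan.
#'
#' @param temperature degrees C, strictly increasing.
#' @param ellipticity mdeg, same length.
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, ellipticity) {
  stopifnot(length(temperature) == length(ellipticity))
  if (any(diff(temperature) <= 0))
    stop("temperature must be strictly increasing")
  structure(list(temperature = as.numeric(temperature),
                 ellipticity = as.numeric(ellipticity)),
            class = "melt_curve")
}

interp_at <- function(spectrum, wl) {
  rng <- range(spectrum$wavelengths)
  if (wl < rng[1L] || wl > rng[2L])
    stop("range error: wavelength ", wl, " nm outside spectrum range [",
         rng[1L], ", ", rng[2L], "]")
  approx(spectrum$wavelengths, spectrum$ellipticity, xout = wl)$y
}

#' Far-UV spectral-shape ratio theta222/theta208
#'
#' Ratio of ellipticities at the two minima typical of an alpha-helix
#' (222 and 208 nm), each read by linear interpolation at exactly 222.0 and
#' 208.0 nm. A shape descriptor for all-alpha proteins, insensitive to
#' uniform scaling (concentration/path length).
#'
#' @param spectrum a [cd_spectrum()] covering 208-222 nm.
#' @return dimensionless ratio.
#' @export
theta_ratio <- function(spectrum) {
  t222 <- interp_at(spectrum, 222)
  t208 <- interp_at(spectrum, 208)
  if (t208 == 0) stop("division error: theta208 is zero")
  t222 / t208
}

#' Relative ellipticity change on ion binding
#'
#' `(theta222_ion - theta222_egta) / theta222_egta`: the fractional change
#' in 222 nm ellipticity relative to the ion-free (EGTA) form, reporting on
#' gained helicity/compaction upon cation binding.
#'
#' @param theta222_ion mdeg, ion-loaded form.
#' @param theta222_egta mdeg, EGTA form; must be nonzero.
#' @return dimensionless.
#' @export
delta_theta <- function(theta222_ion, theta222_egta) {
  if (theta222_egta == 0) stop("division error: theta222_egta is zero")
  (theta222_ion - theta222_egta) / theta222_egta
}

#' Near-UV baseline normalisation
#'
#' Subtracts the mean ellipticity over the 310-320 nm band, where no signal
#' is expected, removing cuvette-positioning offsets. The output's mean over
#' that band is zero.
#'
#' @param spectrum a [cd_spectrum()] covering 310-320 nm.
#' @param band numeric length-2 band (nm), default `c(310, 320)`.
#' @return baseline-corrected [cd_spectrum()].
#' @export
normalize_near_uv <- function(spectrum, band = c(310, 320)) {
  in_band <- spectrum$wavelengths >= band[1L] & spectrum$wavelengths <= band[2L]
  if (!any(in_band))
    stop("range error: spectrum does not cover the ", band[1L], "-",
         band[2L], " nm band")
  cd_spectrum(spectrum$wavelengths,
              spectrum$ellipticity - mean(spectrum$ellipticity[in_band]))
}

hill_theta <- function(temp, theta_folded, theta_unfolded, tm, h) {
  fu <- temp^h / (tm^h + temp^h)
  theta_folded + (theta_unfolded - theta_folded) * fu
}

#' Fit a 4-parameter Hill sigmoid to a thermal melt
#'
#' Least-squares fit of
#' `theta(T) = theta_folded + (theta_unfolded - theta_folded) * T^h / (T_m^h + T^h)`
#' with T in degrees C as scanned; `theta(T_m)` is the midpoint of the two
#' baselines regardless of temperature scale. Multi-start over a grid of
#' (T_m, h) with baselines seeded from the scan ends. The fit is flagged
#' `censored` — reported as `"> {max T}"` — when no trustworthy midpoint
#' lies inside the scan: the fitted T_m exceeds the scan maximum, no
#' transition is detected (fitted amplitude below 3x the residual SD), or
#' the fitted transition fails to reach 90 percent completion within the
#' scan (`T_m * 9^(1/h) > max T`, i.e. the unfolded baseline is never
#' established, so the midpoint rests on extrapolation).
#'
#' @param curve a [melt_curve()] with at least 8 points spanning >= 20
#'   degrees C.
#' @return list of class `melt_fit`: `theta_folded`, `theta_unfolded`
#'   (mdeg), `tm` (degrees C), `h` (Hill exponent), `tm_se`, `converged`,
#'   `censored`, `tm_label` (e.g. `"49.8"` or `"> 96"`), `rss`.
#' @export
fit_melt <- function(curve) {
  temp <- curve$temperature; y <- curve$ellipticity
  if (length(temp) < 8L)
    stop("insufficient-data error: need at least 8 points")
  if (diff(range(temp)) < 20)
    stop("insufficient-data error: scan must span at least 20 degrees C")
  t_max <- max(temp)
  n_edge <- max(3L, length(temp) %/% 10L)
  th_f0 <- mean(head(y, n_edge)); th_u0 <- mean(tail(y, n_edge))
  resid_fun <- function(par) {
    hill_theta(temp, par[1L], par[2L], exp(par[3L]), exp(par[4L])) - y
  }
  tm_grid <- seq(min(temp) + 2, t_max + 10, length.out = 8L)
  h_grid <- c(5, 15, 30, 60)
  best <- NULL
  for (tm0 in tm_grid) for (h0 in h_grid) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(th_f0, th_u0, log(tm0), log(h0)),
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("fit-failure: no melt fit converged")
  par <- best$par
  tm <- exp(par[3L]); h <- exp(par[4L])
  dof <- max(length(y) - 4L, 1L)
  resid_sd <- sqrt(best$deviance / dof)
  amplitude_in_scan <- abs(hill_theta(t_max, par[1L], par[2L], tm, h) -
                           hill_theta(min(temp), par[1L], par[2L], tm, h))
  t90 <- tm * 9^(1 / h)    # temperature of 90 percent completion
  censored <- tm > t_max || amplitude_in_scan < 3 * resid_sd || t90 > t_max
  cov <- tryCatch(solve(best$hessian) * resid_sd^2,
                  error = function(e) matrix(NA_real_, 4L, 4L))
  tm_se <- tm * sqrt(max(cov[3L, 3L], 0))   # delta method on log T_m
  structure(list(theta_folded = par[1L], theta_unfolded = par[2L],
                 tm = tm, h = h, tm_se = tm_se,
                 converged = best$info %in% 1:4,
                 censored = censored,
                 tm_label = if (censored) sprintf("> %g", t_max)
                            else sprintf("%.1f", tm),
                 rss = best$deviance),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> T_m = %s degC (h = %.1f, baselines %.1f / %.1f mdeg)%s\n",
              x$tm_label, x$h, x$theta_folded, x$theta_unfolded,
              if (x$censored) " [censored]" else ""))
  invisible(x)
}

#' Normalise a fluorescence titration to its low-calcium intensity
#'
#' Intrinsic tryptophan emission (e.g. at 332 nm) as a function of free
#' calcium, divided by the intensity at the lowest free-calcium point, so
#' the series starts at 1. Input order is irrelevant: points are sorted by
#' free calcium internally.
#'
#' @param free_ca free calcium concentrations, molar.
#' @param f332 fluorescence intensities, arbitrary units, same length.
#' @return data.frame with `free_ca` (sorted ascending) and `f_norm`.
#' @export
normalize_fluorescence <- function(free_ca, f332) {
  stopifnot(length(free_ca) == length(f332), length(free_ca) > 0)
  ord <- order(free_ca)
  free_ca <- free_ca[ord]; f332 <- f332[ord]
  if (f332[1L] == 0)
    stop("division error: zero intensity at the low-calcium reference point")
  data.frame(free_ca = free_ca, f_norm = f332 / f332[1L])
}

#' Read a CD spectrum or melt curve from CSV
#'
#' Column pairs recognised: (`wavelength_nm`, `ellipticity_mdeg`) for
#' spectra; (`temperature_C`, `ellipticity_mdeg`) for melt curves;
#' (`free_ca_M`, `F332`) for fluorescence titrations.
#'
#' @param path CSV file path.
#' @return a [cd_spectrum()], [melt_curve()], or fluorescence data.frame.
#' @export
read_spectro_csv <- function(path) {
  d <- read.csv(path)
  if (all(c("wavelength_nm", "ellipticity_mdeg") %in% names(d)))
    cd_spectrum(d$wavelength_nm, d$ellipticity_mdeg)
  else if (all(c("temperature_C", "ellipticity_mdeg") %in% names(d)))
    melt_curve(d$temperature_C, d$ellipticity_mdeg)
  else if (all(c("free_ca_M", "F332") %in% names(d)))
    d[, c("free_ca_M", "F332")]
  else stop("unrecognised spectro CSV columns: ",
            paste(names(d), collapse = ", "))
}
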