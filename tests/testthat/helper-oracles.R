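# Independent oracles used by the tests; these deliberately avoid the code
# paths they check.

# Horn's quaternion method for least-squares rigid superposition: an
# algorithmically independent alternative to the SVD (Kabsch) route.
quaternion_superpose_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2L, colMeans(mobile))
  b <- sweep(reference, 2L, colMeans(reference))
  s <- crossprod(a, b)   # 3x3 correlation
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4L, 4L, byrow = TRUE)
  lam <- max(eigen(n4, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# brute-force centered truncated-window moving statistics (population SD)
brute_running_stats <- function(series, window) {
  n <- length(series)
  lo_off <- (window - 1L) %/% 2L
  hi_off <- window %/% 2L
  means <- numeric(n); sds <- numeric(n)
  for (i in seq_len(n)) {
    w <- series[max(1L, i - lo_off):min(n, i + hi_off)]
    means[i] <- sum(w) / length(w)
    sds[i] <- sqrt(sum((w - means[i])^2) / length(w))
  }
  list(means = means, sds = sds)
}

# random proper rotation via QR decomposition
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3L, 3L))
  r <- qr.Q(qr_dec) %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

# three-point angle (deg) at vertex b, written independently of the package
three_point_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# closed-form free ligand for a single binding site (quadratic)
one_site_free_ligand <- function(x_total, m_total, kd) {
  b <- m_total - x_total + kd
  (-b + sqrt(b^2 + 4 * kd * x_total)) / 2
}

# minimal hand-built two-atom model for distance fixtures
two_atom_model <- function(d = 12, res_a = 168L, res_b = 178L) {
  structure_model(data.frame(
    serial = 1:2, atom_name = "CA", residue_name = c("ASP", "ARG"),
    chain_id = "A", residue_number = c(res_a, res_b), element = "C",
    x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE))
}

table1_wt_ca <- function() itc_model(c(16.3e-9, 36e-9, 0.25e-6),
                                     c(-4.2, -5, 1.20))
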