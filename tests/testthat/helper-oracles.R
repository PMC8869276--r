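# Independent brute-force oracles, deliberately written from first
# principles (explicit loops, eigenvalue form of epsilon) rather than via
# the package's own code paths.

# Repeated-measures ANOVA: explicit sums of squares plus the eigenvalue
# form of the Greenhouse-Geisser epsilon of the double-centred covariance.
rm_anova_oracle <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(Y[, j]) - gm)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(Y[i, ]) - gm)^2
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (Y[i, j] - gm)^2
  ss_err <- ss_tot - ss_subj - ss_cond
  Fv <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  S <- cov(Y)
  C <- diag(k) - matrix(1 / k, k, k)
  lam <- Re(eigen(C %*% S %*% C, symmetric = TRUE)$values)
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  list(F = Fv, epsilon = eps, df1 = eps * (k - 1), df2 = eps * (k - 1) * (n - 1))
}

# Long-format feature table from a wide subjects x ROIs matrix.
wide_to_table <- function(Y, feature = "v") {
  rois <- colnames(Y)
  if (is.null(rois)) rois <- paste0("R", seq_len(ncol(Y)))
  out <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(nrow(Y))), ncol(Y)),
    roi = rep(rois, each = nrow(Y)))
  out[[feature]] <- as.vector(Y)
  out
}

# Population variance of a vector (divisor n).
pvar <- function(x) mean((x - mean(x))^2)

# Direct full-length boxcar periodogram integrated over a band by the
# rectangle rule on its native fine grid - an estimator-independent check
# of the Welch band powers.
periodogram_band_oracle <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  xd <- stats::lm.fit(cbind(1, seq_len(n)), x)$residuals
  X <- stats::fft(xd)
  nf <- floor(n / 2) + 1
  p <- 2 * Mod(X[seq_len(nf)])^2 / (fs * n)
  p[1] <- 0
  f <- (seq_len(nf) - 1) * fs / n
  sum(p[f >= f_lo & f < f_hi]) * fs / n
}
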