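#' Shapiro-Wilk normality check
#'
#' Thin wrapper over the reference implementation in `stats`; used as a
#' reported diagnostic, never as an automatic gate to nonparametric tests.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list `(W, p, n)`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::sd(values) == 0)
    stop("Shapiro-Wilk is undefined for constant input")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, n = n)
}

# Wide n x k matrix of one feature (subjects x ROIs); errors listing
# missing cells when the crossing is incomplete.
feature_wide <- function(table, feature) {
  if (!feature %in% names(table)) stop("no such feature column: ", feature)
  subs <- unique(table$subject_id); rois <- unique(table$roi)
  m <- matrix(NA_real_, length(subs), length(rois),
              dimnames = list(subs, rois))
  for (i in seq_len(nrow(table)))
    m[table$subject_id[i], table$roi[i]] <- table[[feature]][i]
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete subject x ROI crossing; missing cell(s): ",
         paste(sprintf("%s/%s", rownames(m)[miss[, 1]],
                       colnames(m)[miss[, 2]]), collapse = ", "))
  }
  m
}

# Greenhouse-Geisser epsilon from the sample covariance of condition scores:
# the double-centred covariance D has eps = tr(D)^2 / ((k-1) sum(D^2)).
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  D <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  sum(diag(D))^2 / ((k - 1) * sum(D^2))
}

#' One-way repeated-measures ANOVA across ROIs
#'
#' Classical within-subject decomposition with subject blocking:
#' `F = MS_conditions / MS_error` on `(k-1, (k-1)(n-1))` degrees of freedom,
#' with a sphericity correction factor epsilon multiplying both d.f. —
#' Greenhouse-Geisser (default, computed from the sample covariance of the
#' condition scores) or Huynh-Feldt. Uncorrected results are retained
#' alongside.
#'
#' @param table a feature table (complete subject x ROI crossing).
#' @param feature feature column name, e.g. `"delta_t_C"` or
#'   `"dpsd_myogenic"`.
#' @param epsilon `"gg"` (Greenhouse-Geisser, default), `"hf"`
#'   (Huynh-Feldt) or `"none"`.
#' @return an `anova_rm`: list with `feature`, `F`, `df1`, `df2`
#'   (corrected), `df1_unc`, `df2_unc`, `epsilon`, `p` (corrected),
#'   `p_unc`, `correction`, `ss` (component sums of squares), `n`, `k`.
#' @export
rm_anova <- function(table, feature, epsilon = c("gg", "hf", "none")) {
  epsilon <- match.arg(epsilon)
  Y <- feature_wide(table, feature)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2) stop("repeated-measures ANOVA needs >= 2 subjects")
  gm <- mean(Y)
  ss_total <- sum((Y - gm)^2)
  ss_subj <- k * sum((rowMeans(Y) - gm)^2)
  ss_cond <- n * sum((colMeans(Y) - gm)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1u <- k - 1; df2u <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1u
  ms_err <- ss_err / df2u
  Fv <- if (ms_err == 0) { if (ms_cond == 0) 0 else Inf } else ms_cond / ms_err
  eps_gg <- gg_epsilon(Y)
  eps <- switch(epsilon,
    none = 1,
    gg = eps_gg,
    hf = min(1, (n * df1u * eps_gg - 2) / (df1u * (n - 1 - df1u * eps_gg))))
  df1 <- eps * df1u; df2 <- eps * df2u
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  p_unc <- stats::pf(Fv, df1u, df2u, lower.tail = FALSE)
  structure(list(feature = feature, F = Fv, df1 = df1, df2 = df2,
                 df1_unc = df1u, df2_unc = df2u, epsilon = eps,
                 epsilon_gg = eps_gg, p = p, p_unc = p_unc,
                 correction = epsilon,
                 ss = c(conditions = ss_cond, subjects = ss_subj,
                        error = ss_err, total = ss_total),
                 n = n, k = k),
            class = "anova_rm")
}

#' @export
print.anova_rm <- function(x, ...) {
  cat(sprintf("RM-ANOVA on %s: F(%.2f, %.2f) = %.2f, p = %.4g (%s, eps = %.3f)\n",
              x$feature, x$df1, x$df2, x$F, x$p, x$correction, x$epsilon))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Fisher LSD post hoc pairwise comparisons
#'
#' All ROI pairs compared by two-sided paired t-tests with no multiplicity
#' adjustment (the Fisher LSD convention following a significant omnibus
#' test). Each pair uses its own paired error term — the common software
#' convention — rather than the pooled ANOVA error; the choice is recorded
#' in the result.
#'
#' @param table a feature table (complete subject x ROI crossing).
#' @param feature feature column name.
#' @return data.frame per pair: `roi_a`, `roi_b`, `mean_diff` (a - b), `t`,
#'   `df`, `p`, `stars`; attribute `error_term = "per-pair"`.
#' @export
lsd_posthoc <- function(table, feature) {
  Y <- feature_wide(table, feature)
  rois <- colnames(Y)
  pairs <- utils::combn(length(rois), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- Y[, a] - Y[, b]
    if (stats::sd(d) == 0) {
      # degenerate paired test: zero-variance differences
      tt <- list(statistic = c(t = if (mean(d) == 0) 0 else Inf * sign(mean(d))),
                 parameter = c(df = length(d) - 1),
                 p.value = if (mean(d) == 0) 1 else 0)
    } else tt <- stats::t.test(Y[, a], Y[, b], paired = TRUE)
    data.frame(roi_a = rois[a], roi_b = rois[b], mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stars = significance_stars(tt$p.value))
  })
  out <- do.call(rbind, rows)
  attr(out, "error_term") <- "per-pair"
  out
}

#' Pearson correlations of every thermal feature with RPE
#'
#' One correlation per (feature, ROI) cell — the 6 x 4 matrix of r values
#' between the per-subject ratings of perceived exertion and each thermal
#' feature. Two-sided p-values come from the t transform of r on n - 2
#' d.f.; cells with zero variance on either side are flagged, not errors.
#' No multiple-testing correction is applied across cells.
#'
#' @param table a feature table with an `rpe` column (constant within
#'   subject).
#' @param features feature column names (default: `delta_t_C` and the five
#'   `dpsd_*` columns present).
#' @return data.frame `(feature, roi, r, p, n, stars, degenerate)`.
#' @export
correlate_with_rpe <- function(table, features = NULL) {
  if (is.null(features))
    features <- intersect(c("delta_t_C", paste0("dpsd_", vasomotion_bands()$label)),
                          names(table))
  rois <- unique(table$roi)
  rows <- list()
  for (f in features) for (r in rois) {
    sub <- table[table$roi == r, ]
    sub <- sub[order(sub$subject_id), ]
    x <- sub[[f]]; y <- sub$rpe
    n <- length(x)
    if (n < 3) stop("need >= 3 subjects per correlation cell")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      rows[[paste(f, r)]] <- data.frame(feature = f, roi = r, r = NA_real_,
                                        p = NA_real_, n = n, stars = "",
                                        degenerate = TRUE)
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    rows[[paste(f, r)]] <- data.frame(
      feature = f, roi = r, r = unname(ct$estimate), p = ct$p.value, n = n,
      stars = ifelse(ct$p.value < 0.01, "**", ifelse(ct$p.value < 0.05, "*", "")),
      degenerate = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
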