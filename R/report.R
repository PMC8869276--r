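boxplot_summary <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Build the full statistics report for a feature table
#'
#' Runs, for every thermal feature (the temperature change and the five
#' band-power changes): the Shapiro-Wilk diagnostic per ROI, the
#' repeated-measures ANOVA across ROIs with sphericity correction, the LSD
#' post hoc grid, per-ROI boxplot summaries (median, quartiles, range), and
#' the feature x ROI Pearson correlation matrix against RPE. The
#' significance level is 0.05 throughout; normality failures are logged as
#' warnings in the report, never switched on.
#'
#' @param table a feature table from [compute_feature_table()].
#' @param epsilon sphericity correction passed to [rm_anova()].
#' @param alpha significance level (default 0.05).
#' @return a `stats_report` list: `anova` (one row per feature), `posthoc`
#'   (list by feature), `correlations`, `boxplots`, `shapiro`, `warnings`,
#'   `settings`.
#' @export
build_report <- function(table, epsilon = c("gg", "hf", "none"), alpha = 0.05) {
  epsilon <- match.arg(epsilon)
  features <- intersect(c("delta_t_C", paste0("dpsd_", vasomotion_bands()$label)),
                        names(table))
  warnings <- character()
  if (length(attr(table, "excluded") %||% character()) > 0)
    warnings <- c(warnings, paste("excluded:", attr(table, "excluded")))
  anova_rows <- list(); posthoc <- list(); boxplots <- list(); shapiro <- list()
  for (f in features) {
    a <- rm_anova(table, f, epsilon = epsilon)
    anova_rows[[f]] <- data.frame(
      feature = f, F = a$F, df1 = a$df1, df2 = a$df2, epsilon = a$epsilon,
      p = a$p, p_uncorrected = a$p_unc, correction = a$correction,
      significant = a$p < alpha, stars = significance_stars(a$p))
    posthoc[[f]] <- lsd_posthoc(table, f)
    boxplots[[f]] <- lapply(split(table[[f]], table$roi), boxplot_summary)
    shapiro[[f]] <- lapply(split(table[[f]], table$roi), function(x) {
      if (length(x) < 3 || stats::sd(x) == 0)
        return(list(W = NA, p = NA, n = length(x)))
      shapiro_wilk(x)
    })
    bad <- names(shapiro[[f]])[vapply(shapiro[[f]], function(s)
      is.finite(s$p) && s$p < alpha, logical(1))]
    if (length(bad) > 0)
      warnings <- c(warnings, sprintf(
        "normality check failed for %s in ROI(s) %s (reported, not acted on)",
        f, paste(bad, collapse = ", ")))
  }
  if (any(table$resolution_limited %||% FALSE))
    warnings <- c(warnings,
                  "metabolic band integrated from the first resolvable frequency (resolution-limited)")
  structure(list(
    anova = do.call(rbind, c(anova_rows, list(make.row.names = FALSE))),
    posthoc = posthoc,
    correlations = correlate_with_rpe(table, features),
    boxplots = boxplots, shapiro = shapiro, warnings = warnings,
    settings = list(alpha = alpha, epsilon = epsilon,
                    posthoc_error_term = "per-pair",
                    correlation_adjustment = "none (unadjusted cells)")),
    class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("stats_report\n\nANOVA (repeated measures across ROIs):\n")
  print(x$anova, row.names = FALSE, digits = 4)
  cat("\nRPE correlations (r, unadjusted):\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  if (length(x$warnings)) cat("\nwarnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Write a stats report to disk
#'
#' Writes `report.json` (machine-readable, lossless round-trip of every
#' number) and `report.md` (human-readable tables).
#'
#' @param report a `stats_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  md <- c("# Thermal-feature statistics report", "",
          "## Repeated-measures ANOVA across ROIs", "",
          df_to_md(report$anova), "",
          "## LSD post hoc (paired t, unadjusted)", "")
  for (f in names(report$posthoc))
    md <- c(md, paste0("### ", f), "", df_to_md(report$posthoc[[f]]), "")
  md <- c(md, "## Pearson correlations with RPE (* p<0.05, ** p<0.01)", "",
          df_to_md(report$correlations), "")
  if (length(report$warnings))
    md <- c(md, "## Warnings", "", paste("-", report$warnings), "")
  writeLines(md, file.path(dir, "report.md"))
  invisible(json_path)
}

df_to_md <- function(d) {
  fmt <- function(v) if (is.numeric(v)) formatC(v, digits = 4, format = "g") else as.character(v)
  cells <- vapply(d, fmt, character(nrow(d)))
  if (nrow(d) == 1L) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(d), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Read back a report.json
#' @param path JSON file written by [write_report()].
#' @return list mirroring the `stats_report` structure.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
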