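test_that("normality diagnostic behaves at its contract boundaries", {
  # plug-in normal quantiles score near the top of the W scale
  q <- qnorm(((1:8) - 0.375) / (8 + 0.25))
  sw <- shapiro_wilk(q)
  expect_gt(sw$W, 0.98)
  expect_gt(sw$p, 0.5)
  expect_error(shapiro_wilk(rep(1, 8)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("identical condition columns give F = 0", {
  Y <- matrix(rnorm(8), 8, 4)  # same column recycled
  a <- rm_anova(wide_to_table(Y), "v")
  expect_equal(a$F, 0)
  expect_equal(unname(a$ss["conditions"]), 0)
})

test_that("with two conditions the RM-ANOVA is the squared paired t-test", {
  set.seed(51)
  for (i in 1:20) {
    Y <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("A", "B")))
    a <- rm_anova(wide_to_table(Y), "v")
    tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$epsilon, 1, tolerance = 1e-12)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("F, epsilon and corrected d.f. match the brute-force oracle", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(5:12, 1); k <- sample(3:5, 1)
    Y <- matrix(rnorm(n * k), n, k)
    a <- rm_anova(wide_to_table(Y), "v")
    o <- rm_anova_oracle(Y)
    expect_equal(a$F, o$F, tolerance = 1e-8)
    expect_equal(a$epsilon, o$epsilon, tolerance = 1e-8)
    expect_equal(a$df1, o$df1, tolerance = 1e-8)
    expect_equal(a$df2, o$df2, tolerance = 1e-8)
    # epsilon bounds: 1/(k-1) <= eps <= 1
    expect_gte(a$epsilon, 1 / (k - 1) - 1e-10)
    expect_lte(a$epsilon, 1 + 1e-10)
    # Huynh-Feldt is less conservative than Greenhouse-Geisser, capped at 1
    hf <- rm_anova(wide_to_table(Y), "v", epsilon = "hf")
    expect_gte(hf$epsilon, a$epsilon - 1e-10)
    expect_lte(hf$epsilon, 1)
  }
})

test_that("RM-ANOVA matches the aov() error-strata oracle", {
  set.seed(53)
  Y <- matrix(rnorm(32), 8, 4)
  a <- rm_anova(wide_to_table(Y), "v")
  d <- data.frame(y = as.vector(Y), s = factor(rep(1:8, 4)),
                  c = factor(rep(1:4, each = 8)))
  sm <- summary(aov(y ~ c + Error(s / c), data = d))
  expect_equal(a$F, sm[["Error: s:c"]][[1]]["c", "F value"], tolerance = 1e-10)
})

test_that("ANOVA is invariant to subject relabelling and per-subject shifts", {
  set.seed(54)
  Y <- matrix(rnorm(32), 8, 4)
  a <- rm_anova(wide_to_table(Y), "v")
  perm <- sample(8)
  b <- rm_anova(wide_to_table(Y[perm, ]), "v")
  expect_equal(b$F, a$F, tolerance = 1e-12)
  expect_equal(b$epsilon, a$epsilon, tolerance = 1e-12)
  shifted <- Y + rnorm(8) %o% rep(1, 4)   # constant added within subject
  cc <- rm_anova(wide_to_table(shifted), "v")
  expect_equal(cc$F, a$F, tolerance = 1e-9)
  expect_equal(cc$epsilon, a$epsilon, tolerance = 1e-9)
})

test_that("incomplete crossings are rejected with the missing cells named", {
  tab <- wide_to_table(matrix(rnorm(32), 8, 4))
  tab <- tab[-c(3, 20), ]
  expect_error(rm_anova(tab, "v"), "missing cell")
  expect_error(rm_anova(tab, "nope"), "no such feature")
})

test_that("LSD post hoc: six unadjusted pairs, antisymmetric, starred", {
  set.seed(57)
  # exercised leg raised by 1.5 degC over near-noiseless alternatives
  Y <- cbind(Ex = 1.5 + rnorm(8, 0, 0.05), NonEx = rnorm(8, 0, 0.05),
             Nose = rnorm(8, 0, 0.05), Corr = rnorm(8, 0, 0.05))
  ph <- lsd_posthoc(wide_to_table(Y), "v")
  expect_equal(nrow(ph), 6)
  ex_pairs <- ph$roi_a == "Ex" | ph$roi_b == "Ex"
  expect_true(all(ph$p[ex_pairs] < 0.001))
  expect_true(all(ph$stars[ex_pairs] == "***"))
  expect_true(all(ph$p[!ex_pairs] > 0.05))
  # unadjusted paired t oracle
  tt <- t.test(Y[, "Ex"], Y[, "Nose"], paired = TRUE)
  row <- ph[ph$roi_a == "Ex" & ph$roi_b == "Nose", ]
  expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  expect_equal(row$mean_diff, mean(Y[, "Ex"] - Y[, "Nose"]), tolerance = 1e-12)
  # antisymmetry under column reversal
  Yr <- Y[, rev(colnames(Y))]
  phr <- lsd_posthoc(wide_to_table(Yr), "v")
  r1 <- ph[ph$roi_a == "Ex" & ph$roi_b == "Corr", ]
  r2 <- phr[phr$roi_a == "Corr" & phr$roi_b == "Ex", ]
  expect_equal(r2$mean_diff, -r1$mean_diff, tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
  # an identical pair is a zero difference with p = 1
  Y2 <- cbind(A = Y[, 1], B = Y[, 1], C = Y[, 2], D = Y[, 3])
  ph2 <- lsd_posthoc(wide_to_table(Y2), "v")
  ab <- ph2[ph2$roi_a == "A" & ph2$roi_b == "B", ]
  expect_equal(ab$mean_diff, 0)
  expect_equal(ab$t, 0)
  expect_equal(ab$p, 1)
})

test_that("RPE correlations recover exact and hand-computed r values", {
  tab <- wide_to_table(cbind(R1 = 1:5 * 1.0, R2 = rnorm(5)))
  tab$delta_t_C <- tab$v
  # feature an exact positive affine function of RPE -> r = 1; negative -> -1
  tab$rpe <- rep(0, 10)
  tab$rpe[tab$roi == "R1"] <- 2 + 3 * tab$delta_t_C[tab$roi == "R1"]
  tab$rpe[tab$roi == "R2"] <- 1:5
  r1 <- correlate_with_rpe(tab, "delta_t_C")
  expect_equal(r1$r[r1$roi == "R1"], 1, tolerance = 1e-12)
  tab$rpe[tab$roi == "R1"] <- 2 - 3 * tab$delta_t_C[tab$roi == "R1"]
  r2 <- correlate_with_rpe(tab, "delta_t_C")
  expect_equal(r2$r[r2$roi == "R1"], -1, tolerance = 1e-12)

  # x = 1..5 vs y = (2,1,4,3,5): closed-form Pearson r = 0.8
  tab2 <- data.frame(subject_id = sprintf("S%d", 1:5), roi = "R",
                     delta_t_C = 1:5, rpe = c(2, 1, 4, 3, 5))
  r3 <- correlate_with_rpe(tab2, "delta_t_C")
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_manual, 0.8, tolerance = 1e-12)
  expect_equal(r3$r, 0.8, tolerance = 1e-12)
  # p from the t transform on n - 2 d.f.
  tstat <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(r3$p, 2 * pt(-tstat, 3), tolerance = 1e-12)

  # zero-variance cells are flagged, not fatal
  tab2$delta_t_C <- 5
  r4 <- correlate_with_rpe(tab2, "delta_t_C")
  expect_true(r4$degenerate)
  expect_true(is.na(r4$r))
})

test_that("the report carries six ANOVA rows, quartiles and JSON round-trip", {
  tl <- default_tl()
  spec <- cohort_spec(8, roi_models = list(
    "Exercised Leg" = roi_effect(delta_t_mean = 1.5),
    "Nonexercised Leg" = roi_effect(),
    "Nose Tip" = roi_effect(baseline_temp_mean = 34),
    "Corrugator" = roi_effect(baseline_temp_mean = 34)),
    coupling = rpe_coupling(intercept = 11,
                            slopes = c("Exercised Leg:delta_t" = -2),
                            residual_sd = 0.7), seed = 7)
  co <- synthesize_cohort(spec, tl)
  ft <- compute_feature_table(co$traces, tl, co$rpe)
  rep <- build_report(ft)
  expect_equal(nrow(rep$anova), 6)
  expect_equal(nrow(rep$correlations), 24)
  expect_equal(rep$settings$alpha, 0.05)

  # boxplot summaries match an order-statistics oracle
  x <- ft$delta_t_C[ft$roi == "Exercised Leg"]
  bx <- rep$boxplots$delta_t_C[["Exercised Leg"]]
  xs <- sort(x)
  expect_equal(bx$min, xs[1])
  expect_equal(bx$max, xs[8])
  expect_equal(bx$median, (xs[4] + xs[5]) / 2)
  expect_equal(bx$q1, unname(quantile(x, 0.25)))

  d <- withr::local_tempdir()
  write_report(rep, d)
  back <- read_report(file.path(d, "report.json"))
  expect_equal(back$anova$F, rep$anova$F)
  expect_equal(back$correlations$r, rep$correlations$r)
  expect_true(file.exists(file.path(d, "report.md")))
})
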