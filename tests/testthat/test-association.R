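test_that("z-standardization uses the sample-SD convention", {
  z <- standardize_exposure(c(2, 4, 6))
  expect_equal(z, c(-1, 0, 1))
  x <- rnorm(50, 10, 3)
  z <- standardize_exposure(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_error(standardize_exposure(rep(5, 10)), "zero variance")
})

test_that("a perfectly linear toy fit recovers the closed-form slope", {
  dat <- tibble::tibble(x = c(-1, 0, 1), y = c(1, 2, 3))
  # closed form: slope = Sxy/Sxx = 2/2 = 1 on raw x; per-SD slope = 1 * sd(x)
  fit <- fit_association(dat, "x", "y")
  expect_equal(fit$estimate, sd(c(-1, 0, 1)) * 1, tolerance = 1e-12)
  expect_equal(fit$ci_low, fit$estimate, tolerance = 1e-8)
  expect_equal(fit$ci_high, fit$estimate, tolerance = 1e-8)
  expect_equal(fit$n_used, 3)
})

test_that("log-outcome estimates are exponentiated per-SD effects", {
  x <- seq(-2, 2, length.out = 41)
  dat <- tibble::tibble(x = x, y = exp(0.1 * standardize_exposure(x)))
  fit <- fit_association(dat, "x", "y", log_outcome = TRUE)
  expect_equal(fit$estimate, exp(0.1), tolerance = 1e-8)
  expect_equal(fit$scale, "exponentiated")
  dat$y[1] <- 0
  expect_error(fit_association(dat, "x", "y", log_outcome = TRUE), "nonpositive")
})

test_that("fitting on z equals the raw-exposure slope times the exposure SD", {
  withr::with_seed(41, {
    dat <- tibble::tibble(x = rnorm(80, 5, 2))
    dat$y <- 1.7 * dat$x + rnorm(80)
  })
  fit <- fit_association(dat, "x", "y")
  raw_slope <- unname(coef(lm(y ~ x, dat))["x"])
  expect_equal(fit$estimate, raw_slope * sd(dat$x), tolerance = 1e-10)
})

test_that("complete-case analysis reports the rows actually used", {
  withr::with_seed(42, {
    dat <- tibble::tibble(x = rnorm(60), w = rnorm(60))
    dat$y <- dat$x + rnorm(60)
    dat$w[1:5] <- NA
  })
  fit <- fit_association(dat, "x", "y", covariates = "w")
  expect_equal(fit$n_used, 55)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  withr::with_seed(43, {
    dat <- tibble::tibble(x = rnorm(30), w = rnorm(30))
    dat$w2 <- dat$w
    dat$y <- rnorm(30)
  })
  expect_error(fit_association(dat, "x", "y", covariates = c("w", "w2")),
               "collinear.*w2")
})

test_that("the default grid enumerates 51 cells: 49 fitted and 2 BMI cells skipped", {
  run <- run_pipeline(pipeline_config(seed = 3))
  grid <- run$grid
  res <- tidy(grid)
  expect_equal(nrow(res), 49)
  expect_true(all(res$status == "ok"))
  expect_equal(nrow(grid$skipped), 2)
  expect_setequal(grid$skipped$index, c("WCRF", "EHLI"))
  expect_true(all(grid$skipped$outcome == "bmi"))
  expect_equal(nrow(res) + nrow(grid$skipped),
               3 * length(outcome_names()))
  # family fixed at 51 with the corrected threshold
  expect_equal(grid$family, 51)
  expect_equal(grid$threshold, 0.05 / 51)
  # glycemic outcomes exponentiated, everything else on the identity scale
  expect_setequal(unique(res$outcome[res$scale == "exponentiated"]),
                  log_outcome_names())
  # MDS models use the diet-only sample; complete cases bound n
  expect_true(all(res$n_used <= run$manifest$n_diet_only))
  expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
})

test_that("subgroup filters restrict the analytic sample", {
  full <- run_pipeline(pipeline_config(seed = 3))
  sub <- run_pipeline(pipeline_config(seed = 3, subgroup = ~ age < 50))
  n_full <- tidy(full$grid)$n_used
  n_sub <- tidy(sub$grid)$n_used
  expect_equal(nrow(tidy(sub$grid)), 49)
  expect_true(all(n_sub < n_full))
})

test_that("Bonferroni tiers split at alpha/family and alpha", {
  res <- tibble::tibble(p_value = c(0.0005, 0.00098, 0.036, 0.05, 0.2))
  out <- apply_bonferroni(res, n_comparisons = 51, alpha = 0.05)
  expect_equal(attr(out, "threshold"), 0.05 / 51)
  expect_equal(round(attr(out, "threshold"), 3), 0.001)
  expect_equal(as.character(out$tier),
               c("strong", "strong", "nominal", "null", "null"))
  # no correction with a single comparison
  one <- apply_bonferroni(res, n_comparisons = 1, alpha = 0.05)
  expect_equal(attr(one, "threshold"), 0.05)
  expect_error(apply_bonferroni(res, 51, alpha = 1.2), "alpha")
})

test_that("tertile comparisons choose chi-square, ANOVA or Kruskal-Wallis", {
  # perfectly homogeneous 2 x 3 table: statistic 0, p = 1
  dat <- tibble::tibble(grp = rep(c("a", "b"), each = 30))
  tert <- rep(rep(1:3, each = 10), 2)
  r <- compare_by_tertile(dat, "grp", tert)
  expect_equal(r$method, "chi-square")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # hand-computable 2x2: chi2 = n(ad-bc)^2 / (row and column products)
  dat2 <- tibble::tibble(grp = c(rep("a", 10), rep("b", 20),
                                 rep("a", 20), rep("b", 10)))
  tert2 <- rep(1:2, each = 30)
  r2 <- compare_by_tertile(dat2, "grp", tert2)
  expect_equal(r2$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30))

  # glycemic outcomes default to Kruskal-Wallis, others to ANOVA
  dat3 <- tibble::tibble(homa_ir = rexp(60) + 1, facit_general = rnorm(60, 120))
  tert3 <- rep(1:3, each = 20)
  expect_equal(compare_by_tertile(dat3, "homa_ir", tert3)$method, "kruskal-wallis")
  r4 <- compare_by_tertile(dat3, "facit_general", tert3)
  expect_equal(r4$method, "anova")
  expect_false(is.na(r4$shapiro_p))
  expect_error(compare_by_tertile(dat3, "homa_ir", rep(1, 60)), "2 non-empty")
})

test_that("ANOVA tertile comparisons hold the nominal type-I rate", {
  rates <- withr::with_seed(44, {
    reps <- 500
    tert <- rep(1:3, each = 20)
    mean(vapply(seq_len(reps), function(i) {
      dat <- tibble::tibble(v = rnorm(60))
      compare_by_tertile(dat, "v", tert)$p_value < 0.05
    }, logical(1)))
  })
  expect_lt(abs(rates - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})
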