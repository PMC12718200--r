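test_that("cohort generation is deterministic given config and seed", {
  cfg <- cohort_config(n_participants = 30, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg1 <- cohort_config(n_participants = 1, seed = 7)
  expect_identical(generate_cohort(cfg1), generate_cohort(cfg1))
  other <- generate_cohort(cohort_config(n_participants = 30, seed = 8))
  expect_false(identical(generate_cohort(cfg), other))
})

test_that("marginal means and proportions recover their configured targets", {
  n <- 1500
  co <- generate_cohort(cohort_config(n_participants = n, seed = 3))

  # truncated-normal oracle for the BMI mean: mu + sd * phi(a)/(1 - Phi(a))
  a <- (30 - 47.5) / 9.3
  target_bmi <- 47.5 + 9.3 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(co$bmi) - target_bmi), 3 * 9.3 / sqrt(n))
  expect_gte(min(co$bmi), 30)

  p50 <- 1 - pnorm((50 - 53.5) / 8.5)  # configured P(age >= 50), about 0.66
  expect_lt(abs(mean(co$age >= 50) - p50), 3 * sqrt(p50 * (1 - p50) / n))

  p_never <- 0.547
  expect_lt(abs(mean(co$smoking == "never") - p_never),
            3 * sqrt(p_never * (1 - p_never) / n))
})

test_that("generated values respect their declared support", {
  co <- generate_cohort(cohort_config(n_participants = 400, seed = 5))
  intake <- c("fruit_nuts", "vegetables", "legumes", "cereals", "whole_grains",
              "refined_grains", "fish_seafood", "dairy", "red_meat",
              "processed_meat", "sugary_drinks", "mufa", "sfa", "fiber",
              "alcohol", "total_energy")
  for (v in intake) expect_gte(min(co[[v]], na.rm = TRUE), 0)
  expect_gt(min(co$height_cm), 0)
  expect_gt(min(co$weight_kg), 0)
  facit <- as.matrix(co[grep("^facit_", names(co))])
  expect_true(all(facit[!is.na(facit)] %in% 0:4))
  hads <- as.matrix(co[grep("^hads_", names(co))])
  expect_true(all(hads[!is.na(hads)] %in% 0:3))
})

test_that("invalid configurations fail naming the variable", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(
    cohort_config(marginals = list(x = list(family = "gamma", shape = 1))),
    "invalid distribution family.*'x'")
  expect_error(
    cohort_config(marginals = list(bad = list(family = "normal", mean = 0,
                                              sd = 1, lower = 5, upper = 5))),
    "infeasible truncation.*'bad'")
  expect_error(cohort_config(missingness = c(age = 1.2)), "missingness")
})

test_that("noiseless planted effects are recovered exactly by the matching model", {
  dat <- scored_analysis_data(n = 150, seed = 9)
  planted <- plant_effect(dat, "wcrf_total", "facit_general",
                          beta_per_sd = 4.45, noise_sd = 0, intercept = 120)
  fit <- fit_association(planted, "wcrf_total", "facit_general")
  expect_equal(fit$estimate, 4.45, tolerance = 1e-8)

  with_cov <- plant_effect(dat, "mds_total", "hads_overall", beta_per_sd = 5,
                           covariate_effects = c(age = 0.2), noise_sd = 0,
                           intercept = 10)
  fit2 <- fit_association(with_cov, "mds_total", "hads_overall",
                          covariates = "age")
  expect_equal(fit2$estimate, 5, tolerance = 1e-8)
})

test_that("log-scale planted effects average to the planted ratio over replicates", {
  dat <- scored_analysis_data(n = 150, seed = 10)
  ests <- withr::with_seed(11, vapply(seq_len(500), function(i) {
    planted <- plant_effect(dat, "ehli_total", "homa_ir",
                            beta_per_sd = log(0.92), noise_sd = 0.3,
                            intercept = log(5.5))
    fit_association(planted, "ehli_total", "homa_ir", log_outcome = TRUE)$estimate
  }, numeric(1)))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.92), 3 * mc_se)
})

test_that("planted null effects reject at the nominal rate", {
  dat <- scored_analysis_data(n = 150, seed = 12)
  pvals <- withr::with_seed(13, vapply(seq_len(1000), function(i) {
    planted <- plant_effect(dat, "mds_total", "facit_general",
                            beta_per_sd = 0, noise_sd = 1)
    fit_association(planted, "mds_total", "facit_general")$p_value
  }, numeric(1)))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("planted-effect estimates are unbiased with noise", {
  dat <- scored_analysis_data(n = 120, seed = 14)
  beta <- 2
  ests <- withr::with_seed(15, vapply(seq_len(500), function(i) {
    planted <- plant_effect(dat, "wcrf_total", "hads_overall",
                            beta_per_sd = beta, noise_sd = 3)
    fit_association(planted, "wcrf_total", "hads_overall")$estimate
  }, numeric(1)))
  expect_lt(abs(mean(ests) - beta), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("plant_effect rejects unknown outcomes, listing the valid ones", {
  dat <- scored_analysis_data(n = 20, seed = 16)
  expect_error(plant_effect(dat, "mds_total", "not_an_outcome", 1),
               "unknown outcome.*homa_ir")
})

test_that("exclusion fixtures plant exactly the requested flags", {
  fx <- make_exclusion_fixture(20, 5, 5, 5, seed = 2)
  bounds <- fixed_energy_bounds()
  # independent re-scan of the fixture
  energy_bad <- which(fx$total_energy < bounds[["lower"]] |
                        fx$total_energy > bounds[["upper"]])
  demog_bad <- which(is.na(fx$education))
  pa_bad <- which(is.na(fx$physical_activity))
  expect_length(energy_bad, 5)
  expect_length(demog_bad, 5)
  expect_length(pa_bad, 5)
  expect_length(unique(c(energy_bad, demog_bad, pa_bad)), 15)

  clean <- make_exclusion_fixture(10, 0, 0, 0, seed = 1)
  expect_true(all(clean$total_energy >= bounds[["lower"]] &
                    clean$total_energy <= bounds[["upper"]]))
  expect_false(anyNA(clean$education))
  expect_false(anyNA(clean$physical_activity))

  expect_error(make_exclusion_fixture(10, 5, 5, 5), "exceed")
})
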