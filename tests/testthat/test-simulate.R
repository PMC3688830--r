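test_that("same configuration gives identical cohorts", {
  cfg <- default_sim_config(seed = 51, n_patients = 100)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(provenance(a), "simulated")
  # different seeds differ
  c2 <- simulate_cohort(default_sim_config(seed = 52, n_patients = 100))
  expect_false(identical(a$sresc_score, c2$sresc_score))
})

test_that("simulated scores stay on the 1-9 scale with no empty maps", {
  co <- simulate_cohort(default_sim_config(seed = 53, n_patients = 2000))
  expect_true(all(co$sresc_score >= 1 & co$sresc_score <= 9))
  expect_true(all(nzchar(co$sites)))
  # score always equals the cardinality of the stored map
  n_sites <- lengths(strsplit(co$sites, ";"))
  expect_equal(co$sresc_score, as.integer(n_sites))
})

test_that("default configuration reproduces the development marginals", {
  co <- simulate_cohort(default_sim_config(seed = 54, n_patients = 10000))
  expect_lt(abs(mean(co$sresc_score) - 3.15), 0.3)
  expect_lt(abs(mean(co$stone_free) - 0.723), 0.03)
})

test_that("a zero slope removes the score-outcome association", {
  cfg <- sim_config(n_patients = 2000,
                    outcome_model = list(intercept = qlogis(0.72),
                                         slope = 0),
                    seed = 55)
  co <- simulate_cohort(cfg)
  tab <- table(co$sresc_group, co$stone_free)
  p <- chi_square_test(as.matrix(tab))$p_value
  expect_gt(p, 0.01)
  a <- auc_with_ties(co$sresc_score, 1 - co$stone_free)
  expect_lt(abs(a$auc - 0.5), 0.03)
})

test_that("a strongly negative slope makes the SFR monotone in score bins", {
  co <- simulate_cohort(default_sim_config(seed = 56, n_patients = 20000))
  sfr <- tapply(co$stone_free, factor(pmin(co$sresc_score, 7), levels = 1:7),
                mean)
  expect_true(all(diff(sfr) < 0))
})

test_that("covariates follow the configured distributions", {
  co <- simulate_cohort(default_sim_config(seed = 57, n_patients = 8000))
  expect_lt(abs(mean(co$age) - 54.9), 1)
  expect_lt(abs(mean(co$bmi) - 25.5), 0.3)
  expect_lt(abs(mean(co$largest_diameter_mm) - 23.6), 1)
  expect_lt(abs(sd(co$largest_diameter_mm) - 9.2), 1)
  expect_lt(abs(mean(co$sex == "M") - 0.652), 0.03)
  hyd <- prop.table(table(co$hydronephrosis))
  expect_lt(max(abs(hyd - c(0.168, 0.374, 0.271, 0.187))), 0.03)
})

test_that("rater noise model scores lower with misses above adds", {
  co <- simulate_cohort(default_sim_config(seed = 58, n_patients = 155))
  r <- simulate_rater_pair(co, seed = 59)
  expect_equal(r$rater_a, co$sresc_score)
  expect_lt(mean(r$rater_b), mean(r$rater_a))
  k <- weighted_kappa(r$rater_a, r$rater_b)
  expect_gt(k$kappa, 0.7)
  expect_lt(k$kappa, 1.0)
  # zero noise reproduces rater A exactly
  r0 <- simulate_rater_pair(co, rater_model = list(miss = 0, add = 0),
                            seed = 60)
  expect_identical(r0$rater_a, r0$rater_b)
  expect_equal(weighted_kappa(r0$rater_a, r0$rater_b)$kappa, 1)
})

test_that("disagreement concentrates at high scores", {
  co <- simulate_cohort(default_sim_config(seed = 61, n_patients = 4000))
  r <- simulate_rater_pair(co, seed = 62)
  dis <- abs(r$rater_a - r$rater_b)
  expect_gt(mean(dis[r$rater_a >= 4]), mean(dis[r$rater_a < 4]))
})

test_that("configurations serialise to JSON and back", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- default_sim_config(seed = 63, n_patients = 77)
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$n_patients, 77L)
  expect_equal(cfg2$seed, 63L)
  expect_equal(cfg2$outcome_model$slope, cfg$outcome_model$slope,
               tolerance = 1e-12)
  expect_identical(as.data.frame(simulate_cohort(cfg2)),
                   as.data.frame(simulate_cohort(cfg)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(seed = 1, site_model = list(
    pelvis = 1.2, calyceal = 0.1, enrichment = 2)), "probabilities")
  expect_error(sim_config(n_patients = 0, seed = 1), ">= 1")
  expect_error(sim_config(n_patients = 10), "seed")
  expect_error(simulate_rater_pair(reconstructed_cohort(), seed = 1),
               "stone maps")
})
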