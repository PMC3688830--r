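test_that("reconstruction reproduces the development cohort exactly", {
  co <- reconstructed_cohort()
  expect_s3_class(co, "sresc_cohort")
  expect_equal(nrow(co), 155L)
  expect_equal(sum(co$stone_free), 112L)
  expect_equal(provenance(co), "reconstruction")
  # per-score (stone-free, failure) counts
  sf <- tapply(co$stone_free, factor(co$sresc_score, levels = 1:9), sum)
  n <- table(factor(co$sresc_score, levels = 1:9))
  expect_equal(unname(as.integer(sf)), c(40, 32, 19, 10, 5, 3, 2, 0, 1))
  expect_equal(unname(as.integer(n) - as.integer(sf)),
               c(2, 1, 7, 6, 10, 6, 3, 6, 2))
  # score 8: six records, all failures
  expect_equal(sum(co$sresc_score == 8), 6L)
  expect_equal(sum(co$stone_free[co$sresc_score == 8]), 0L)
  # deterministic and bit-identical across calls
  expect_identical(co, reconstructed_cohort())
})

test_that("cohort summary matches the published headline statistics", {
  s <- cohort_summary(reconstructed_cohort())
  expect_equal(round(s$mean_score, 2), 3.15)
  expect_equal(round(s$sd_score, 2), 2.12)
  expect_equal(round(100 * s$sfr_overall, 1), 72.3)
  expect_equal(round(100 * s$by_group$sfr, 1), c(96.0, 69.0, 28.9))
  expect_equal(s$by_group$n, c(75L, 42L, 38L))
  # all nine per-score stone-free percentages, to one decimal
  expect_equal(round(100 * s$by_score$sfr, 1),
               c(95.2, 97.0, 73.1, 62.5, 33.3, 33.3, 40.0, 0.0, 33.3))
})

test_that("single-record summary uses the stated SD convention", {
  co <- sresc_cohort(data.frame(patient_id = "a", sresc_score = 1,
                                stone_free = 1))
  expect_warning(s <- cohort_summary(co), "SD")
  expect_equal(s$sd_score, 0)
  expect_equal(s$sfr_overall, 1)
  expect_equal(s$mean_score, 1)
})

test_that("cohort CSV round-trips identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- reconstructed_cohort()
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co), ignore_attr = TRUE)
  expect_equal(provenance(back), "file")
  # simulated cohorts round-trip too, covariates included
  co2 <- simulate_cohort(default_sim_config(seed = 2, n_patients = 40))
  write_cohort(co2, path)
  back2 <- read_cohort(path)
  expect_equal(back2$sites, co2$sites)
  expect_equal(back2$sresc_score, co2$sresc_score)
  expect_equal(back2$age, co2$age, tolerance = 1e-12)
  expect_equal(as.character(back2$clavien_grade),
               as.character(co2$clavien_grade))
})

test_that("validation rejects malformed cohorts with row numbers", {
  base <- data.frame(patient_id = c("a", "b"), sresc_score = c(2, 10),
                     stone_free = c(1, 0))
  expect_error(sresc_cohort(base), "1-9.*2")
  base$sresc_score <- c(2, 3)
  base$stone_free <- c(1, 2)
  expect_error(sresc_cohort(base), "stone_free.*2")
  base$stone_free <- c(1, 0)
  base$patient_id <- c("a", "a")
  expect_error(sresc_cohort(base), "duplicate")
  base$patient_id <- c("a", "b")
  base$sresc_group <- c("low", "high")
  expect_error(sresc_cohort(base), "inconsistent.*2")
  base$sresc_group <- NULL
  base$hydronephrosis <- c("mild", "terrible")
  expect_error(sresc_cohort(base), "vocabulary")
})

test_that("score is auto-computed from sites when absent", {
  d <- data.frame(patient_id = "a", sites = "1;2;4;5", stone_free = 0)
  co <- sresc_cohort(d)
  expect_equal(co$sresc_score, 4L)
  expect_equal(as.character(co$sresc_group), "medium")
  # and from file, with a missing score column entirely
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,sites,stone_free", "a,1;2;4;5,0", "b,3,1"), path)
  co2 <- read_cohort(path)
  expect_equal(co2$sresc_score, c(4L, 1L))
})

test_that("strict mode rejects unknown columns, default keeps them", {
  d <- data.frame(patient_id = "a", sresc_score = 3, stone_free = 1,
                  surgeon = "X")
  expect_error(sresc_cohort(d, strict = TRUE), "surgeon")
  co <- sresc_cohort(d)
  expect_equal(co$surgeon, "X")
})

test_that("missing mandatory columns are named in file errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,sresc_score", "a,3"), path)
  expect_error(read_cohort(path), "stone_free")
})
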