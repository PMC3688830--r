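test_that("reproduction report carries every headline quantity", {
  rep <- reproduce_report(seed = 1, n_bootstrap = 30)
  expect_equal(rep$summary$n, 155L)
  expect_equal(round(rep$summary$sfr_overall, 3), 0.723)
  expect_equal(round(rep$auc_score$auc, 3), 0.860)
  expect_equal(round(rep$auc_group$auc, 3), 0.853)
  expect_equal(round(rep$fit_score$or_table$or, 3), 0.477)
  expect_equal(round(rep$fit_group$or_table$or, 3), c(0.093, 0.017))
  expect_lt(rep$chisq_group$p_value, 0.001)
  expect_true(is.finite(rep$calibration$mae))
  expect_equal(rep$metadata$seed, 1L)
})

test_that("same-seed report JSON is byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(reproduce_report(seed = 4, n_bootstrap = 20), d1)
  write_report(reproduce_report(seed = 4, n_bootstrap = 20), d2)
  j1 <- readBin(file.path(d1, "report.json"), "raw",
                file.size(file.path(d1, "report.json")))
  j2 <- readBin(file.path(d2, "report.json"), "raw",
                file.size(file.path(d2, "report.json")))
  expect_identical(j1, j2)
  expect_true(file.exists(file.path(d1, "report.md")))
  expect_true(file.exists(file.path(d1, "calibration.csv")))
  expect_true(file.exists(file.path(d1, "decision_curve.csv")))
})

test_that("validating the written reconstruction reproduces the report", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(reconstructed_cohort(), path)
  rep_file <- validate_report(path, seed = 2, n_bootstrap = 20)
  rep_direct <- reproduce_report(seed = 2, n_bootstrap = 20)
  expect_equal(rep_file$summary$mean_score, rep_direct$summary$mean_score)
  expect_equal(rep_file$auc_score$auc, rep_direct$auc_score$auc)
  expect_equal(rep_file$fit_score$coefficients,
               rep_direct$fit_score$coefficients, tolerance = 1e-12)
  expect_equal(rep_file$calibration$mae, rep_direct$calibration$mae)
})

test_that("single-class outcomes skip the modelling stages with a warning", {
  co <- sresc_cohort(data.frame(patient_id = sprintf("p%d", 1:10),
                                sresc_score = rep(1:5, 2),
                                stone_free = 1))
  expect_warning(rep <- validate_report(co, seed = 1, n_bootstrap = 5),
                 "single-class")
  expect_null(rep$auc_score)
  expect_null(rep$calibration)
  expect_equal(rep$summary$n, 10L)
})

test_that("command line interface scores, simulates and reproduces", {
  cli <- system.file("scripts", "sresc-cli.R", package = "sresc")
  skip_if(cli == "", "installed CLI script not found")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli, "score", "--sites", "1,2,4,5"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("score=4 group=medium", out)))
  # duplicates collapse
  out2 <- system2(rscript, c(cli, "score", "--sites", "1,1,1"),
                  stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("score=1 group=low", out2)))
  # invalid sites exit non-zero
  bad <- suppressWarnings(
    system2(rscript, c(cli, "score", "--sites", "0,10"),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad, "status")))
  # simulate writes a deterministic CSV
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "sim1.csv"); f2 <- file.path(tmp, "sim2.csv")
  for (f in c(f1, f2))
    expect_equal(attr(suppressWarnings(
      system2(rscript, c(cli, "simulate", "--n", "30", "--seed", "9",
                         "--out", f), stdout = TRUE, stderr = TRUE)),
      "status"), NULL)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(read.csv(f1)), 30L)
  # reproduce writes the report bundle
  rd <- file.path(tmp, "rep")
  res <- suppressWarnings(
    system2(rscript, c(cli, "reproduce", "--seed", "3", "--boot", "10",
                       "--out", rd), stdout = TRUE, stderr = TRUE))
  expect_null(attr(res, "status"))
  expect_true(file.exists(file.path(rd, "report.json")))
  js <- jsonlite::read_json(file.path(rd, "report.json"))
  expect_equal(js$n, 155L)
  expect_equal(round(js$overall_sfr, 3), 0.723)
  expect_equal(round(js$auc_score$auc, 3), 0.86)
})
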