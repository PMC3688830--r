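# End-to-end reproduction / validation report: one object bundling every
# headline quantity the score's validation produces, writable as JSON
# (machine-readable, full precision, byte-identical for a fixed seed) and
# markdown (human-readable, published precision).

.report_bundle <- function(cohort, seed, n_bootstrap, source_label) {
  summ <- cohort_summary(cohort)
  resid <- 1L - cohort$stone_free

  # group x outcome association
  tab <- cbind(stone_free = summ$by_group$stone_free,
               residual = summ$by_group$n - summ$by_group$stone_free)
  chisq <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    chi_square_test(tab) else NULL

  single_class <- length(unique(cohort$stone_free)) < 2L
  if (single_class)
    warning("single-class outcome: model, AUC, calibration and DCA ",
            "stages skipped", call. = FALSE)
  fit_score <- if (!single_class)
    fit_logistic(data.frame(score = cohort$sresc_score), cohort$stone_free)
  groups_present <- length(unique(cohort$sresc_group)) == 3L
  fit_group <- if (!single_class && groups_present)
    fit_logistic(group_indicators(cohort$sresc_group), cohort$stone_free)

  auc_score <- if (!single_class) auc_with_ties(cohort$sresc_score, resid)
  auc_group <- if (!single_class)
    auc_with_ties(as.integer(cohort$sresc_group), resid)

  calibration <- if (!single_class)
    calibration_bootstrap(cohort, model = "score", n_bootstrap = n_bootstrap,
                          seed = seed)
  dca <- if (!single_class)
    decision_curve(resid,
                   predicted_probabilities(cohort, "score",
                                           event = "residual_stone"))

  structure(list(
    metadata = list(package_version = as.character(
                      utils::packageVersion("sresc")),
                    source = source_label, seed = as.integer(seed),
                    n_bootstrap = as.integer(n_bootstrap)),
    summary = summ,
    chisq_group = chisq,
    fit_score = fit_score,
    fit_group = fit_group,
    auc_score = auc_score,
    auc_group = auc_group,
    calibration = calibration,
    dca = dca),
    class = "sresc_report")
}

#' Reproduce the development cohort's validation report
#'
#' Runs the whole pipeline on [reconstructed_cohort()]: cohort summary
#' (mean +/- SD score, overall/per-score/per-group stone-free rates),
#' group chi-square, univariate score and group-indicator odds ratios
#' with Wald CIs, tie-corrected AUCs of the 9-level score and 3-tier
#' grouping, seeded bootstrap calibration, and the decision curve for the
#' residual-stone event.
#'
#' @param seed Integer seed for the bootstrap (default 20130618).
#' @param n_bootstrap Bootstrap resamples for calibration (default 200).
#' @return An object of class `"sresc_report"`.
#' @examples
#' rep <- reproduce_report(seed = 1, n_bootstrap = 20)
#' rep$auc_score$auc
#' @seealso [write_report()], [validate_report()]
#' @export
reproduce_report <- function(seed = 20130618L, n_bootstrap = 200L) {
  .report_bundle(reconstructed_cohort(), seed, n_bootstrap,
                 source_label = "reconstruction")
}

#' Validation report for a user cohort
#'
#' Same structure as [reproduce_report()] on any cohort.  Stages that the
#' data cannot support are skipped with an explicit warning: a
#' single-class outcome skips the model, AUC, calibration and DCA stages;
#' a missing group level skips the group-indicator fit.
#'
#' @param cohort An `sresc_cohort`, or a path to a cohort CSV.
#' @param seed,n_bootstrap As for [reproduce_report()].
#' @return An object of class `"sresc_report"`.
#' @export
validate_report <- function(cohort, seed = 20130618L, n_bootstrap = 200L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "sresc_cohort"))
  .report_bundle(cohort, seed, n_bootstrap,
                 source_label = provenance(cohort))
}

#' @export
print.sresc_report <- function(x, ...) {
  cat("== S-ReSC validation report ==\n")
  print(x$summary)
  if (!is.null(x$chisq_group)) {
    cat("\nGroup x outcome: ")
    print(x$chisq_group)
  }
  if (!is.null(x$fit_score)) { cat("\nScore model: "); print(x$fit_score) }
  if (!is.null(x$fit_group)) { cat("\nGroup model: "); print(x$fit_group) }
  if (!is.null(x$auc_score)) { cat("\n9-level score "); print(x$auc_score) }
  if (!is.null(x$auc_group)) { cat("3-tier group  "); print(x$auc_group) }
  if (!is.null(x$calibration)) { cat("\n"); print(x$calibration) }
  if (!is.null(x$dca)) { cat("\n"); print(x$dca) }
  invisible(x)
}

# Flatten a report to plain lists for JSON.  Deliberately excludes
# wall-clock time so that two same-seed runs serialise byte-identically.
.report_as_list <- function(x) {
  s <- x$summary
  out <- list(
    metadata = x$metadata,
    n = s$n,
    mean_score = s$mean_score,
    sd_score = s$sd_score,
    overall_sfr = s$sfr_overall,
    sfr_by_score = s$by_score,
    sfr_by_group = s$by_group)
  if (!is.null(x$chisq_group))
    out$chisq_group <- x$chisq_group[c("statistic", "df", "p_value")]
  if (!is.null(x$fit_score)) {
    out$or_score <- x$fit_score$or_table
    out$logistic_score <- list(
      coefficients = as.list(x$fit_score$coefficients),
      loglik = x$fit_score$loglik,
      iterations = x$fit_score$iterations,
      converged = x$fit_score$converged)
  }
  if (!is.null(x$fit_group)) out$or_group <- x$fit_group$or_table
  roc_bit <- function(r)
    list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
         n_pos = r$n_pos, n_neg = r$n_neg)
  if (!is.null(x$auc_score)) out$auc_score <- roc_bit(x$auc_score)
  if (!is.null(x$auc_group)) out$auc_group <- roc_bit(x$auc_group)
  if (!is.null(x$calibration))
    out$calibration <- list(mae = x$calibration$mae,
                            apparent_mae = x$calibration$apparent_mae,
                            n_bootstrap = x$calibration$n_bootstrap,
                            seed = x$calibration$seed,
                            model = x$calibration$model,
                            points = x$calibration$points)
  if (!is.null(x$dca))
    out$dca <- list(prevalence = x$dca$prevalence, curve = x$dca$curve)
  out
}

#' Write a validation report to disk
#'
#' Emits `report.json` (machine-readable, full precision; byte-identical
#' across same-seed runs), `report.md` (human-readable, published
#' precision: 3 decimals for odds ratios and AUCs, 1 decimal for
#' percentages, plus a run timestamp), and CSV exports of the calibration
#' points and decision curve when those stages ran.
#'
#' @param report An `"sresc_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sresc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  jsonlite::write_json(.report_as_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(report$calibration))
    utils::write.csv(report$calibration$points,
                     file.path(dir, "calibration.csv"), row.names = FALSE)
  if (!is.null(report$dca))
    utils::write.csv(report$dca$curve,
                     file.path(dir, "decision_curve.csv"),
                     row.names = FALSE)

  s <- report$summary
  md <- c("# S-ReSC validation report", "",
          sprintf("- run: %s; package %s; seed %d; %d bootstrap resamples",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
                  report$metadata$package_version, report$metadata$seed,
                  report$metadata$n_bootstrap),
          sprintf("- source: %s", report$metadata$source), "",
          sprintf("n = %d; S-ReSC score %.2f +/- %.2f; overall SFR %.1f%%",
                  s$n, s$mean_score, s$sd_score, 100 * s$sfr_overall), "",
          "| group | SFR | n |", "|---|---|---|",
          sprintf("| %s | %.1f%% | %d/%d |", s$by_group$group,
                  100 * s$by_group$sfr, s$by_group$stone_free,
                  s$by_group$n))
  if (!is.null(report$fit_score)) {
    ot <- report$fit_score$or_table
    md <- c(md, "",
            sprintf("Score OR %.3f (95%% CI %.3f-%.3f) per point",
                    ot$or[1], ot$ci_low[1], ot$ci_high[1]))
  }
  if (!is.null(report$fit_group)) {
    ot <- report$fit_group$or_table
    md <- c(md, sprintf("%s vs. low OR %.3f (95%% CI %.3f-%.3f)",
                        ot$term, ot$or, ot$ci_low, ot$ci_high))
  }
  if (!is.null(report$auc_score))
    md <- c(md, "", sprintf("AUC: %.3f (9-level score), %.3f (3-tier group)",
                            report$auc_score$auc, report$auc_group$auc))
  if (!is.null(report$calibration))
    md <- c(md, sprintf("Calibration MAE (bootstrap-corrected): %.3f",
                        report$calibration$mae))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
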