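# Calibration of the score-based prediction model: fitted probabilities,
# and Harrell-style bootstrap optimism correction of the calibration curve.

#' Fitted event probabilities from the score or group model
#'
#' Fits the univariate logistic model of the chosen event on the integer
#' score (`model = "score"`) or on the 3-tier group indicators
#' (`model = "group"`, a saturated categorical model whose fitted values
#' equal the observed group event rates) and returns the per-patient
#' fitted probabilities.  The event orientation is explicit and recorded
#' in the result: `"stone_free"` (the calibration default) or
#' `"residual_stone"` (the actionable event, the decision-curve default).
#'
#' @param cohort An `sresc_cohort`.
#' @param model `"score"` or `"group"`.
#' @param event `"stone_free"` or `"residual_stone"`.
#' @return Numeric vector of fitted probabilities, one per patient, with
#'   attributes `model`, `event` and `fit` (the underlying
#'   [fit_logistic()] object).
#' @examples
#' p <- predicted_probabilities(reconstructed_cohort(), "score")
#' range(p)
#' @export
predicted_probabilities <- function(cohort,
                                    model = c("score", "group"),
                                    event = c("stone_free",
                                              "residual_stone")) {
  stopifnot(inherits(cohort, "sresc_cohort"))
  model <- match.arg(model)
  event <- match.arg(event)
  y <- if (event == "stone_free") cohort$stone_free else 1L - cohort$stone_free
  x <- if (model == "score") data.frame(score = cohort$sresc_score)
       else group_indicators(cohort$sresc_group)
  fit <- fit_logistic(x, y)
  structure(fit$fitted, model = model, event = event, fit = fit)
}

# Apparent calibration curve: observed event proportion at each distinct
# score level (smooth = "none"), or a lowess smooth of outcome on
# predicted probability evaluated at the level predictions
# (smooth = "lowess").
.cal_observed <- function(pred_at_level, level_of_obs, y, pred_of_obs,
                          smooth) {
  if (smooth == "none") {
    as.numeric(tapply(y, level_of_obs, mean)[names(pred_at_level)])
  } else {
    sm <- stats::lowess(pred_of_obs, y, iter = 0)
    stats::approx(sm$x, sm$y, xout = pred_at_level, rule = 2,
                  ties = "ordered")$y
  }
}

#' Bootstrap optimism-corrected calibration
#'
#' Assesses agreement between predicted and observed stone-free
#' probabilities for the score-based logistic model, with Harrell-style
#' optimism correction: the model is refit on each case-resampled
#' bootstrap cohort (same size as the original, drawn with replacement),
#' the calibration curve of the bootstrap model is evaluated both on the
#' bootstrap sample and on the original cohort, and the mean difference
#' (the optimism) is subtracted from the apparent curve.  Resamples in
#' which the outcome is single-class (or, for the group model, a group is
#' empty) are redrawn and counted.
#'
#' Evaluation points are the distinct predicted probabilities — one per
#' observed score level (or group).  The mean absolute error is the
#' patient-weighted mean of |predicted - corrected observed| over those
#' points.  With `smooth = "none"` the observed curve is the raw event
#' proportion per level; `smooth = "lowess"` uses a lowess smooth of the
#' outcome on the predicted probability, as conventional calibration
#' plots do.
#'
#' @param cohort An `sresc_cohort`.
#' @param model `"score"` or `"group"`.
#' @param event `"stone_free"` (default) or `"residual_stone"`.
#' @param n_bootstrap Number of bootstrap resamples (default 200).
#' @param seed Integer seed; required, so no run is silently
#'   irreproducible.
#' @param smooth `"none"` (default) or `"lowess"`.
#' @return Object of class `"calibration_result"`: `points` (data frame
#'   with `level`, `n`, `predicted`, `observed`, `corrected`), `mae`,
#'   `apparent_mae`, `n_bootstrap`, `n_redrawn`, `seed`, `model`,
#'   `event`, `smooth`.
#' @examples
#' cal <- calibration_bootstrap(reconstructed_cohort(), n_bootstrap = 50,
#'                              seed = 1)
#' cal$mae
#' @export
calibration_bootstrap <- function(cohort, model = c("score", "group"),
                                  event = c("stone_free", "residual_stone"),
                                  n_bootstrap = 200L, seed,
                                  smooth = c("none", "lowess")) {
  stopifnot(inherits(cohort, "sresc_cohort"))
  model <- match.arg(model)
  event <- match.arg(event)
  smooth <- match.arg(smooth)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is required", call. = FALSE)
  n_bootstrap <- as.integer(n_bootstrap)
  if (n_bootstrap < 1L) stop("n_bootstrap must be >= 1", call. = FALSE)

  y <- if (event == "stone_free") cohort$stone_free else 1L - cohort$stone_free
  n <- length(y)
  xlev <- if (model == "score") cohort$sresc_score
          else as.character(cohort$sresc_group)
  # canonical patient order: the estimator depends only on (level, outcome)
  # pairs, so sorting makes the seeded result invariant to row order
  ord <- order(xlev, y)
  y <- y[ord]
  xlev <- xlev[ord]
  design <- function(lev) {
    if (model == "score") data.frame(score = lev)
    else group_indicators(lev)
  }
  fit0 <- fit_logistic(design(xlev), y)
  lev_u <- sort(unique(xlev))
  pred_lv <- stats::plogis(drop(
    cbind(1, as.matrix(design(lev_u))) %*% fit0$coefficients))
  names(pred_lv) <- as.character(lev_u)
  lev_f <- factor(xlev, levels = lev_u)
  n_lv <- as.integer(table(lev_f))
  pred_obs <- fit0$fitted

  obs0 <- .cal_observed(pred_lv, lev_f, y, pred_obs, smooth)
  apparent <- obs0 - pred_lv

  set.seed(as.integer(seed))
  optimism <- matrix(NA_real_, n_bootstrap, length(lev_u))
  n_redrawn <- 0L
  for (b in seq_len(n_bootstrap)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- length(unique(y[idx])) == 2L &&
        (model == "score" || all(lev_u %in% xlev[idx]))
      if (ok) break
      n_redrawn <- n_redrawn + 1L
    }
    yb <- y[idx]; xb <- xlev[idx]
    # a resample can be quasi-separated (e.g. a group with no failures);
    # its fitted values still converge to the cell proportions, which is
    # all the calibration curve needs, so the warning is muted here
    fitb <- suppressWarnings(fit_logistic(design(xb), yb))
    predb_lv <- stats::plogis(drop(
      cbind(1, as.matrix(design(lev_u))) %*% fitb$coefficients))
    names(predb_lv) <- as.character(lev_u)
    # bootstrap model on bootstrap sample (apparent) ...
    levb <- factor(xb, levels = lev_u)
    predb_obs <- stats::plogis(drop(
      cbind(1, as.matrix(design(xb))) %*% fitb$coefficients))
    err_boot <- .cal_observed(predb_lv, levb, yb, predb_obs, smooth) - predb_lv
    # ... minus bootstrap model on the original cohort (test)
    predb_orig <- stats::plogis(drop(
      cbind(1, as.matrix(design(xlev))) %*% fitb$coefficients))
    err_orig <- .cal_observed(predb_lv, lev_f, y, predb_orig, smooth) - predb_lv
    optimism[b, ] <- err_boot - err_orig
  }
  opt <- colMeans(optimism, na.rm = TRUE)
  corrected <- pred_lv + (apparent - opt)
  points <- data.frame(level = lev_u, n = n_lv,
                       predicted = unname(pred_lv),
                       observed = unname(obs0),
                       corrected = unname(corrected))
  structure(list(points = points,
                 mae = sum(n_lv * abs(pred_lv - corrected)) / n,
                 apparent_mae = sum(n_lv * abs(pred_lv - obs0)) / n,
                 n_bootstrap = n_bootstrap, n_redrawn = n_redrawn,
                 seed = as.integer(seed), model = model, event = event,
                 smooth = smooth),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("Bootstrap calibration (%s model, event = %s, %d ",
                     "resamples, seed %d)\n"),
              x$model, x$event, x$n_bootstrap, x$seed))
  cat(sprintf("  mean absolute error: %.3f (apparent %.3f)\n",
              x$mae, x$apparent_mae))
  if (x$n_redrawn > 0)
    cat(sprintf("  %d degenerate resample(s) redrawn\n", x$n_redrawn))
  invisible(x)
}

#' Plot a calibration curve
#'
#' Predicted probability against observed and optimism-corrected observed
#' proportions, with the identity line as the ideal.
#'
#' @param x A `"calibration_result"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.calibration_result <- function(x, ...) {
  p <- x$points
  graphics::plot(p$predicted, p$observed, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = sprintf("Predicted probability (%s)", x$event),
                 ylab = "Observed proportion", pch = 1, ...)
  graphics::abline(0, 1, lty = 3)
  graphics::points(p$predicted, p$corrected, pch = 16)
  graphics::lines(p$predicted[order(p$predicted)],
                  p$corrected[order(p$predicted)])
  graphics::legend("topleft", pch = c(1, 16), bty = "n",
                   legend = c("apparent", "bias-corrected"))
  invisible(x)
}
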