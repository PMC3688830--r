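# Tie-corrected ROC area.  With an ordinal predictor such as a 1-9 score,
# ties between cases and controls are frequent and must be credited 0.5
# per pair (the Mann-Whitney convention); the confidence interval uses the
# DeLong placement-value variance estimator.

#' ROC area with tied ordinal predictors
#'
#' AUC = (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg), i.e. the
#' probability that a randomly drawn positive case has a strictly higher
#' predictor value than a randomly drawn negative, plus half the
#' probability of a tie.  Orientation is explicit: positives are the rows
#' with `outcome == 1` and the AUC measures how well *higher* predictor
#' values identify them.  No "flip to >= 0.5" convention is applied — an
#' AUC below 0.5 is reported as such (discrimination between the two
#' classes is symmetric: swapping the class labels gives 1 - AUC).
#'
#' The 95% CI is `auc +/- 1.96 * sqrt(S10/n_pos + S01/n_neg)` from the
#' DeLong placement values, truncated to \[0, 1\].
#'
#' @param predictor Numeric vector (or ordered factor) of scores.
#' @param outcome Binary vector; `1` marks the positive class.
#' @return Object of class `"roc_result"`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, and `curve`, a data frame of operating points
#'   (`threshold`, `sensitivity`, `fpr`) obtained by thresholding at each
#'   distinct predictor value (predict positive when `predictor >=
#'   threshold`).
#' @examples
#' co <- reconstructed_cohort()
#' auc_with_ties(co$sresc_score, 1 - co$stone_free)   # higher score -> failure
#' @export
auc_with_ties <- function(predictor, outcome) {
  if (is.factor(predictor)) predictor <- as.numeric(predictor)
  predictor <- as.numeric(predictor)
  outcome <- as.numeric(outcome)
  if (length(predictor) != length(outcome))
    stop("predictor and outcome lengths differ", call. = FALSE)
  if (anyNA(predictor) || anyNA(outcome))
    stop("missing values not allowed", call. = FALSE)
  if (!all(outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  pos <- predictor[outcome == 1]
  neg <- predictor[outcome == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L)
    stop("both outcome classes must be present", call. = FALSE)

  # midrank formulation: placement of each positive among the negatives
  # psi(x, y) = 1 if x > y, 0.5 if x == y, 0 otherwise
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n          # per-positive placements
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m  # per-negative placements
  auc <- mean(v10)
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)

  thr <- sort(unique(predictor), decreasing = TRUE)
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)))

  structure(list(auc = auc,
                 ci_low = max(0, auc - 1.96 * se),
                 ci_high = min(1, auc + 1.96 * se),
                 se = se, n_pos = m, n_neg = n, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); %d positives, %d negatives\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}
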