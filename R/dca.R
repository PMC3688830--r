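# Decision curve analysis: net benefit of acting on the model's predicted
# event probability at each threshold, against treat-all and treat-none.

#' Decision curve analysis
#'
#' At threshold probability `p_t`, a patient is classified positive when
#' the predicted event probability is at least `p_t`, and the net benefit
#' of that policy is `TP/N - (FP/N) * p_t / (1 - p_t)`: true positives per
#' patient, minus false positives per patient weighted by the odds of the
#' threshold (the harm-benefit exchange rate the threshold implies).
#' Treat-all classifies everyone positive; treat-none has net benefit 0 by
#' definition.  The event should be the actionable one (for this score,
#' residual stone after sPCNL).
#'
#' @param outcomes Binary vector, `1` = event.
#' @param probabilities Predicted event probabilities in \[0, 1\].
#' @param thresholds Threshold grid, strictly inside (0, 1).  Default
#'   0.01 to 0.99 in steps of 0.01.
#' @return Object of class `"dca_result"`: `curve` (data frame with
#'   `threshold`, `nb_model`, `nb_all`, `nb_none`), `prevalence`, `n`.
#' @examples
#' dca <- decision_curve(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.1),
#'                       thresholds = 0.5)
#' dca$curve
#' @export
decision_curve <- function(outcomes, probabilities,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- as.numeric(outcomes)
  p <- as.numeric(probabilities)
  if (length(y) != length(p))
    stop("outcomes and probabilities lengths differ", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary 0/1", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly between 0 and 1", call. = FALSE)
  n <- length(y)
  prev <- mean(y)
  nb <- function(pos) {
    tp <- sum(y == 1 & pos) / n
    fp <- sum(y == 0 & pos) / n
    function(pt) tp - fp * pt / (1 - pt)
  }
  nb_model <- vapply(thresholds,
                     function(pt) nb(p >= pt)(pt), numeric(1))
  nb_all <- vapply(thresholds,
                   function(pt) prev - (1 - prev) * pt / (1 - pt),
                   numeric(1))
  curve <- data.frame(threshold = thresholds, nb_model = nb_model,
                      nb_all = nb_all, nb_none = 0)
  structure(list(curve = curve, prevalence = prev, n = n),
            class = "dca_result")
}

#' @export
print.dca_result <- function(x, ...) {
  rng <- range(x$curve$threshold)
  pos <- x$curve$threshold[x$curve$nb_model > pmax(x$curve$nb_all, 0)]
  cat(sprintf(paste0("Decision curve: n = %d, event prevalence %.3f, ",
                     "thresholds %.2f-%.2f\n"), x$n, x$prevalence,
              rng[1], rng[2]))
  if (length(pos))
    cat(sprintf("  model beats both default policies for p_t in %.2f-%.2f\n",
                min(pos), max(pos)))
  invisible(x)
}

#' Plot a decision curve
#'
#' Net benefit of the model, treat-all and treat-none policies across the
#' threshold grid.
#'
#' @param x A `"dca_result"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dca_result <- function(x, ...) {
  cv <- x$curve
  ylim <- c(min(0, min(cv$nb_model)), max(cv$nb_model, cv$nb_all, 0.02))
  graphics::plot(cv$threshold, cv$nb_model, type = "l", ylim = ylim,
                 xlab = "Threshold probability", ylab = "Net benefit", ...)
  graphics::lines(cv$threshold, cv$nb_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", lty = c(1, 2, 3), bty = "n",
                   legend = c("model", "treat all", "treat none"))
  invisible(x)
}
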