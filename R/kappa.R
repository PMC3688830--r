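# Weighted kappa for ordinal agreement between two raters.  With quadratic
# ("squared") disagreement weights (i - j)^2, kappa equals 1 minus the
# ratio of observed to chance-expected weighted disagreement; the standard
# error is the large-sample Fleiss-Cohen-Everitt form.

#' Quadratic-weighted kappa between two raters
#'
#' Computes `kappa = 1 - sum(w * O) / sum(w * E)` where `O` is the joint
#' rating proportion matrix, `E` the product of its margins, and
#' `w[i, j] = (i - j)^2` for the `"squared"` scheme (or `0/1` off-diagonal
#' for `"unweighted"`, giving Cohen's kappa).  The category space defaults
#' to the full 1-9 score range even when some scores are unobserved, so
#' the expected matrix is always defined on the whole scale.
#'
#' The 95% CI is `kappa +/- 1.96 * SE` with the large-sample standard
#' error of the weighted kappa (Fleiss-Cohen-Everitt), computed on the
#' equivalent agreement-weight form `w_a = 1 - (i-j)^2 / (k-1)^2`.
#'
#' @param ratings_a,ratings_b Equal-length vectors of ordinal ratings,
#'   values drawn from `categories`.
#' @param categories Ordered category values; default the 1-9 score scale.
#' @param weights `"squared"` (default) or `"unweighted"`.
#' @return Object of class `"kappa_result"`: `kappa`, `ci_low`, `ci_high`,
#'   `se`, `weights` (scheme label), `weight_matrix` (disagreement
#'   weights, symmetric, zero diagonal), `observed` and `expected`
#'   (weighted-disagreement matrices, counts scale), `n`.
#' @examples
#' a <- c(1, 3, 5, 7, 9, 2, 4)
#' weighted_kappa(a, a)$kappa   # 1
#' @export
weighted_kappa <- function(ratings_a, ratings_b, categories = 1:9,
                           weights = c("squared", "unweighted")) {
  weights <- match.arg(weights)
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length", call. = FALSE)
  n <- length(ratings_a)
  if (n == 0L) stop("no ratings", call. = FALSE)
  ia <- match(ratings_a, categories)
  ib <- match(ratings_b, categories)
  if (anyNA(ia) || anyNA(ib))
    stop("ratings outside the declared category set", call. = FALSE)
  k <- length(categories)
  if (k < 2L) stop("need at least two categories", call. = FALSE)

  idx <- seq_len(k)
  wd <- outer(idx, idx, function(i, j) (i - j)^2)    # disagreement weights
  if (weights == "unweighted") wd <- (wd > 0) + 0
  wmax <- max(wd)
  wa <- 1 - wd / wmax                                # agreement weights

  O <- table(factor(ia, levels = idx), factor(ib, levels = idx))
  O <- matrix(as.numeric(O), k, k)
  P <- O / n
  pa <- rowSums(P); pb <- colSums(P)
  E <- outer(pa, pb)

  exp_dis <- sum(wd * E)
  if (exp_dis == 0) {
    warning("all ratings in a single category: kappa undefined",
            call. = FALSE)
    return(structure(list(kappa = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, se = NA_real_,
                          weights = weights, weight_matrix = wd,
                          observed = wd * O, expected = wd * E * n, n = n),
                     class = "kappa_result"))
  }
  kap <- 1 - sum(wd * P) / exp_dis

  # Fleiss-Cohen-Everitt variance on the agreement-weight form
  po <- sum(wa * P); pe <- sum(wa * E)
  wa_i <- drop(wa %*% pb)    # row-wise expected agreement weight
  wa_j <- drop(pa %*% wa)    # column-wise
  term <- outer(wa_i, wa_j, "+")
  v <- (sum(P * (wa - term * (1 - kap))^2) - (kap - pe * (1 - kap))^2) /
    (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))

  structure(list(kappa = kap,
                 ci_low = max(-1, kap - 1.96 * se),
                 ci_high = min(1, kap + 1.96 * se),
                 se = se, weights = weights, weight_matrix = wd,
                 observed = wd * O, expected = wd * E * n, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("%s-weighted kappa: %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$weights, x$kappa, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` on a contingency table of
#' counts, without continuity correction, with `df = (r - 1)(c - 1)` and
#' the p-value from the chi-square distribution.
#'
#' @param counts Matrix (or table) of non-negative counts, at least 2x2.
#' @return Object of class `"chisq_result"`: `statistic`, `df`, `p_value`,
#'   `expected`.
#' @examples
#' chi_square_test(rbind(c(72, 3), c(29, 13), c(11, 27)))
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  r <- rowSums(counts); c_ <- colSums(counts)
  if (any(r == 0) || any(c_ == 0))
    stop("zero row or column margin", call. = FALSE)
  E <- outer(r, c_) / sum(counts)
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = E),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
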