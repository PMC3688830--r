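# Independent oracles used across tests.

# O(n^2) pairwise AUC: concordant pairs + half the ties over all
# positive-negative pairs.
brute_force_auc <- function(score, outcome) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

# Patient-level data for a 2x2 exposure/outcome table
# (a = exposed events, b = exposed non-events, c = ref events, d = ref
# non-events), for feeding fit_logistic.
table_2x2_data <- function(a, b, c, d) {
  data.frame(exposed = rep(c(1, 1, 0, 0), c(a, b, c, d)),
             y = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}

# Unweighted Cohen's kappa computed directly from the definition.
cohens_kappa <- function(x, y, categories) {
  fx <- factor(x, levels = categories)
  fy <- factor(y, levels = categories)
  P <- table(fx, fy) / length(x)
  po <- sum(diag(P))
  pe <- sum(rowSums(P) * colSums(P))
  (po - pe) / (1 - pe)
}
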