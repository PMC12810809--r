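# Independent oracles: direct textbook formulas and brute-force
# enumeration, kept deliberately separate from the package's code paths.

# AUC by explicit enumeration of all positive-negative pairs
# (1 if pos > neg, 0.5 on ties).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Pearson r from the definition formula (sum of cross-products).
pearson_definition <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# OLS via explicit normal equations.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Youden J evaluated exhaustively at every candidate decision rule
# "score >= t" for t in the distinct observed scores; returns the best J
# and the highest threshold attaining it.
youden_bruteforce <- function(scores, labels) {
  best_j <- -Inf
  best_t <- NA_real_
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (j > best_j) {
      best_j <- j
      best_t <- t
    }
  }
  list(j = best_j, threshold = best_t)
}

# A random scores/labels fixture with ties likely (scores on a 0.1 mm grid).
random_roc_fixture <- function(n) {
  repeat {
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) == 2) break
  }
  list(scores = round(runif(n, 0, 20), 1), labels = labels)
}
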