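# Fixtures are built in code: small phantoms for fast tests, brute-force
# oracles for the classifier arithmetic.

small_spec <- function(..., noise_model = "none") {
  phantom_spec(
    grid_dim = c(32, 32, 12), lesion_center = c(9, 18, 6),
    lesion_semiaxes = c(3, 4, 2), noise_model = noise_model, ...
  )
}

tiny_spec <- function(..., noise_model = "none") {
  phantom_spec(
    grid_dim = c(24, 24, 10), lesion_center = c(7, 13, 5),
    lesion_semiaxes = c(2, 3, 2), noise_model = noise_model, ...
  )
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# constant-valued volume helper
vol <- function(value, d = c(4, 4, 2)) array(value, d)

# Pair-counting Mann-Whitney oracle for the AUC (ties count 1/2);
# scores already oriented so that higher = positive.
auc_oracle <- function(oriented, labels) {
  x <- oriented[labels == 1]; y <- oriented[labels == 0]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# Exhaustive threshold-scan oracle for the maximum Youden J.
youden_oracle <- function(scores, labels, direction) {
  cand <- sort(unique(c(scores, -Inf, Inf)))
  best <- -Inf
  for (c0 in cand) {
    pred <- if (direction == "below") scores <= c0 else scores >= c0
    tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
    fp <- sum(pred & labels == 0); tn <- sum(!pred & labels == 0)
    if (tp + fn > 0 && tn + fp > 0) {
      j <- tp / (tp + fn) + tn / (tn + fp) - 1
      best <- max(best, j)
    }
  }
  best
}
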