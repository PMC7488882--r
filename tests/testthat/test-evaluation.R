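test_that("correlations match closed forms and hand-computed ranks", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$estimate, 1)
  expect_equal(correlate(exp(x), x, "spearman")$estimate, 1)

  y <- c(10, 30, 20, 50, 40)  # ranks 1,3,2,5,4: sum d^2 = 4
  expect_equal(correlate(x, y, "spearman")$estimate, 1 - 6 * 4 / (5 * 24))  # 0.8
  expect_equal(correlate(x, y, "kendall")$estimate, (8 - 2) / 10)           # 0.6

  expect_error(correlate(rep(1, 5), y), class = "strokeclock_constant_input")
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  # perfectly separated
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0), direction = "above")
  expect_equal(r$auc, 1)
  # 3 of 4 concordant pairs
  r2 <- roc_auc(c(0.9, 0.4, 0.8, 0.3), c(1, 1, 0, 0), direction = "above")
  expect_equal(r2$auc, 0.75)
  # exhaustive small instances over a tied alphabet
  labels <- c(1, 1, 1, 0, 0, 0)
  grid <- as.matrix(expand.grid(rep(list(1:3), 6)))
  for (i in seq(1, nrow(grid), by = 7)) {
    s <- as.numeric(grid[i, ])
    expect_equal(roc_auc(s, labels, "above")$auc, auc_oracle(s, labels))
  }
  # random larger instances, both directions
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(6:20, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)
    expect_equal(roc_auc(s, lab, "below")$auc, auc_oracle(-s, lab))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), class = "strokeclock_single_class")
})

test_that("null scores give AUC near one half", {
  set.seed(77)
  r <- roc_auc(rnorm(2000), rbinom(2000, 1, 0.5), "below")
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_gt(r$p_value, 0.05)
})

test_that("DeLong AUC comparison: identity, pair counting, discrimination", {
  set.seed(5)
  n <- 40
  lab <- rep(c(1, 0), each = n / 2)
  perfect <- -lab + rnorm(n, 0, 0.01)     # low score = positive, nearly separable
  random <- rnorm(n)
  # classifier against itself
  self <- compare_aucs(list(a = random, b = random), lab, directions = "below")
  expect_equal(self$p, 1)
  # three classifiers -> three Bonferroni-adjusted pairwise tests
  three <- compare_aucs(list(a = perfect, b = random, c = rnorm(n)), lab, "below")
  expect_equal(nrow(three), 3L)
  expect_equal(three$p_adj, pmin(1, three$p * 3))
  # perfect vs random separates at the adjusted level
  pr <- three[three$classifier_a == "a" & three$classifier_b == "b", ]
  expect_lt(pr$p_adj, 0.05)

  expect_error(compare_aucs(list(a = perfect, b = random[-1]), lab),
               class = "strokeclock_unpaired")
})

test_that("DeLong test agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  n <- 60
  lab <- rbinom(n, 1, 0.45); lab[1:2] <- c(0, 1)
  s1 <- rnorm(n) - lab; s2 <- rnorm(n) - 0.5 * lab
  mine <- compare_aucs(list(a = s1, b = s2), lab, directions = "below")
  ref <- pROC::roc.test(pROC::roc(lab, -s1, direction = "<", quiet = TRUE),
                        pROC::roc(lab, -s2, direction = "<", quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p, as.numeric(ref$p.value), tolerance = 1e-10)
  expect_equal(mine$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
})

test_that("Youden cutoff maximizes J over all thresholds", {
  y <- youden_cutoff(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0), direction = "above")
  expect_equal(y$cutoff, 0.6)
  expect_equal(y$j, 1)

  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:15, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)
    dirn <- sample(c("below", "above"), 1)
    if (length(unique(s)) < 2) next
    expect_equal(youden_cutoff(s, lab, dirn)$j, youden_oracle(s, lab, dirn),
                 tolerance = 1e-12)
  }
})

test_that("Youden ties break toward classifying more patients as beyond", {
  # low-score positives with a gap: any cutoff in the gap has equal J;
  # the safety-oriented tie-break takes the most specific (smallest) one
  s <- c(1.0, 1.1, 1.4, 1.5)
  lab <- c(1, 1, 0, 0)
  y <- youden_cutoff(s, lab, direction = "below")
  expect_equal(y$j, 1)
  expect_equal(y$cutoff, (1.1 + 1.4) / 2)
  # cutoff interpretation: ratio <= cutoff => within window
  expect_equal(y$confusion$tp, 2); expect_equal(y$confusion$tn, 2)
})

test_that("diagnostic metrics reproduce printed predictive values", {
  m <- diagnostic_metrics(confusion_table(tp = 12, fp = 5, fn = 4, tn = 14))
  expect_equal(round(100 * m$value[m$metric == "ppv"], 2), 70.59)
  expect_equal(round(100 * m$value[m$metric == "npv"], 2), 77.78)
  expect_equal(m$value[m$metric == "sensitivity"], 12 / 16)

  m2 <- diagnostic_metrics(confusion_table(tp = 16, fn = 0, fp = 16, tn = 3))
  expect_equal(m2$value[m2$metric == "npv"], 1)
  expect_equal(m2$value[m2$metric == "ppv"], 0.5)

  perfect <- diagnostic_metrics(confusion_table(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_true(all(perfect$value == 1))
  expect_true(all(perfect$upper - perfect$lower == 0))

  # zero denominator flags the metric undefined instead of failing the rest
  m3 <- diagnostic_metrics(confusion_table(tp = 0, fp = 0, fn = 3, tn = 5))
  expect_true(m3$undefined[m3$metric == "ppv"])
  expect_false(m3$undefined[m3$metric == "accuracy"])
})

test_that("F1 score and its interval match the imbalanced-cohort arithmetic", {
  f <- f1_score(confusion_table(tp = 4, fp = 2, fn = 1, tn = 10))
  expect_equal(f$f1, 8 / 11)
  expect_equal(round(f$f1, 2), 0.73)
  expect_equal(round(unname(f$ci), 2), c(0.52, 0.94))

  expect_equal(f1_score(confusion_table(5, 0, 0, 5))$f1, 1)
  expect_equal(f1_score(confusion_table(0, 2, 3, 5))$f1, 0)
  expect_true(f1_score(confusion_table(0, 0, 0, 5))$undefined)
})

test_that("logistic models: symmetry, prevalence, separation, AICc bookkeeping", {
  tab <- data.frame(label = rep(c(0, 1), 10), x = 0)
  f0 <- fit_logistic(tab, character(0))
  expect_equal(f0$coefficients$beta[1], 0, tolerance = 1e-9)
  expect_equal(unique(round(f0$fitted, 9)), 0.5)

  set.seed(8)
  n <- 200
  x <- runif(n)
  tab2 <- data.frame(x = x, label = rbinom(n, 1, plogis(1 - 2 * x)))
  f2 <- fit_logistic(tab2, "x")
  expect_equal(mean(f2$fitted), mean(tab2$label), tolerance = 1e-9)
  expect_equal(f2$df, 1L)
  expect_gte(f2$chisq, 0)
  k <- 2
  expect_equal(f2$aicc, stats::AIC(f2$fit) + 2 * k * (k + 1) / (n - k - 1))

  sep <- data.frame(x = 1:10, label = as.integer(1:10 > 5))
  expect_error(fit_logistic(sep, "x"), class = "strokeclock_separation")
})

test_that("window probabilities follow the inverse logit", {
  expect_equal(predict_probability(list(intercept = 0), c(x = 1)), 0.5)
  p <- predict_probability(list(intercept = 18.3, coefficients = c(r = -17.13)),
                           c(r = 1.072))
  expect_equal(p, plogis(18.3 - 17.13 * 1.072), tolerance = 1e-12)
  expect_equal(round(p, 3), 0.484)
  # monotone decreasing in the ratio for negative slope
  grid <- seq(0.9, 1.3, by = 0.05)
  pg <- predict_probability(list(intercept = 18.3, coefficients = c(r = -17.13)), grid)
  expect_true(all(diff(pg) < 0))

  set.seed(4)
  tabf <- data.frame(x = runif(50), label = rbinom(50, 1, 0.5))
  fit <- fit_logistic(tabf, "x")
  expect_equal(predict_probability(fit, data.frame(x = 0.5)),
               plogis(sum(stats::coef(fit$fit) * c(1, 0.5))), tolerance = 1e-12)
})

test_that("precision-recall-gain curve and AUPRG behave per the gain algebra", {
  expect_equal(precision_gain(0.75, 0.5), 2 / 3)

  # single-threshold all-positive classifier sits at (recall gain 1, precision gain 0)
  pr <- prg_curve(rep(1, 8), c(1, 1, 1, 0, 0, 0, 0, 0), direction = "above")
  expect_equal(pr$auprg, 0)
  last <- nrow(pr$points)
  expect_equal(pr$points$recall_gain[last], 1)
  expect_equal(pr$points$precision_gain[last], 0)

  # perfect ranking scores exactly 1 and dominates every other ranking
  lab <- c(1, 1, 1, 0, 0, 0, 0, 0)
  perfect <- prg_curve(seq(8, 1), lab, direction = "above")
  expect_equal(perfect$auprg, 1)
  combos <- utils::combn(8, 3)
  vals <- apply(combos, 2, function(pos) {
    l <- rep(0, 8); l[pos] <- 1
    prg_curve(seq(8, 1), l, direction = "above")$auprg
  })
  expect_equal(max(vals), 1)
  expect_true(all(vals <= 1 + 1e-12))

  expect_error(prg_curve(1:4, rep(1, 4), "above"), class = "strokeclock_single_class")
})

test_that("random rankings have AUPRG near zero in expectation", {
  set.seed(55)
  lab <- c(rep(1, 16), rep(0, 19))
  v <- replicate(1000, prg_curve(rnorm(35), sample(lab), "below")$auprg)
  expect_lt(abs(mean(v)), 0.05)
})

test_that("free-marginal kappa follows (Po - 1/k) / (1 - 1/k)", {
  all_agree <- matrix("match", 6, 4)
  k1 <- free_marginal_kappa(all_agree, k = 3)
  expect_equal(k1$kappa, 1)
  expect_equal(k1$po, 1)

  expect_equal(free_marginal_kappa(po = 1 / 3, k = 3)$kappa, 0)
  expect_equal(round(free_marginal_kappa(po = 0.728, k = 3)$kappa, 2), 0.59)

  expect_error(free_marginal_kappa(po = 0.7, k = 1), class = "strokeclock_bad_input")

  # mixed table: Po is the mean pairwise agreement over items
  r <- rbind(c("match", "match", "match", "mismatch"),
             c("match", "match", "match", "match"))
  k2 <- free_marginal_kappa(r, k = 3)
  expect_equal(k2$po, mean(c(3 / 6, 1)))
})

test_that("majority adjudication resolves votes, ties and abstentions", {
  r <- rbind(c("match", "match", "match", "mismatch"),
             c("match", "match", "mismatch", "mismatch"),
             c("match", NA, NA, NA))
  arb <- c(NA, "mismatch", NA)
  out <- majority_adjudicate(r, arb)
  expect_equal(out, c("match", "mismatch", "match"))

  expect_error(majority_adjudicate(rbind(c("match", "mismatch", NA, NA))),
               class = "strokeclock_missing_arbitrator")
})
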