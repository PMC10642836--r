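urb3 <- c(3, 5); drb3 <- c(1, 2, 4)
lab5 <- rep(c("URB", "DRB"), c(2, 3))

test_that("the empirical ROC enumerates midpoint thresholds with endpoints", {
  roc <- roc_curve(c(urb3, drb3), lab5)
  expect_equal(nrow(roc), 6)
  at25 <- roc[roc$threshold == 2.5, ]
  expect_equal(at25$sensitivity, 1)
  expect_equal(at25$specificity, 2 / 3)
  # (0,1) and (1,0) endpoints present
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 0))
  expect_true(any(roc$sensitivity == 0 & roc$specificity == 1))

  perfect <- roc_curve(c(10, 11, 1, 2), rep(c("URB", "DRB"), each = 2))
  expect_true(any(perfect$sensitivity == 1 & perfect$specificity == 1))

  flat <- roc_curve(rep(4, 5), lab5)
  expect_equal(nrow(flat), 2)
})

test_that("AUC is the Mann-Whitney pair fraction", {
  expect_equal(auc(c(urb3, drb3), lab5), 5 / 6)
  expect_equal(auc(c(10, 11, 1, 2), rep(c("URB", "DRB"), each = 2)), 1)
  # complement identity under value negation
  set.seed(4)
  v <- rnorm(20); l <- rep(c("URB", "DRB"), 10)
  expect_equal(auc(v, l) + auc(-v, l), 1)
  # null calibration at large n
  set.seed(9)
  vbig <- rnorm(2000); lbig <- sample(rep(c("URB", "DRB"), 1000))
  expect_lt(abs(auc(vbig, lbig) - 0.5), 0.05)
  # ties count one half
  expect_equal(auc(c(1, 1), c("URB", "DRB")), 0.5)
  # agreement with an independent ROC implementation
  skip_if_not_installed("pROC")
  expect_equal(auc(v, l),
               as.numeric(pROC::auc(pROC::roc(l, v, levels = c("DRB", "URB"),
                                              direction = "<", quiet = TRUE))))
})

test_that("AUC equals the normalized rank-sum statistic across modules", {
  set.seed(17)
  a <- rnorm(11, 1); b <- rnorm(10)
  w <- mann_whitney(a, b)$statistic      # U counted from the first group
  expect_equal(auc(c(a, b), rep(c("URB", "DRB"), c(11, 10))),
               w / (11 * 10))
})

test_that("bootstrap validation is seeded, honest and class-preserving", {
  set.seed(30)
  v <- c(rnorm(10, 3), rnorm(10)); l <- rep(c("URB", "DRB"), each = 10)
  b1 <- bootstrap_auc(v, l, B = 300, seed = 7)
  b2 <- bootstrap_auc(v, l, B = 300, seed = 7)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_gte(b1$ci_low, 0.8)           # separable marker
  expect_gte(b1$attempts, 300)
  expect_true(b1$ci_low <= median(b1$boot_auc) &&
                median(b1$boot_auc) <= b1$ci_high)

  b3 <- bootstrap_auc(v, l, B = 1, seed = 2)
  expect_equal(b3$ci_low, b3$ci_high)
  expect_error(bootstrap_auc(v, l, B = 0), "at least 1")
  expect_error(bootstrap_auc(v, rep("URB", 20)), "both classes")
})

test_that("Youden cutoffs binarize markers on the informative side", {
  mk <- youden_cutoff(c(urb3, drb3), lab5)
  expect_equal(mk$cutoff, 2.5)
  expect_equal(mk$j, 2 / 3, tolerance = 1e-12)
  expect_equal(mk$direction, "up-in-URB")
  expect_equal(binarize_marker(mk, c(urb3, drb3)), c(1L, 1L, 0L, 0L, 1L))

  perfect <- youden_cutoff(c(10, 12, 1, 2), rep(c("URB", "DRB"), each = 2))
  expect_equal(perfect$j, 1)
  expect_equal(perfect$cutoff, 6)

  # a below-0.5 marker flips direction; binarization follows the event side
  flipped <- youden_cutoff(-c(urb3, drb3), lab5)
  expect_equal(flipped$direction, "down-in-URB")
  expect_equal(flipped$auc, 5 / 6)
  expect_equal(binarize_marker(flipped, -c(urb3, drb3)),
               c(1L, 1L, 0L, 0L, 1L))

  expect_error(youden_cutoff(rep(2, 5), lab5), "degenerate ROC")
})

test_that("composite scores sum binarized markers sample-wise", {
  b <- list(c(1, 0, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 1))
  s <- composite_score(b)
  expect_equal(as.integer(s), c(3, 1, 1, 1))
  expect_equal(attr(s, "n_markers"), 3)
  # permutation-invariant in marker order
  expect_equal(as.integer(composite_score(b[c(3, 1, 2)])), as.integer(s))
  expect_error(composite_score(list()), "empty marker panel")
  expect_error(composite_score(list(c(1, 0), c(1, 0, 1))), "disagree")

  # all markers perfect: scores only 0 or G, G exactly for URB
  lab <- rep(c("URB", "DRB"), c(3, 3))
  bin <- replicate(4, as.integer(lab == "URB"), simplify = FALSE)
  sp <- composite_score(bin)
  expect_setequal(unique(as.integer(sp)), c(0L, 4L))
  perf <- score_performance(sp, lab, threshold = 4)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  perf0 <- score_performance(sp, lab, threshold = 0)
  expect_equal(perf0$sensitivity, 1)
  expect_equal(perf0$specificity, 0)
})

test_that("a multi-marker panel is no worse than its best single marker", {
  sens_spec_sum <- numeric(0)
  for (seed in 1:20) {
    ds <- simulate_dataset(sim_config(seed = 400 + seed, n_endogenous = 60,
                                      n_reference = 6, de_fraction = 0.3,
                                      lfc_magnitude = 2,
                                      background_fraction = 0))
    norm <- normalize_pipeline(ds$counts)
    de <- run_de(norm$matrix, ds$annotations, norm$noise_calls)
    if (sum(de$significant) < 5) next
    panel <- select_markers(de, norm$matrix, ds$annotations, k = 5)
    best_single <- max(vapply(panel$markers, `[[`, numeric(1), "j"))
    sweep <- score_performance(panel$score, panel$labels, 3)$sweep
    best_panel <- max(sweep$sensitivity + sweep$specificity - 1)
    sens_spec_sum <- c(sens_spec_sum, best_panel - best_single)
  }
  expect_gte(mean(sens_spec_sum), 0)
})

test_that("the least-squares probability curve behaves like a calibrated sigmoid", {
  # symmetric scores with mirrored labels pin the midpoint at one half
  scores <- c(1, 5, 2, 4, 3, 3, 2, 4)
  labels <- c("DRB", "URB", "DRB", "URB", "DRB", "URB", "URB", "DRB")
  fit <- fit_probability_model(scores, labels)
  expect_equal(predict_probability(fit, 3), 0.5, tolerance = 1e-6)

  # the null model is one half everywhere
  null_model <- structure(list(a = 0, b = 0), class = "rbdge_prob_model")
  expect_equal(predict_probability(null_model, c(-10, 0, 42)), rep(0.5, 3))

  # separable scores saturate the two sides
  ssep <- c(0, 0, 0, 5, 5, 5)
  lsep <- rep(c("DRB", "URB"), each = 3)
  fsep <- fit_probability_model(ssep, lsep)
  expect_gte(predict_probability(fsep, 5), 0.99)
  expect_lte(predict_probability(fsep, 0), 0.01)
  expect_gt(fsep$b, 0)
  expect_lte(abs(fsep$b), 50)

  # monotone in the score when b > 0
  s <- seq(0, 5, by = 0.5)
  expect_true(all(diff(predict_probability(fsep, s)) > 0))

  # parameter recovery: predicted curve tracks the generating probabilities
  set.seed(55)
  S <- sample(0:5, 300, replace = TRUE)
  p_true <- 1 / (1 + exp(-(-2.5 + 1 * S)))
  y <- ifelse(runif(300) < p_true, "URB", "DRB")
  f2 <- fit_probability_model(S, y)
  expect_lte(mean(abs(predict_probability(f2, 0:5) -
                        1 / (1 + exp(-(-2.5 + 1 * 0:5))))), 0.1)

  expect_error(fit_probability_model(rep(2, 6), lsep), "distinct score")
  expect_error(fit_probability_model(ssep, rep("URB", 6)), "both classes")
})
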