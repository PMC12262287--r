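test_that("heuristic classification applies strict mean/variance cut-offs", {
  expect_equal(heuristic_classify(5, 20), "HSR-like")
  expect_equal(heuristic_classify(15, 100), "EC-like")
  expect_equal(heuristic_classify(10, 20), "EC-like")   # strict <
  expect_equal(heuristic_classify(5, 64), "EC-like")
})

test_that("threshold grid search maximizes accuracy with deterministic ties", {
  stats <- data.frame(mean = c(2, 4, 20, 30), variance = c(10, 20, 200, 300),
                      truth = c("HSR-like", "HSR-like", "EC-like", "EC-like"))
  best <- threshold_grid_search(stats, mean_grid = c(5, 10, 25),
                                var_grid = c(50, 150, 250))
  expect_equal(best$accuracy, 1.0)
  expect_equal(best$mean_cut, 5)    # smallest of the perfect cut-offs
  expect_equal(best$var_cut, 50)
  single <- threshold_grid_search(stats, 25, 250)
  expect_equal(single$accuracy, mean(c("HSR-like", "HSR-like", "HSR-like",
                                       "EC-like") == stats$truth))
  # brute-force recount on a seeded mixture
  set.seed(13)
  stats2 <- data.frame(mean = runif(40, 0, 30), variance = runif(40, 0, 300),
                       truth = sample(c("HSR-like", "EC-like"), 40, TRUE))
  best2 <- threshold_grid_search(stats2, c(5, 10, 15), c(64, 150))
  acc <- 0
  for (i in seq_len(40))
    acc <- acc + ((stats2$mean[i] < best2$mean_cut &&
                   stats2$variance[i] < best2$var_cut) ==
                  (stats2$truth[i] == "HSR-like"))
  expect_equal(best2$accuracy, acc / 40)
  expect_error(threshold_grid_search(stats, numeric(0), 1), "empty grid")
})

test_that("focal gate combination overrides or passes through", {
  post <- c("EC-amp" = 0.6, "HSR-amp" = 0.3, "no-amp" = 0.1)
  expect_equal(combine_focal_gate(post, "no-focal-amp")$hard_label, "no-amp")
  expect_equal(combine_focal_gate(post, "focal-amp")$hard_label, "EC-amp")
  expect_equal(combine_focal_gate(post, NULL)$hard_label, "EC-amp")
  expect_equal(combine_focal_gate(post, NULL)$source, "target_only")
  # focal-amp restricted to the amplified classes even when no-amp leads
  post2 <- c("EC-amp" = 0.2, "HSR-amp" = 0.3, "no-amp" = 0.5)
  expect_equal(combine_focal_gate(post2, "focal-amp")$hard_label, "HSR-amp")
})

test_that("bootstrap sample calls are seeded, reproducible and degenerate-safe", {
  all_ec <- rep("EC-amp", 40)
  d <- bootstrap_sample_call(all_ec, seed = 1)
  expect_equal(unname(d), c(1, 0, 0))
  d2 <- bootstrap_sample_call(all_ec, seed = 99)
  expect_equal(d, d2)                       # homogeneous input ignores seed
  mixed <- c(rep("EC-amp", 7), rep("HSR-amp", 3))
  expect_identical(bootstrap_sample_call(mixed, seed = 5),
                   bootstrap_sample_call(mixed, seed = 5))
})

test_that("bootstrap win fractions match the binomial oracle", {
  labels <- c(rep("EC-amp", 70), rep("HSR-amp", 30))
  d <- bootstrap_sample_call(labels, cells_per_draw = 10,
                             n_iterations = 4000, seed = 8)
  # EC wins when its draw count is >= 6, and half of the 5-5 ties
  p_oracle <- sum(dbinom(6:10, 10, 0.7)) + 0.5 * dbinom(5, 10, 0.7)
  se <- sqrt(p_oracle * (1 - p_oracle) / 4000)
  expect_lt(abs(d[["EC-amp"]] - p_oracle), 3 * se)
})

test_that("sample rule thresholds apply in order with inclusive boundaries", {
  frac <- function(ec = 0, hsr = 0, no = 0)
    c("EC-amp" = ec, "HSR-amp" = hsr, "no-amp" = no)
  expect_equal(sample_rule_call(frac(no = 1)), "no-amp")
  expect_equal(sample_rule_call(frac(0.45, 0.40, 0.15)), "heterogeneous")
  expect_equal(sample_rule_call(frac(0.50, 0.50, 0)), "EC-amp")
  expect_equal(sample_rule_call(frac(0.10, 0.80, 0.10)), "HSR-amp")
  expect_equal(sample_rule_call(frac(0.11, 0.79, 0.10)), "heterogeneous")
  expect_equal(sample_rule_call(frac(0.15, 0.05, 0.80)), "no-amp")
  expect_equal(sample_rule_call(frac(0.16, 0.05, 0.79)), "heterogeneous")
  expect_equal(sample_rule_call(frac(0.49, 0.41, 0.10)), "heterogeneous")
})

test_that("chi-square heterogeneity comparison matches the Pearson formula", {
  a <- c(ec = 10, hsr = 20); b <- c(ec = 20, hsr = 10)
  res <- heterogeneity_chisq(a, b)
  # hand-computed Pearson value on the 2x2 table (all margins 30)
  expect_equal(res$statistic, sum((c(10, 20, 20, 10) - 15)^2 / 15))
  expect_equal(res$df, 1L)
  same <- heterogeneity_chisq(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # classes empty in both samples are dropped from df
  a3 <- c(ec = 10, hsr = 20, no = 0); b3 <- c(ec = 20, hsr = 10, no = 0)
  expect_equal(heterogeneity_chisq(a3, b3)$df, 1L)
  expect_error(heterogeneity_chisq(c(0, 0), c(1, 2)), "no counts")
})

test_that("chi-square p-values agree with a multinomial Monte-Carlo oracle", {
  set.seed(31)
  a <- c(12, 18, 6); b <- c(20, 9, 7)
  res <- heterogeneity_chisq(a, b)
  # simulate tables under the pooled null with fixed row totals
  pool <- (a + b) / sum(a + b)
  n_sim <- 2000
  stats <- replicate(n_sim, {
    sa <- as.vector(rmultinom(1, sum(a), pool))
    sb <- as.vector(rmultinom(1, sum(b), pool))
    tab <- rbind(sa, sb)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - expd)^2 / expd, na.rm = TRUE)
  })
  p_mc <- mean(stats >= res$statistic)
  se <- sqrt(p_mc * (1 - p_mc) / n_sim)
  expect_lt(abs(res$p_value - p_mc), 3 * se + 0.01)
})

test_that("window predictions merge by mean posterior", {
  preds <- data.frame(nucleus_id = c(1, 1, 2),
                      "EC-amp" = c(0.6, 0.2, 0.1),
                      "HSR-amp" = c(0.3, 0.7, 0.2),
                      "no-amp" = c(0.1, 0.1, 0.7), check.names = FALSE)
  m <- combine_window_predictions(preds)
  expect_equal(nrow(m), 2L)
  expect_equal(m[m$nucleus_id == 1, "HSR-amp"], 0.5)
  expect_equal(m$hard_label, c("HSR-amp", "no-amp"))
})

test_that("the classifier harness overfits a separable toy set and is deterministic", {
  toy <- make_toy_patch_set(10, seed = 100)        # 20 patches
  cfg <- classifier_config(n_classes = 2L, hidden_units = 16L,
                           learning_rate = 0.05, max_epochs = 200L,
                           patience = 200L, feature_size = 8L, seed = 1L)
  model <- suppressWarnings(classifier_train(toy$patches, toy$labels, cfg))
  pred <- classifier_predict(model, toy$patches)
  expect_equal(mean(pred$hard_label == toy$labels), 1.0)
  # posteriors sum to one and argmax defines the hard label
  post <- as.matrix(pred[model$classes])
  expect_equal(unname(rowSums(post)), rep(1, 20), tolerance = 1e-9)
  expect_equal(pred$hard_label,
               model$classes[max.col(post, ties.method = "first")])
  # identical seed, identical model; repeated prediction identical
  model2 <- suppressWarnings(classifier_train(toy$patches, toy$labels, cfg))
  expect_identical(model$history, model2$history)
  expect_identical(classifier_predict(model, toy$patches[1]),
                   classifier_predict(model, toy$patches[1]))
  expect_error(classifier_train(toy$patches, rep("EC-amp", 20), cfg),
               "single class")
})

test_that("early stopping halts after the patience window", {
  toy <- make_toy_patch_set(6, seed = 7)
  cfg <- classifier_config(n_classes = 2L, hidden_units = 4L,
                           learning_rate = 1e-6,   # too small to improve
                           max_epochs = 150L, patience = 7L, seed = 2L)
  model <- suppressWarnings(classifier_train(toy$patches, toy$labels, cfg))
  expect_lt(length(model$history), 150L)
})

test_that("balanced sampling draws strata with equal expected weight", {
  set.seed(3)
  strata <- c(rep(1L, 100), rep(2L, 10))
  draws <- integer(2)
  for (i in 1:300)
    draws <- draws + tabulate(strata[balanced_stratum_indices(strata)], 2L)
  # every epoch draws exactly max-stratum-size from each stratum
  expect_equal(draws[1], draws[2])
  idx <- balanced_stratum_indices(strata)
  expect_length(idx, 200L)
  # minority observations are drawn far more often per capita
  expect_gt(mean(idx > 100), 0.45)
})
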