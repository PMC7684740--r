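# Prevalence-matched prediction: stratified sampling arithmetic, the case
# weighting identity, threshold selection, backends, hold-out metrics, and
# the no-leakage contract.

test_that("Wilson interval matches the closed form and the prop.test route", {
  ci <- wilson_ci(27, 100)
  expect_equal(unname(round(ci, 3)), c(0.193, 0.364))
  pt <- prop.test(27, 100, correct = FALSE)$conf.int
  expect_equal(unname(ci), as.numeric(pt), tolerance = 1e-10)
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
  expect_equal(unname(wilson_ci(10, 10)[2]), 1)
})

test_that("subsampling is stratified, sized and deterministic", {
  d <- make_records(1000, smoker = rep(c(TRUE, FALSE), c(200, 800)))
  s1 <- subsample_known(d, 0.3, seed = 4)
  expect_equal(nrow(s1), 300L)
  expect_lte(abs(sum(is_smoker(s1$smoking)) - 60), 1)
  expect_identical(s1, subsample_known(d, 0.3, seed = 4))
  expect_false(identical(s1$record_id, subsample_known(d, 0.3, seed = 5)$record_id))
  expect_identical(subsample_known(d, 1.0, seed = 1)$record_id, d$record_id)
  expect_error(subsample_known(d[1:400, ], 0.3, seed = 1), "below the minimum")
  d$smoking[1] <- "unknown"
  expect_error(subsample_known(d, 0.5, seed = 1), "known-status")
})

test_that("MNAR case weights hit the target prevalence exactly", {
  smoker <- rep(c(TRUE, FALSE), c(256, 744))
  w <- mnar_weights(smoker, 0.272)
  expect_equal(attr(w, "w_smoker"), (0.272 * 0.744) / (0.256 * 0.728))
  expect_equal(weighted.mean(smoker, w), 0.272)            # identity, not approximation
  expect_equal(unique(w[!smoker]), 1)
  expect_true(all(mnar_weights(smoker, mean(smoker)) == 1))  # p_target = p_sub
  w_dn <- mnar_weights(smoker, 0.1)                          # downweighting branch
  expect_lt(attr(w_dn, "w_smoker"), 1)
  expect_equal(weighted.mean(smoker, w_dn), 0.1)
  expect_error(mnar_weights(rep(TRUE, 5), 0.5), "degenerate class")
})

test_that("train/hold-out split is an exhaustive stratified partition", {
  d <- make_records(1000, smoker = rep(c(TRUE, FALSE), c(300, 700)))
  sp <- split_train_holdout(d, 0.7, seed = 2)
  expect_equal(nrow(sp$train), 700L)
  expect_equal(nrow(sp$holdout), 300L)
  expect_setequal(c(sp$train$record_id, sp$holdout$record_id), d$record_id)
  expect_length(intersect(sp$train$record_id, sp$holdout$record_id), 0)
  expect_lte(abs(mean(is_smoker(sp$train$smoking)) - 0.3), 1 / 700)
  expect_identical(sp, split_train_holdout(d, 0.7, seed = 2))
  expect_error(split_train_holdout(d[1:2, ], 0.1, seed = 1), "degenerate split")
})

test_that("the feature spec emits its fixed one-hot geometry", {
  d <- small_registry()
  spec <- build_feature_spec(d)
  expect_equal(spec$n_features, 53L)          # enumerated blocks; paper-era count differs
  x <- encode_features(d[1:200, ], spec)
  expect_equal(ncol(x), 53L)
  expect_true(all(rowSums(x) == length(spec$levels)))   # one level active per block
  # quartile boundaries are frozen in the spec, not recomputed per encoding
  probe <- d[1:3, ]
  probe$birth_weight_g <- c(spec$bw_breaks[1] - 1, spec$bw_breaks[1] + 1, 9999)
  xp <- encode_features(probe, spec)
  expect_equal(unname(xp[, "bw_quartile.q1"]), c(1, 0, 0))
  expect_equal(unname(xp[, "bw_quartile.q4"]), c(0, 0, 1))
  bad <- probe; bad$region <- "atlantis"
  expect_error(encode_features(bad, spec), "atlantis")
})

test_that("threshold selection matches the enumeration rule and its examples", {
  sc <- seq(0.05, 0.95, by = 0.1)
  thr <- select_threshold(sc, p_target = 0.3)
  expect_equal(thr$tau, 0.75)                 # three of ten scores at/above tau
  expect_equal(thr$achieved, 0.3)
  # everything classified positive when the target approaches 1
  expect_equal(select_threshold(sc, p_target = 0.999)$tau, 0.05)
  # raising the target weakly lowers the threshold
  taus <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                 function(p) select_threshold(sc, p_target = p)$tau, numeric(1))
  expect_true(all(diff(taus) <= 0))
  expect_warning(t0 <- select_threshold(rep(0.4, 8), p_target = 0.3), "identical")
  expect_equal(t0$tau, 0.4)
})

test_that("both backends separate a separable fixture perfectly", {
  d <- make_records(240, smoker = rep(c(TRUE, FALSE), 120))
  spec <- build_feature_spec(d)
  x <- encode_features(d, spec)
  y <- is_smoker(d$smoking)
  for (be in c("logistic", "nnet")) {
    clf <- train_annual_model(x, y, backend = be,
                              grid = list(size = c(2), decay = c(0.01)),
                              cv = list(folds = 3, repeats = 1), seed = 1)
    thr <- select_threshold(predict_prob(clf, x), p_target = 0.5)
    ev <- evaluate_holdout(clf, thr$tau, x, y)
    expect_equal(ev$accuracy, 1.0)
    expect_equal(ev$p_pred, 0.5)
    expect_true(ev$ci[["low"]] <= 0.5 && 0.5 <= ev$ci[["high"]])
  }
})

test_that("unit weights and identity MNAR weights give the same fit", {
  d <- make_records(300, smoker = rep(c(TRUE, FALSE), c(90, 210)))
  d$education <- sample(rep(c("primary", "medium", "high"), 100))  # add noise dims
  spec <- build_feature_spec(d)
  x <- encode_features(d, spec)
  y <- is_smoker(d$smoking)
  w_id <- mnar_weights(y, mean(y))
  f1 <- train_annual_model(x, y, weights = NULL, backend = "logistic", seed = 3)
  f2 <- train_annual_model(x, y, weights = as.numeric(w_id), backend = "logistic", seed = 3)
  expect_equal(f1$fit$beta, f2$fit$beta, tolerance = 1e-8)
})

test_that("run_annual_prediction is deterministic and never reads the truth column", {
  reg <- small_registry()
  y <- 2006
  d <- reg[reg$year == y, ]
  known <- d[is_known(d$smoking), ]
  unknown <- d[!is_known(d$smoking), ]
  r1 <- run_annual_prediction(known, unknown, p_target = 0.2, seed = 10, min_subset_n = 100)
  r2 <- run_annual_prediction(known, unknown, p_target = 0.2, seed = 10, min_subset_n = 100)
  expect_identical(r1, r2)
  known2 <- known; known2$true_smoking <- NULL
  unknown2 <- unknown; unknown2$true_smoking <- NULL
  r3 <- run_annual_prediction(known2, unknown2, p_target = 0.2, seed = 10, min_subset_n = 100)
  expect_identical(r1, r3)
  # weighted classified share on train sits at the target up to weight granularity
  expect_lt(abs(r1$train_classified - r1$p_target), 2 / r1$n_train)
  expect_true(r1$p_unknown_ci_low <= r1$p_unknown_pred &
                r1$p_unknown_pred <= r1$p_unknown_ci_high)
})

test_that("the pipeline records skips and per-year seeds", {
  reg <- small_registry()
  cal <- calibrate_all_years(reg)
  cal$p_target[1] <- NA; cal$note[1] <- "skipped: constructed"
  pred <- run_prediction_pipeline(reg, cal, base_seed = 5, min_subset_n = 100)
  expect_s3_class(pred, "annual_predictions")
  expect_equal(nrow(pred), nrow(cal))
  expect_match(pred$note[1], "constructed")
  done <- !is.na(pred$p_unknown_pred)
  expect_equal(pred$seed[done], 5L + pred$year[done])
  expect_true(all(pred$n_train[done] + pred$n_holdout[done] == pred$n_subset[done]))
})
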