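# Per-year prediction of smoking among unknown-status mothers:
# stratified subsample of the known group -> MNAR case weights -> 70/30
# train/hold-out split -> probabilistic classifier (weighted logistic
# regression or single-hidden-layer neural network selected by repeated
# stratified CV on weighted log-loss) -> prevalence-matched threshold ->
# hold-out validation -> predicted prevalence with Wilson CI in the unknown
# group.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return named numeric vector \code{c(low, high)}.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

stratified_take <- function(smoker, n_take, min_each = 0L) {
  # indices of a stratified SRSWOR of size n_take preserving the smoker share
  # to within one record
  n <- length(smoker)
  idx_s <- which(smoker); idx_n <- which(!smoker)
  n_s <- min(length(idx_s), max(min_each, round(n_take * length(idx_s) / n)))
  n_n <- n_take - n_s
  if (n_n > length(idx_n)) { n_n <- length(idx_n); n_s <- n_take - n_n }
  c(if (n_s > 0) sample(idx_s, n_s), if (n_n > 0) sample(idx_n, n_n))
}

#' Stratified subsample of known-status records
#'
#' Simple random sample without replacement of \code{round(fraction * n)}
#' records, stratified by (combined) smoking status so the subset prevalence
#' matches the year prevalence to within one record. Deterministic given
#' \code{seed}.
#'
#' @param records known-status registry rows for one year.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @param min_n smallest acceptable subset size (default 200); below this the
#'   annual model is not meaningfully trainable.
#' @return the sampled rows (original order preserved).
#' @export
subsample_known <- function(records, fraction = 0.3, seed = 1L, min_n = 200L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (any(!is_known(records$smoking)))
    stop("subsample_known() expects known-status records only", call. = FALSE)
  n_take <- round(fraction * nrow(records))
  if (n_take < min_n)
    stop(sprintf("subset of %d records is below the minimum of %d", n_take, min_n),
         call. = FALSE)
  smoker <- is_smoker(records$smoking)
  idx <- withr::with_seed(as.integer(seed), stratified_take(smoker, n_take))
  records[sort(idx), , drop = FALSE]
}

#' MNAR case weights
#'
#' Weights that make the weighted smoking prevalence of a subset equal the
#' MNAR target prevalence exactly: non-smokers get weight 1 and smokers get
#' \deqn{w = \frac{p_{target} (1 - p_{sub})}{p_{sub} (1 - p_{target})},}
#' the odds ratio between target and subset prevalence — the unique per-class
#' multiplicative scheme with that property.
#'
#' @param smoker logical vector (TRUE = smoker).
#' @param p_target target prevalence in (0, 1).
#' @return numeric weight vector; attribute \code{w_smoker} holds the smoker
#'   weight.
#' @export
mnar_weights <- function(smoker, p_target) {
  stopifnot(is.logical(smoker), p_target > 0, p_target < 1)
  p_sub <- mean(smoker)
  if (p_sub == 0 || p_sub == 1)
    stop("degenerate class: subset contains only ",
         if (p_sub == 1) "smokers" else "non-smokers", call. = FALSE)
  w_s <- p_target * (1 - p_sub) / (p_sub * (1 - p_target))
  w <- ifelse(smoker, w_s, 1)
  attr(w, "w_smoker") <- w_s
  w
}

#' Stratified train / hold-out split
#'
#' Disjoint and exhaustive partition, stratified by (combined) smoking status
#' so prevalence is preserved on both sides to within one record;
#' deterministic given \code{seed}.
#'
#' @param records known-status rows (typically the annual subset).
#' @param train_fraction proportion assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{holdout}.
#' @export
split_train_holdout <- function(records, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * nrow(records))
  if (n_train == 0L || n_train == nrow(records))
    stop("degenerate split: one side would be empty", call. = FALSE)
  smoker <- is_smoker(records$smoking)
  idx <- withr::with_seed(as.integer(seed) + 1L, stratified_take(smoker, n_train))
  list(train = records[sort(idx), , drop = FALSE],
       holdout = records[sort(setdiff(seq_len(nrow(records)), idx)), , drop = FALSE])
}

# Feature encoding ------------------------------------------------------------

#' Feature specification for the annual classifiers
#'
#' Fixed categorical blocks, each emitted as a full one-hot set: maternal age
#' group (4), parity group (3), marital status (2), education incl. missing
#' (4), country region (5), notification form (2), hospital (17), birth-weight
#' quartile (4), infant sex (2) and gestational-age group (10, incl. unknown).
#' Birth-weight quartile boundaries are computed from the records given here
#' (the year's known-status subset) and frozen for reuse on hold-out and
#' unknown-group records.
#'
#' @param records rows from which the birth-weight quartile boundaries are
#'   taken.
#' @return object of class \code{feature_spec}; \code{n_features} records the
#'   emitted indicator count.
#' @export
build_feature_spec <- function(records) {
  bw_breaks <- stats::quantile(records$birth_weight_g, c(0.25, 0.5, 0.75),
                               type = 7, names = FALSE)
  spec <- list(
    bw_breaks = bw_breaks,
    levels = list(
      age_group = c("le19", "20_29", "30_39", "ge40"),
      parity_group = c("p0", "p1", "p2plus"),
      marital_status = c("partnered", "single"),
      education = c("primary", "medium", "high", "missing"),
      region = c("nordic", "europe_non_nordic", "asia", "africa", "other"),
      form = c("paper", "electronic"),
      hospital_id = c("small_hospitals", sprintf("hosp_%02d", 1:16)),
      bw_quartile = c("q1", "q2", "q3", "q4"),
      infant_sex = c("female", "male"),
      ga_group = c("ga22_27", "ga28_36", "ga37", "ga38", "ga39", "ga40",
                   "ga41", "ga42", "ga43_46", "ga_unknown")
    )
  )
  spec$n_features <- sum(lengths(spec$levels))
  class(spec) <- "feature_spec"
  spec
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("feature spec: %d one-hot indicators over %d blocks; bw quartile breaks %s g\n",
              x$n_features, length(x$levels),
              paste(round(x$bw_breaks), collapse = "/")))
  invisible(x)
}

feature_level <- function(records, block, spec) {
  switch(block,
    age_group = cut(records$maternal_age_years, c(-Inf, 19, 29, 39, Inf),
                    labels = spec$levels$age_group),
    parity_group = cut(records$parity, c(-Inf, 0, 1, Inf),
                       labels = spec$levels$parity_group),
    marital_status = records$marital_status,
    education = records$education,
    region = records$region,
    form = records$form,
    hospital_id = records$hospital_id,
    bw_quartile = cut(records$birth_weight_g, c(-Inf, spec$bw_breaks, Inf),
                      labels = spec$levels$bw_quartile),
    infant_sex = records$infant_sex,
    ga_group = {
      g <- cut(records$ga_weeks, c(-Inf, 27, 36, 37, 38, 39, 40, 41, 42, Inf),
               labels = spec$levels$ga_group[1:9])
      g <- as.character(g)
      g[is.na(records$ga_weeks)] <- "ga_unknown"
      g
    })
}

#' Encode records as a one-hot feature matrix
#'
#' @param records registry rows.
#' @param spec a frozen [build_feature_spec()] object.
#' @return numeric matrix with \code{spec$n_features} columns named
#'   \code{block.level}; every record activates exactly one indicator per
#'   block.
#' @export
encode_features <- function(records, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  n <- nrow(records)
  cols <- vector("list", length(spec$levels))
  for (bi in seq_along(spec$levels)) {
    block <- names(spec$levels)[bi]
    lev <- spec$levels[[block]]
    val <- as.character(feature_level(records, block, spec))
    bad <- !val %in% lev & !is.na(val)
    if (any(bad))
      stop(sprintf("level '%s' of block '%s' is not in the feature spec",
                   val[bad][1], block), call. = FALSE)
    m <- matrix(0, n, length(lev), dimnames = list(NULL, paste(block, lev, sep = ".")))
    m[cbind(seq_len(n), match(val, lev))] <- 1
    cols[[bi]] <- m
  }
  do.call(cbind, cols)
}

# Classifier backends ---------------------------------------------------------

make_cv_folds <- function(y, k, repeats, seed) {
  # stratified fold assignments; every fold holds both classes whenever the
  # minority class has >= k members (else folds are rebuilt with fewer splits)
  withr::with_seed(as.integer(seed) + 2L, {
    k_eff <- min(k, max(2L, min(table(y))))
    lapply(seq_len(repeats), function(r) {
      f <- integer(length(y))
      for (cl in unique(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(k_eff), length(idx)))
      }
      f
    })
  })
}

weighted_log_loss <- function(y, p, w) {
  eps <- 1e-12
  p <- pmin(1 - eps, pmax(eps, p))
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

# Weighted logistic regression with a small ridge penalty (IRLS on the
# penalised score equations; the intercept is not penalised). The penalty
# keeps coefficients finite under the quasi-complete separation that one-hot
# cells with few smokers produce, so predicted risks stay strictly inside
# (0, 1) and remain distinct across covariate patterns — a prerequisite for a
# usable prevalence-matched threshold.
fit_logistic <- function(x, y, w, lambda = 1e-3, maxit = 50L, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda * sum(w), p - 1L)))
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(1 - 1e-6, max(1e-6, stats::weighted.mean(y, w))))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- w * mu * (1 - mu)
    grad <- crossprod(X, w * (y - mu)) - pen %*% beta
    hess <- crossprod(X, X * wt) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = drop(beta), lambda = lambda, iter = it)
}

predict_logistic <- function(fit, x) {
  as.numeric(stats::plogis(drop(cbind(1, x) %*% fit$beta)))
}

fit_nnet <- function(x, y, w, size, decay, seed) {
  withr::with_seed(as.integer(seed) + 3L,
    nnet::nnet(x, y, weights = w, size = size, decay = decay, entropy = TRUE,
               maxit = 200, MaxNWts = 5000, trace = FALSE))
}

#' Train the annual smoking classifier
#'
#' Two probabilistic backends. \code{"logistic"}: weighted logistic regression
#' on the one-hot features — deterministic, no tuning. \code{"nnet"}:
#' single-hidden-layer feed-forward network; hyperparameters (hidden units
#' from \code{grid$size}, weight decay from \code{grid$decay}) selected by
#' repeated stratified k-fold cross-validation minimising weighted log-loss,
#' then refit on all training rows. Case weights are the MNAR weights, so the
#' classifier is trained at the target prevalence.
#'
#' @param x one-hot feature matrix ([encode_features()]).
#' @param y numeric or logical smoking labels (1 = smoker).
#' @param weights case weights (default all 1).
#' @param backend \code{"logistic"} or \code{"nnet"}.
#' @param grid hyperparameter grid for the nnet backend.
#' @param cv list with \code{folds} and \code{repeats} (defaults 10 and 5).
#' @param seed integer seed controlling folds and network initialisation.
#' @return object of class \code{smoking_classifier} recording the backend,
#'   the fitted model, chosen hyperparameters and the CV score.
#' @export
train_annual_model <- function(x, y, weights = NULL,
                               backend = c("logistic", "nnet"),
                               grid = list(size = c(1, 3, 5),
                                           decay = c(0, 0.01, 0.1)),
                               cv = list(folds = 10, repeats = 5),
                               seed = 1L) {
  backend <- match.arg(backend)
  y <- as.numeric(y)
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(y) == nrow(x), length(weights) == length(y))
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)

  if (backend == "logistic") {
    fit <- fit_logistic(x, y, weights)
    clf <- list(backend = "logistic", fit = fit, chosen = NULL, cv_score = NA_real_,
                feature_names = colnames(x))
  } else {
    combos <- expand.grid(size = grid$size, decay = grid$decay)
    folds <- make_cv_folds(y, cv$folds, cv$repeats, seed)
    scores <- numeric(nrow(combos))
    for (ci in seq_len(nrow(combos))) {
      losses <- c()
      for (r in seq_along(folds)) {
        f <- folds[[r]]
        for (k in sort(unique(f))) {
          tr <- f != k
          if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
          fit_k <- fit_nnet(x[tr, , drop = FALSE], y[tr], weights[tr],
                            combos$size[ci], combos$decay[ci],
                            seed + 101L * ci + 7L * r + k)
          p_k <- as.numeric(stats::predict(fit_k, x[!tr, , drop = FALSE]))
          losses <- c(losses, weighted_log_loss(y[!tr], p_k, weights[!tr]))
        }
      }
      scores[ci] <- mean(losses)
    }
    best <- which.min(scores)
    fit <- fit_nnet(x, y, weights, combos$size[best], combos$decay[best], seed)
    clf <- list(backend = "nnet", fit = fit,
                chosen = list(size = combos$size[best], decay = combos$decay[best]),
                cv_score = scores[best], cv_table = cbind(combos, logloss = scores),
                feature_names = colnames(x))
  }
  class(clf) <- "smoking_classifier"
  clf
}

#' Predicted smoking probabilities from a trained classifier
#'
#' @param clf a [train_annual_model()] object.
#' @param x feature matrix encoded with the same frozen feature spec.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(clf, x) {
  stopifnot(inherits(clf, "smoking_classifier"))
  if (clf$backend == "logistic") predict_logistic(clf$fit, x)
  else as.numeric(stats::predict(clf$fit, x))
}

#' @export
print.smoking_classifier <- function(x, ...) {
  if (x$backend == "logistic") cat("smoking classifier: weighted logistic regression\n")
  else cat(sprintf("smoking classifier: nnet (size %d, decay %g), CV weighted log-loss %.4f\n",
                   x$chosen$size, x$chosen$decay, x$cv_score))
  invisible(x)
}

#' Prevalence-matched classification threshold
#'
#' The threshold is the largest cutoff \eqn{\tau} such that the weighted
#' fraction of scores at or above \eqn{\tau} is at least \code{p_target}
#' (ties broken toward the larger cutoff). With all scores identical the
#' threshold equals that score and a warning notes that the prevalence cannot
#' be matched.
#'
#' @param scores predicted probabilities on the training set.
#' @param weights case weights (default all 1).
#' @param p_target target prevalence in (0, 1).
#' @return list with \code{tau} and \code{achieved} (weighted classified
#'   prevalence at \code{tau}).
#' @export
select_threshold <- function(scores, weights = NULL, p_target) {
  stopifnot(p_target > 0, p_target < 1, all(scores >= 0), all(scores <= 1))
  if (is.null(weights)) weights <- rep(1, length(scores))
  cand <- sort(unique(scores), decreasing = TRUE)
  if (length(cand) == 1L) {
    warning("all scores identical; prevalence cannot be matched", call. = FALSE)
    return(list(tau = cand, achieved = 1))
  }
  tot <- sum(weights)
  frac <- vapply(cand, function(c) sum(weights[scores >= c]) / tot, numeric(1))
  ok <- which(frac >= p_target)
  tau <- if (length(ok)) cand[ok[1]] else cand[length(cand)]
  list(tau = tau, achieved = sum(weights[scores >= tau]) / tot)
}

#' Hold-out validation at the chosen threshold
#'
#' Accuracy is the unweighted fraction of hold-out records whose thresholded
#' classification matches the recorded combined smoker/non-smoker label; the
#' predicted prevalence is the fraction classified smoker, with a Wilson score
#' interval.
#'
#' @param clf trained classifier.
#' @param tau probability threshold.
#' @param x hold-out feature matrix.
#' @param smoker logical hold-out labels.
#' @param ci_level confidence level for the Wilson interval.
#' @return list with \code{accuracy}, \code{p_pred}, \code{ci}, \code{p_obs},
#'   \code{n}.
#' @export
evaluate_holdout <- function(clf, tau, x, smoker, ci_level = 0.95) {
  if (length(smoker) == 0L) stop("empty hold-out set", call. = FALSE)
  pred <- predict_prob(clf, x) >= tau
  list(accuracy = mean(pred == smoker),
       p_pred = mean(pred),
       ci = wilson_ci(sum(pred), length(pred), ci_level),
       p_obs = mean(smoker),
       n = length(pred))
}

#' Predicted smoking prevalence in the unknown-status group
#'
#' Fraction of unknown-status records classified smoker at the threshold,
#' with a Wilson score interval. Uses only the frozen feature encoding; the
#' latent truth column of synthetic data is never read.
#'
#' @param clf trained classifier.
#' @param tau probability threshold.
#' @param x_unknown feature matrix of the year's unknown-status records,
#'   encoded with the year's frozen feature spec.
#' @param ci_level confidence level.
#' @return list with \code{p_pred}, \code{ci}, \code{n}.
#' @export
predict_unknown_prevalence <- function(clf, tau, x_unknown, ci_level = 0.95) {
  n <- nrow(x_unknown)
  if (is.null(n) || n == 0L) stop("empty unknown group", call. = FALSE)
  pred <- predict_prob(clf, x_unknown) >= tau
  list(p_pred = mean(pred), ci = wilson_ci(sum(pred), n, ci_level), n = n)
}

# Orchestration ---------------------------------------------------------------

#' Run the full annual prediction for one year
#'
#' Subsample the known group, weight to the MNAR target, split 70/30, train,
#' pick the prevalence-matched threshold on the weighted training scores,
#' validate on the hold-out, and predict the prevalence in the unknown group.
#'
#' @param known known-status rows of the year.
#' @param unknown unknown-status rows of the year.
#' @param p_target MNAR target prevalence for the year.
#' @param backend,grid,cv passed to [train_annual_model()].
#' @param subset_fraction share of the known group used (default 0.3).
#' @param train_fraction share of the subset used for training (default 0.7).
#' @param seed integer seed for all stochastic steps of this year.
#' @param min_subset_n passed to [subsample_known()].
#' @param ci_level confidence level for the Wilson intervals.
#' @return one-row data.frame with the annual result fields (year left NA for
#'   the caller to fill).
#' @export
run_annual_prediction <- function(known, unknown, p_target,
                                  backend = "logistic",
                                  grid = list(size = c(1, 3, 5),
                                              decay = c(0, 0.01, 0.1)),
                                  cv = list(folds = 10, repeats = 5),
                                  subset_fraction = 0.3, train_fraction = 0.7,
                                  seed = 1L, min_subset_n = 200L,
                                  ci_level = 0.95) {
  subset <- subsample_known(known, subset_fraction, seed = seed, min_n = min_subset_n)
  smoker_sub <- is_smoker(subset$smoking)
  w_all <- mnar_weights(smoker_sub, p_target)
  parts <- split_train_holdout(subset, train_fraction, seed = seed)
  spec <- build_feature_spec(subset)

  in_train <- subset$record_id %in% parts$train$record_id
  x_train <- encode_features(parts$train, spec)
  y_train <- is_smoker(parts$train$smoking)
  w_train <- w_all[in_train]

  clf <- train_annual_model(x_train, y_train, weights = w_train,
                            backend = backend, grid = grid, cv = cv, seed = seed)
  thr <- select_threshold(predict_prob(clf, x_train), w_train, p_target)

  x_hold <- encode_features(parts$holdout, spec)
  hold <- evaluate_holdout(clf, thr$tau, x_hold, is_smoker(parts$holdout$smoking),
                           ci_level)
  unk <- predict_unknown_prevalence(clf, thr$tau, encode_features(unknown, spec),
                                    ci_level)
  data.frame(
    year = NA_integer_, n_subset = nrow(subset), n_train = nrow(parts$train),
    n_holdout = nrow(parts$holdout), n_unknown = unk$n, p_target = p_target,
    backend = backend,
    size = if (is.null(clf$chosen)) NA_integer_ else clf$chosen$size,
    decay = if (is.null(clf$chosen)) NA_real_ else clf$chosen$decay,
    tau = thr$tau, train_classified = thr$achieved,
    holdout_accuracy = hold$accuracy,
    p_holdout_obs = hold$p_obs, p_holdout_pred = hold$p_pred,
    p_holdout_ci_low = hold$ci[["low"]], p_holdout_ci_high = hold$ci[["high"]],
    p_unknown_pred = unk$p_pred,
    p_unknown_ci_low = unk$ci[["low"]], p_unknown_ci_high = unk$ci[["high"]],
    seed = as.integer(seed), stringsAsFactors = FALSE
  )
}

#' Run the prediction stage for every calibrated year
#'
#' One classifier per year, with per-year seed \code{base_seed + year}
#' (recorded in the output). Years whose calibration row carries a skip note
#' or whose groups are too small are skipped with a note.
#'
#' @param records flagged viable registry rows.
#' @param calibration a [calibrate_all_years()] table.
#' @inheritParams run_annual_prediction
#' @param base_seed integer; per-year seed is \code{base_seed + year}.
#' @return data.frame of class \code{annual_predictions}, one row per
#'   attempted year (skips carry a \code{note}).
#' @export
run_prediction_pipeline <- function(records, calibration,
                                    backend = "logistic",
                                    grid = list(size = c(1, 3, 5),
                                                decay = c(0, 0.01, 0.1)),
                                    cv = list(folds = 10, repeats = 5),
                                    subset_fraction = 0.3, train_fraction = 0.7,
                                    base_seed = 1L, min_subset_n = 200L,
                                    ci_level = 0.95) {
  rows <- lapply(seq_len(nrow(calibration)), function(i) {
    cal <- calibration[i, ]
    y <- cal$year
    skip <- function(msg) data.frame(year = y, note = msg, stringsAsFactors = FALSE)
    if (is.na(cal$p_target)) return(skip(cal$note))
    d <- records[records$year == y, , drop = FALSE]
    known <- d[is_known(d$smoking), , drop = FALSE]
    unknown <- d[!is_known(d$smoking), , drop = FALSE]
    if (nrow(unknown) == 0L) return(skip("no unknown-status records"))
    res <- tryCatch(
      run_annual_prediction(known, unknown, cal$p_target, backend = backend,
                            grid = grid, cv = cv,
                            subset_fraction = subset_fraction,
                            train_fraction = train_fraction,
                            seed = as.integer(base_seed) + y,
                            min_subset_n = min_subset_n, ci_level = ci_level),
      error = function(e) skip(paste("skipped:", conditionMessage(e))))
    res$year <- y
    res$note <- if (is.null(res$note)) "" else res$note
    res
  })
  out <- do.call(rbind, c(lapply(rows, pad_prediction_row), list(make.row.names = FALSE)))
  class(out) <- c("annual_predictions", "data.frame")
  out
}

pad_prediction_row <- function(row) {
  cols <- c("year", "n_subset", "n_train", "n_holdout", "n_unknown", "p_target",
            "backend", "size", "decay", "tau", "train_classified",
            "holdout_accuracy", "p_holdout_obs", "p_holdout_pred",
            "p_holdout_ci_low", "p_holdout_ci_high", "p_unknown_pred",
            "p_unknown_ci_low", "p_unknown_ci_high", "seed", "note")
  for (cn in setdiff(cols, names(row))) row[[cn]] <- NA
  row[, cols]
}

#' @export
print.annual_predictions <- function(x, ...) {
  cat("Annual prevalence-matched predictions\n")
  d <- as.data.frame(x)
  for (cn in c("p_target", "p_holdout_pred", "p_unknown_pred"))
    d[[cn]] <- round(100 * d[[cn]], 1)
  d$holdout_accuracy <- round(d$holdout_accuracy, 3)
  print(d[, c("year", "n_train", "p_target", "tau", "holdout_accuracy",
              "p_holdout_pred", "p_unknown_pred", "note")], row.names = FALSE)
  invisible(x)
}
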