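# Synthetic birth-registry generator: annual cohorts with a declining smoking
# trend, covariate-structured non-consent ("unknown smoking status"), and a
# tunable MNAR link between true smoking and missingness.

#' Configuration for the synthetic birth-registry generator
#'
#' Builds and validates the parameter set that [generate_registry()] consumes.
#' Defaults emulate a Nordic birth registry over 1999--2014: first-trimester
#' smoking prevalence declining from 26\% to 7\% (logit-linear), an
#' unknown-smoking-status share averaging ~14\% with a low of ~8\% (1999), a
#' peak of ~19\% (2007) and ~10\% by 2014, paper notification forms replaced by
#' electronic forms from 2005 onwards, and mean birth weights of 3536 g
#' (non-smokers), 3519 g (occasional) and 3428 g (daily smokers).
#'
#' Missingness follows a log-risk (exponential) model: per-record
#' \code{P(unknown) = exp(c_year + effects)}, clamped to (0, 0.95], where
#' \code{c_year} is calibrated so the annual marginal matches
#' \code{unknown_trend}. \code{mnar_delta} is the log-risk increment applied to
#' true smokers; 0 gives missingness-at-random given covariates.
#'
#' @param births_per_year positive integer, births generated per cohort year
#'   (at least 100).
#' @param years integer vector of cohort years (default 1999:2014).
#' @param smoking_trend per-year target marginal smoking prevalence (daily +
#'   occasional). Default: logit-linear from 0.26 at 1999 to 0.07 at 2014,
#'   evaluated at \code{years}.
#' @param occasional_share per-year share of occasional smokers among all
#'   smokers. Default: linear from 3/26 (1999) to 1/7 (2014).
#' @param smoking_effects named list of log-odds effects on smoking:
#'   \code{education}, \code{region}, \code{marital} (named vectors over the
#'   factor levels) and scalars \code{age_per_year} (centred at age 30) and
#'   \code{parity_per_birth}. The yearly intercept is solved numerically so the
#'   marginal prevalence matches \code{smoking_trend}.
#' @param bw_means_g named vector: mean birth weight (g) by true smoking class.
#' @param bw_sd_g residual SD of birth weight in grams (> 0).
#' @param bw_ga_slope birth-weight slope per gestational week (g), centred at
#'   the mean gestational age so class means stay at \code{bw_means_g}.
#' @param bw_sex_diff male minus female birth-weight difference (g), centred at
#'   \code{male_prob}.
#' @param ga_probs probabilities over gestational weeks 22--46 (normalised
#'   internally). Default mass centred at 39--40 weeks.
#' @param ga_unknown_rate share of records whose gestational age is recorded as
#'   unknown (NA).
#' @param unknown_trend per-year target marginal probability of unknown smoking
#'   status. Default follows the 8\% / 19\% / 10\% shape described above.
#' @param missingness_effects named list of log-risk effects on P(unknown):
#'   named vectors \code{form}, \code{region}, \code{hospital} over the factor
#'   levels (reference levels 0).
#' @param mnar_delta log-risk increment to P(unknown) for true smokers
#'   (0 = MAR given covariates). Default log(1.1), a mild MNAR scenario in
#'   line with cotinine-validation studies of non-reporting mothers.
#' @param repeat_mother_rate probability that a birth belongs to a mother
#'   already present in an earlier cohort (when such mothers are available);
#'   drives the cluster structure used by the mother-clustered variance.
#' @param nonviable_rate share of records emitted as non-viable (weight
#'   < 500 g and/or gestational age < 22 weeks); [exclude_nonviable()] removes
#'   them.
#' @param region_probs probabilities over country-region-of-origin levels.
#' @param education_by_region matrix of education-level probabilities
#'   (rows = regions, columns = primary/medium/high/missing).
#' @param hospital_probs probabilities over hospital levels (one pooled
#'   \code{small_hospitals} reference plus 16 named hospitals).
#' @param electronic_share per-year share of electronic notification forms.
#'   Default 0 before 2005 rising to 0.99 by 2014.
#' @param male_prob probability of a male infant.
#' @param single_prob probability of marital status "single".
#' @param age_mean,age_sd mean and SD of maternal age at a mother's first
#'   generated birth (years).
#' @param parity0_lambda Poisson mean of parity before a mother's first
#'   generated birth.
#'
#' @return A validated object of class \code{registry_config} (a list).
#' @seealso [generate_registry()], [exclude_nonviable()]
#' @export
registry_config <- function(births_per_year = 10000,
                            years = 1999:2014,
                            smoking_trend = NULL,
                            occasional_share = NULL,
                            smoking_effects = NULL,
                            bw_means_g = c(nonsmoker = 3536, occasional = 3519, daily = 3428),
                            bw_sd_g = 450,
                            bw_ga_slope = 110,
                            bw_sex_diff = 120,
                            ga_probs = NULL,
                            ga_unknown_rate = 0.005,
                            unknown_trend = NULL,
                            missingness_effects = NULL,
                            mnar_delta = log(1.1),
                            repeat_mother_rate = 0.42,
                            nonviable_rate = 0.002,
                            region_probs = NULL,
                            education_by_region = NULL,
                            hospital_probs = NULL,
                            electronic_share = NULL,
                            male_prob = 0.514,
                            single_prob = 0.11,
                            age_mean = 28,
                            age_sd = 5,
                            parity0_lambda = 0.7) {
  years <- as.integer(years)
  if (length(years) < 1L || anyNA(years)) stop("'years' must be a non-empty integer vector")
  ny <- length(years)

  if (is.null(smoking_trend)) {
    # logit-linear between the 1999 and 2014 anchors, evaluated at `years`
    f <- stats::approxfun(c(1999, 2014), stats::qlogis(c(0.26, 0.07)), rule = 2)
    smoking_trend <- stats::plogis(f(years))
  }
  if (is.null(occasional_share)) {
    f <- stats::approxfun(c(1999, 2014), c(3 / 26, 1 / 7), rule = 2)
    occasional_share <- f(years)
  }
  if (is.null(unknown_trend)) {
    f <- stats::approxfun(c(1999, 2001, 2003, 2005, 2007, 2009, 2011, 2014),
                          c(0.08, 0.11, 0.14, 0.15, 0.19, 0.17, 0.15, 0.10), rule = 2)
    unknown_trend <- f(years)
  }
  if (is.null(electronic_share)) {
    f <- stats::approxfun(c(2004, 2005, 2006, 2007, 2008, 2009, 2010, 2011, 2012, 2013, 2014),
                          c(0, 0.20, 0.40, 0.60, 0.70, 0.80, 0.85, 0.90, 0.93, 0.96, 0.99),
                          rule = 2)
    electronic_share <- pmax(0, f(years))
  }
  if (is.null(smoking_effects)) {
    # steep social gradients: smoking close to deterministic given education,
    # origin and marital status, which is what the classifier accuracies the
    # generator emulates (~0.95+) imply about the registry's feature set
    smoking_effects <- list(
      education = c(high = 0, medium = 4.0, primary = 8.0, missing = 3.0),
      region = c(nordic = 0, europe_non_nordic = -4.0, asia = -8.0,
                 africa = -9.0, other = -2.5),
      marital = c(partnered = 0, single = 5.0),
      age_per_year = -0.20,
      parity_per_birth = 0.6
    )
  }
  if (is.null(ga_probs)) {
    # weeks 22..46; preterm tail thin, mass at 38-41
    ga_probs <- c(rep(0.0004, 6), 0.002, 0.002, 0.003, 0.004, 0.005, 0.007,
                  0.010, 0.015, 0.025, 0.050, 0.130, 0.250, 0.270, 0.160,
                  0.055, 0.008, 0.0015, 0.0008, 0.0003)
  }
  if (length(ga_probs) != 25L) stop("'ga_probs' must have 25 entries (weeks 22..46)")
  ga_probs <- ga_probs / sum(ga_probs)

  if (is.null(region_probs)) {
    region_probs <- c(nordic = 0.838, europe_non_nordic = 0.059, asia = 0.063,
                      africa = 0.030, other = 0.010)
  }
  if (is.null(education_by_region)) {
    # education missingness concentrated outside the Nordic region
    education_by_region <- rbind(
      nordic            = c(primary = 0.18, medium = 0.38, high = 0.427, missing = 0.013),
      europe_non_nordic = c(primary = 0.20, medium = 0.30, high = 0.28,  missing = 0.22),
      asia              = c(primary = 0.25, medium = 0.25, high = 0.22,  missing = 0.28),
      africa            = c(primary = 0.30, medium = 0.25, high = 0.13,  missing = 0.32),
      other             = c(primary = 0.18, medium = 0.30, high = 0.42,  missing = 0.10)
    )
  }
  if (is.null(hospital_probs)) {
    hospital_probs <- c(small_hospitals = 0.25,
                        stats::setNames(c(0.10, 0.08, 0.07, 0.06, 0.06, 0.05, 0.05, 0.04,
                                          0.04, 0.04, 0.03, 0.03, 0.03, 0.03, 0.02, 0.02),
                                        sprintf("hosp_%02d", 1:16)))
  }
  if (is.null(missingness_effects)) {
    missingness_effects <- list(
      form = c(paper = 0, electronic = log(0.58)),
      region = c(nordic = 0, europe_non_nordic = log(1.15), asia = log(1.17),
                 africa = log(1.26), other = log(1.09)),
      hospital = c(small_hospitals = 0,
                   stats::setNames(log(c(2.40, 1.80, 1.50, 1.30, 1.15, 1.05, 0.95, 0.90,
                                         0.85, 0.80, 0.75, 0.70, 0.65, 0.55, 0.45, 0.40)),
                                   sprintf("hosp_%02d", 1:16)))
    )
  }

  cfg <- list(
    births_per_year = as.integer(births_per_year), years = years,
    smoking_trend = smoking_trend, occasional_share = occasional_share,
    smoking_effects = smoking_effects, bw_means_g = bw_means_g,
    bw_sd_g = bw_sd_g, bw_ga_slope = bw_ga_slope, bw_sex_diff = bw_sex_diff,
    ga_probs = ga_probs, ga_unknown_rate = ga_unknown_rate,
    unknown_trend = unknown_trend, missingness_effects = missingness_effects,
    mnar_delta = mnar_delta, repeat_mother_rate = repeat_mother_rate,
    nonviable_rate = nonviable_rate, region_probs = region_probs,
    education_by_region = education_by_region, hospital_probs = hospital_probs,
    electronic_share = electronic_share, male_prob = male_prob,
    single_prob = single_prob, age_mean = age_mean, age_sd = age_sd,
    parity0_lambda = parity0_lambda
  )
  class(cfg) <- "registry_config"
  validate_registry_config(cfg)
  cfg
}

validate_registry_config <- function(cfg) {
  check_prob_vec <- function(x, what, open = TRUE) {
    bad <- if (open) which(!(x > 0 & x < 1)) else which(!(x >= 0 & x <= 1))
    if (length(bad)) {
      nm <- if (!is.null(names(x))) names(x)[bad[1]] else as.character(bad[1])
      stop(sprintf("invalid configuration: %s[%s] = %g is outside the admissible range",
                   what, nm, x[bad[1]]), call. = FALSE)
    }
  }
  if (cfg$births_per_year < 100L) stop("'births_per_year' must be >= 100", call. = FALSE)
  if (!(cfg$bw_sd_g > 0)) stop("'bw_sd_g' must be > 0", call. = FALSE)
  for (nm in c("smoking_trend", "occasional_share", "unknown_trend")) {
    if (length(cfg[[nm]]) != length(cfg$years))
      stop(sprintf("'%s' must have one value per year", nm), call. = FALSE)
    check_prob_vec(cfg[[nm]], nm)
  }
  check_prob_vec(cfg$electronic_share, "electronic_share", open = FALSE)
  for (nm in c("region_probs", "hospital_probs")) {
    check_prob_vec(cfg[[nm]], nm, open = FALSE)
    if (abs(sum(cfg[[nm]]) - 1) > 1e-6)
      stop(sprintf("'%s' must sum to 1", nm), call. = FALSE)
  }
  if (any(abs(rowSums(cfg$education_by_region) - 1) > 1e-6))
    stop("rows of 'education_by_region' must sum to 1", call. = FALSE)
  for (p in c("ga_unknown_rate", "nonviable_rate", "male_prob", "single_prob",
              "repeat_mother_rate")) {
    v <- cfg[[p]]
    if (!(v >= 0 && v < 1)) stop(sprintf("'%s' = %g is outside [0, 1)", p, v), call. = FALSE)
  }
  # every covariate cell of the missingness model must admit a probability in
  # (0, 1): the largest combined effect times the largest annual target must
  # leave room under the 0.95 clamp used by the generator
  me <- cfg$missingness_effects
  max_lp <- max(me$form) + max(me$region) + max(me$hospital) + max(0, cfg$mnar_delta)
  worst <- max(cfg$unknown_trend) * exp(max_lp)
  if (worst >= 5) {
    stop(sprintf(paste0("invalid configuration: missingness cell (form=%s, region=%s, ",
                        "hospital=%s) implies risk ratio exp(%.2f) incompatible with the ",
                        "annual target %.2f"),
                 names(me$form)[which.max(me$form)],
                 names(me$region)[which.max(me$region)],
                 names(me$hospital)[which.max(me$hospital)],
                 max_lp, max(cfg$unknown_trend)), call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.registry_config <- function(x, ...) {
  cat("Synthetic registry configuration\n")
  cat(sprintf("  years: %d-%d (%d cohorts), births/year: %d\n",
              min(x$years), max(x$years), length(x$years), x$births_per_year))
  cat(sprintf("  smoking trend: %.1f%% -> %.1f%%; unknown-status trend: %.1f%% -> %.1f%%\n",
              100 * x$smoking_trend[1], 100 * x$smoking_trend[length(x$years)],
              100 * x$unknown_trend[1], 100 * x$unknown_trend[length(x$years)]))
  cat(sprintf("  MNAR log-risk increment for smokers: %.3f (RR %.2f)\n",
              x$mnar_delta, exp(x$mnar_delta)))
  invisible(x)
}

# Solve the yearly intercept of a mean-matched link: mean(link(c + lp)) = target.
solve_intercept <- function(lp, target, link) {
  f <- function(c) mean(link(c + lp)) - target
  stats::uniroot(f, lower = -20, upper = 5, tol = 1e-9)$root
}

sample_by_group <- function(group, levels_mat) {
  # draw one categorical value per element of `group` (rows of levels_mat)
  out <- character(length(group))
  for (g in rownames(levels_mat)) {
    idx <- which(group == g)
    if (length(idx))
      out[idx] <- sample(colnames(levels_mat), length(idx), replace = TRUE,
                         prob = levels_mat[g, ])
  }
  out
}

#' Generate a synthetic birth registry
#'
#' Draws \code{births_per_year} births for each configured cohort year.
#' Mothers can contribute several births across years (geometric-like
#' recurrence controlled by \code{repeat_mother_rate}), so the mother
#' identifier defines genuine clusters. True smoking class is assigned from a
#' logistic model on education, region, marital status, age and parity whose
#' yearly intercept is solved so the marginal prevalence matches the configured
#' trend; birth weight follows a normal model with smoking-class mean shifts, a
#' gestational-age slope and a sex offset; unknown smoking status follows a
#' log-risk model on form, region and hospital plus \code{mnar_delta} for true
#' smokers, with the yearly intercept solved against the configured
#' unknown-status trend.
#'
#' The returned table keeps the latent \code{true_smoking} column (never read
#' by any analysis stage) so that recovery of the smoking prevalence among
#' unknown-status records can be scored against ground truth.
#'
#' @param config a [registry_config()] object.
#' @param seed integer seed; the output is deterministic given
#'   \code{(config, seed)} and the caller's RNG state is left untouched.
#' @return A data.frame with one row per birth and columns \code{record_id},
#'   \code{mother_id}, \code{year}, \code{maternal_age_years}, \code{parity},
#'   \code{marital_status}, \code{education}, \code{region},
#'   \code{hospital_id}, \code{form}, \code{infant_sex}, \code{ga_weeks}
#'   (integer, NA when unknown), \code{birth_weight_g}, \code{smoking}
#'   (\code{nonsmoker}/\code{occasional}/\code{daily}/\code{unknown}) and
#'   \code{true_smoking}.
#' @export
generate_registry <- function(config, seed = 1L) {
  stopifnot(inherits(config, "registry_config"))
  validate_registry_config(config)
  withr::with_seed(as.integer(seed), generate_registry_impl(config))
}

generate_registry_impl <- function(cfg) {
  years <- cfg$years
  ga_weeks_all <- 22:46
  ga_mean <- sum(ga_weeks_all * cfg$ga_probs)
  eff <- cfg$smoking_effects
  me <- cfg$missingness_effects

  # mother pool, grown as new mothers appear
  pool <- new.env(parent = emptyenv())
  pool$region <- character(0); pool$education <- character(0)
  pool$hospital <- character(0); pool$age0 <- integer(0)
  pool$y0 <- integer(0); pool$y_last <- integer(0); pool$parity <- integer(0)

  out <- vector("list", length(years))
  rec_offset <- 0L

  for (i in seq_along(years)) {
    y <- years[i]
    n <- cfg$births_per_year

    eligible <- which(pool$y_last < y & (pool$age0 + (y - pool$y0)) <= 44L)
    n_rep <- min(length(eligible), stats::rbinom(1L, n, cfg$repeat_mother_rate))
    rep_idx <- if (n_rep > 0) sample(eligible, n_rep) else integer(0)
    n_new <- n - n_rep

    if (n_new > 0) {
      new_region <- sample(names(cfg$region_probs), n_new, replace = TRUE,
                           prob = cfg$region_probs)
      new_edu <- sample_by_group(new_region, cfg$education_by_region)
      new_hosp <- sample(names(cfg$hospital_probs), n_new, replace = TRUE,
                         prob = cfg$hospital_probs)
      new_age0 <- pmin(42L, pmax(16L, as.integer(round(stats::rnorm(n_new, cfg$age_mean, cfg$age_sd)))))
      new_par0 <- stats::rpois(n_new, cfg$parity0_lambda)
      first_new <- length(pool$region) + 1L
      pool$region <- c(pool$region, new_region)
      pool$education <- c(pool$education, new_edu)
      pool$hospital <- c(pool$hospital, new_hosp)
      pool$age0 <- c(pool$age0, new_age0)
      pool$y0 <- c(pool$y0, rep(y, n_new))
      pool$y_last <- c(pool$y_last, rep(y - 1L, n_new))  # updated below
      pool$parity <- c(pool$parity, new_par0)
      new_idx <- seq.int(first_new, length.out = n_new)
    } else new_idx <- integer(0)

    midx <- c(rep_idx, new_idx)
    midx <- midx[sample.int(length(midx))]  # interleave repeat and new mothers

    region <- pool$region[midx]
    education <- pool$education[midx]
    hospital <- pool$hospital[midx]
    age <- pool$age0[midx] + (y - pool$y0[midx])
    parity <- pool$parity[midx]
    pool$parity[midx] <- pool$parity[midx] + 1L
    pool$y_last[midx] <- y

    marital <- ifelse(stats::runif(n) < cfg$single_prob, "single", "partnered")
    form <- ifelse(stats::runif(n) < cfg$electronic_share[i], "electronic", "paper")
    sex <- ifelse(stats::runif(n) < cfg$male_prob, "male", "female")
    ga <- sample(ga_weeks_all, n, replace = TRUE, prob = cfg$ga_probs)
    ga_unknown <- stats::runif(n) < cfg$ga_unknown_rate

    # true smoking class
    lp_smk <- eff$education[education] + eff$region[region] + eff$marital[marital] +
      eff$age_per_year * (age - 30) + eff$parity_per_birth * parity
    b <- solve_intercept(lp_smk, cfg$smoking_trend[i], stats::plogis)
    smoker <- stats::runif(n) < stats::plogis(b + lp_smk)
    occ <- smoker & (stats::runif(n) < cfg$occasional_share[i])
    true_smoking <- ifelse(!smoker, "nonsmoker", ifelse(occ, "occasional", "daily"))

    # birth weight (drawn from the latent gestational age even when recorded NA)
    bw_mu <- cfg$bw_means_g[true_smoking] +
      cfg$bw_ga_slope * (ga - ga_mean) +
      cfg$bw_sex_diff * ((sex == "male") - cfg$male_prob)
    bw <- pmax(500, round(stats::rnorm(n, bw_mu, cfg$bw_sd_g)))

    # non-viable records (removed downstream by exclude_nonviable)
    nv <- which(stats::runif(n) < cfg$nonviable_rate)
    if (length(nv)) {
      low_ga <- nv[seq_len(ceiling(length(nv) / 2))]
      ga[low_ga] <- sample(20:21, length(low_ga), replace = TRUE)
      bw[nv] <- round(stats::runif(length(nv), 250, 499))
      ga_unknown[nv] <- FALSE
    }

    # unknown smoking status: log-risk model, clamped at 0.95
    lp_mis <- me$form[form] + me$region[region] + me$hospital[hospital] +
      cfg$mnar_delta * smoker
    cmis <- solve_intercept(lp_mis, cfg$unknown_trend[i],
                            function(z) pmin(exp(z), 0.95))
    unknown <- stats::runif(n) < pmin(exp(cmis + lp_mis), 0.95)
    smoking <- ifelse(unknown, "unknown", true_smoking)

    out[[i]] <- data.frame(
      record_id = sprintf("b%08d", rec_offset + seq_len(n)),
      mother_id = sprintf("m%07d", midx),
      year = y,
      maternal_age_years = as.integer(age),
      parity = as.integer(parity),
      marital_status = marital,
      education = education,
      region = region,
      hospital_id = hospital,
      form = form,
      infant_sex = sex,
      ga_weeks = ifelse(ga_unknown, NA_integer_, as.integer(ga)),
      birth_weight_g = as.numeric(bw),
      smoking = smoking,
      true_smoking = true_smoking,
      stringsAsFactors = FALSE
    )
    rec_offset <- rec_offset + n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove non-viable births
#'
#' Drops records with birth weight below 500 g or gestational age below 22
#' weeks (records with unknown gestational age are retained on the gestational
#' criterion). Order is preserved and the removal counts are attached and
#' reported.
#'
#' @param records a registry data.frame (see [generate_registry()]).
#' @param quiet suppress the message with removal counts.
#' @return The viable subset, with attribute \code{n_removed} holding the
#'   counts per rule.
#' @export
exclude_nonviable <- function(records, quiet = FALSE) {
  if (nrow(records) == 0L) return(records)
  low_weight <- records$birth_weight_g < 500
  low_ga <- !is.na(records$ga_weeks) & records$ga_weeks < 22
  keep <- !(low_weight | low_ga)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  counts <- c(low_weight = sum(low_weight), low_ga = sum(low_ga),
              removed = sum(!keep))
  attr(out, "n_removed") <- counts
  if (!quiet)
    message(sprintf("excluded %d non-viable records (%d weight < 500 g, %d gestational age < 22 w)",
                    counts[["removed"]], counts[["low_weight"]], counts[["low_ga"]]))
  out
}

#' Write / read a registry CSV
#'
#' Plain one-header-row CSV with the exact column set of
#' [generate_registry()]; the latent \code{true_smoking} column is included
#' only when \code{with_truth = TRUE}.
#'
#' @param records registry data.frame.
#' @param path output file path.
#' @param with_truth keep the latent \code{true_smoking} column.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(records, path, with_truth = FALSE) {
  if (!with_truth) records$true_smoking <- NULL
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Shared small helpers -------------------------------------------------------

#' Smoker / known-status indicators
#'
#' \code{is_smoker()} returns TRUE for daily or occasional smokers (the
#' combined definition used throughout), NA for unknown status;
#' \code{is_known()} flags records whose smoking status was provided.
#'
#' @param smoking character vector of smoking statuses.
#' @return logical vector.
#' @export
is_smoker <- function(smoking) {
  ifelse(smoking == "unknown", NA, smoking %in% c("occasional", "daily"))
}

#' @rdname is_smoker
#' @export
is_known <- function(smoking) smoking != "unknown"
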