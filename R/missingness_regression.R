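# Log-risk regression of unknown smoking status on demographic and
# administrative covariates, with mother-clustered sandwich variance.
# Exponentiated coefficients are relative risks (RRs) because the link is log.

risk_reference_levels <- list(
  form = "paper",
  region = "nordic",
  marital_status = "partnered",
  education = "medium",
  hospital_id = "small_hospitals",
  sga10 = "FALSE"
)

risk_model_frame <- function(records) {
  d <- data.frame(
    unknown = as.integer(!is_known(records$smoking)),
    maternal_age_years = records$maternal_age_years,
    parity = records$parity,
    year = records$year,
    mother_id = records$mother_id,
    stringsAsFactors = FALSE
  )
  for (v in names(risk_reference_levels)) {
    if (!v %in% names(records)) next
    x <- as.character(records[[v]])
    lev <- unique(c(risk_reference_levels[[v]], sort(unique(x))))
    d[[v]] <- factor(x, levels = lev)
  }
  d
}

#' Log-risk GLM for unknown smoking status with cluster-robust variance
#'
#' Fits a generalized linear model with log link for the binary outcome
#' "unknown smoking status" (1) versus known (0), and reports relative risks
#' with 95\% confidence intervals. The default family is Poisson with robust
#' variance (a standard risk-ratio estimator for binary outcomes); a
#' log-binomial family is available as an alternative. When
#' \code{cluster_by_mother} is TRUE the variance is the cluster-robust
#' sandwich grouped by \code{mother_id} (mothers contribute several births),
#' otherwise the model-based variance is used. Confidence limits are
#' \code{exp(log-RR +/- 1.96 SE)} (normal quantile; registry-scale n).
#'
#' Categorical covariates are dummy-coded against fixed reference levels:
#' paper form, Nordic origin, non-SGA, partnered, medium education, and the
#' pooled small-hospitals group. Age, parity and calendar year enter as
#' continuous terms. Missing education is an explicit \code{missing} level —
#' education missingness is concentrated among non-Nordic mothers, and
#' dropping those rows would distort the origin RRs.
#'
#' @param records registry rows (viable; an \code{sga10} column is required
#'   only if \code{"sga10"} is among \code{terms}).
#' @param terms character vector of covariate names, any of
#'   \code{maternal_age_years}, \code{parity}, \code{year}, \code{form},
#'   \code{region}, \code{sga10}, \code{marital_status}, \code{education},
#'   \code{hospital_id}, or \code{factor(year)} for year as a categorical
#'   term.
#' @param family \code{"poisson_log"} (default) or \code{"binomial_log"}.
#' @param cluster_by_mother use the mother-clustered sandwich variance.
#' @return Object of class \code{risk_model}: list with \code{terms} (table of
#'   term, level, reference flag, log-RR, cluster-robust SE, RR, CI bounds),
#'   \code{n_records}, \code{n_clusters}, \code{converged}, \code{family} and
#'   the underlying \code{fit}.
#' @export
fit_log_risk <- function(records,
                         terms = c("maternal_age_years", "parity", "year",
                                   "form", "region", "sga10",
                                   "marital_status", "education", "hospital_id"),
                         family = c("poisson_log", "binomial_log"),
                         cluster_by_mother = TRUE) {
  family <- match.arg(family)
  d <- risk_model_frame(records)
  if (length(unique(d$unknown)) < 2L)
    stop("degenerate outcome: smoking status is ",
         if (all(d$unknown == 0)) "known" else "unknown",
         " for every record; the log-risk model cannot converge", call. = FALSE)
  if ("factor(year)" %in% terms) {
    d$year <- factor(d$year)
    terms[terms == "factor(year)"] <- "year"
  }
  missing_terms <- setdiff(terms, names(d))
  if (length(missing_terms))
    stop("unknown model terms: ", paste(missing_terms, collapse = ", "), call. = FALSE)
  # single-level factors carry no contrast; drop them rather than fail
  droppable <- vapply(terms, function(v) is.factor(d[[v]]) &&
                        length(unique(as.character(d[[v]]))) < 2L, logical(1))
  terms <- terms[!droppable]

  fml <- stats::reformulate(terms, response = "unknown")
  fit <- switch(family,
    poisson_log = stats::glm(fml, data = d, family = stats::poisson(link = "log")),
    binomial_log = {
      # log-binomial fits are fragile; start from the poisson solution
      f0 <- stats::glm(fml, data = d, family = stats::poisson(link = "log"))
      start <- stats::coef(f0)
      start[is.na(start)] <- 0
      suppressWarnings(
        stats::glm(fml, data = d, family = stats::binomial(link = "log"),
                   start = start, control = stats::glm.control(maxit = 100)))
    })
  if (!fit$converged)
    stop(sprintf("log-risk model (%s) did not converge in %d IRLS iterations; deviance trace ends at %.4g",
                 family, fit$iter, fit$deviance), call. = FALSE)
  if (any(fit$fitted.values > 1))
    warning(sprintf("log link produced %d fitted risks > 1 (known log-link pathology); interpret affected cells with care",
                    sum(fit$fitted.values > 1)), call. = FALSE)

  vc <- if (cluster_by_mother) sandwich::vcovCL(fit, cluster = d$mother_id)
        else stats::vcov(fit)
  est <- stats::coef(fit)
  keep <- !is.na(est)
  se <- rep(NA_real_, length(est))
  se[keep] <- sqrt(diag(vc))[names(est)[keep]]

  tab <- data.frame(term = names(est), log_rr = unname(est), se = se,
                    stringsAsFactors = FALSE)
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  tab$rr <- exp(tab$log_rr)
  tab$ci_low <- exp(tab$log_rr - 1.96 * tab$se)
  tab$ci_high <- exp(tab$log_rr + 1.96 * tab$se)
  tab$reference <- FALSE

  # reference rows (RR = 1 by construction) for each categorical term
  for (v in intersect(terms, names(risk_reference_levels))) {
    ref <- levels(d[[v]])[1]
    tab <- rbind(tab,
                 data.frame(term = paste0(v, ref), log_rr = 0, se = NA_real_,
                            rr = 1, ci_low = NA_real_, ci_high = NA_real_,
                            reference = TRUE, stringsAsFactors = FALSE))
  }
  res <- list(terms = tab, n_records = nrow(d),
              n_clusters = length(unique(d$mother_id)),
              converged = fit$converged, family = family,
              cluster_by_mother = cluster_by_mother, fit = fit)
  class(res) <- "risk_model"
  res
}

#' @export
print.risk_model <- function(x, digits = 2, ...) {
  cat(sprintf("Log-risk model (%s), %d records, %d mothers, %s variance\n",
              x$family, x$n_records, x$n_clusters,
              if (x$cluster_by_mother) "mother-clustered robust" else "model-based"))
  tab <- x$terms[!x$terms$reference, ]
  cat(sprintf("  %-28s RR %5.*f (%.*f-%.*f)\n", tab$term, digits, tab$rr,
              digits, tab$ci_low, digits, tab$ci_high), sep = "")
  invisible(x)
}

#' Unadjusted and adjusted risk-ratio table
#'
#' Fits one single-term log-risk model per covariate (the "unadjusted" column)
#' and one full model over all covariates (the "adjusted" column), mirroring
#' the usual two-column registry presentation of factors associated with
#' unknown smoking status.
#'
#' @inheritParams fit_log_risk
#' @return data.frame with term, unadjusted RR and CI, adjusted RR and CI.
#' @export
risk_table <- function(records,
                       terms = c("maternal_age_years", "parity", "year",
                                 "form", "region", "sga10",
                                 "marital_status", "education", "hospital_id"),
                       family = "poisson_log", cluster_by_mother = TRUE) {
  adj <- fit_log_risk(records, terms, family = family,
                      cluster_by_mother = cluster_by_mother)
  out <- adj$terms[, c("term", "reference")]
  out$rr_adjusted <- adj$terms$rr
  out$ci_low_adjusted <- adj$terms$ci_low
  out$ci_high_adjusted <- adj$terms$ci_high
  out$rr_unadjusted <- NA_real_
  out$ci_low_unadjusted <- NA_real_
  out$ci_high_unadjusted <- NA_real_
  for (v in terms) {
    un <- fit_log_risk(records, v, family = family,
                       cluster_by_mother = cluster_by_mother)
    m <- match(un$terms$term, out$term)
    ok <- !is.na(m)
    out$rr_unadjusted[m[ok]] <- un$terms$rr[ok]
    out$ci_low_unadjusted[m[ok]] <- un$terms$ci_low[ok]
    out$ci_high_unadjusted[m[ok]] <- un$terms$ci_high[ok]
  }
  out[, c("term", "reference", "rr_unadjusted", "ci_low_unadjusted",
          "ci_high_unadjusted", "rr_adjusted", "ci_low_adjusted",
          "ci_high_adjusted")]
}
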