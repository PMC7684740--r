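# Small-for-gestational-age (SGA-10) reference construction and flagging.
# SGA-10 = birth weight strictly below the 10th percentile for infant sex and
# gestational week; used as a smoking-sensitive proxy when calibrating the
# MNAR target prevalence.

#' Build an empirical sex-by-gestational-week SGA-10 reference
#'
#' Computes the empirical 10th percentile of birth weight within each
#' (sex, gestational week) stratum. The quantile rule is linear interpolation
#' between order statistics (\code{stats::quantile} type 7) — stated explicitly
#' because quantile conventions differ across ecosystems. Strata with fewer
#' than \code{min_stratum_n} records are pooled with adjacent weeks toward
#' week 39 (the modal week) within the same sex, and the final cutoffs are
#' monotone-rearranged so they are nondecreasing in gestational week. Every
#' cutoff is floored at 500 g.
#'
#' National population standards are not redistributable, so the reference is
#' either built empirically from a user-chosen subset of records — the
#' recommended subset is known-status non-smokers, approximating an unexposed
#' standard, since smoking shifts the weight distribution and would contaminate
#' the reference — or supplied as a CSV via [read_sga_reference()].
#'
#' @param records registry rows with known \code{infant_sex}, non-missing
#'   \code{ga_weeks} and viable \code{birth_weight_g}; rows violating this are
#'   dropped with a message.
#' @param min_stratum_n smallest stratum size used without pooling (default 50).
#' @param provenance free-text note stored with the reference.
#' @return An object of class \code{sga_reference}: list with \code{cutoffs}
#'   (data.frame \code{sex}, \code{ga_weeks}, \code{cutoff_g},
#'   \code{stratum_n}), \code{min_stratum_n} and \code{provenance}.
#' @export
build_sga_reference <- function(records, min_stratum_n = 50,
                                provenance = "empirical") {
  ok <- !is.na(records$ga_weeks) & records$ga_weeks >= 22 &
    records$birth_weight_g >= 500 & records$infant_sex %in% c("female", "male")
  if (!all(ok)) {
    message(sprintf("dropping %d records without usable sex/gestational age/weight",
                    sum(!ok)))
    records <- records[ok, , drop = FALSE]
  }
  if (nrow(records) == 0L)
    stop("no usable records to build an SGA reference from", call. = FALSE)

  rows <- list()
  for (sx in sort(unique(records$infant_sex))) {
    w <- records$birth_weight_g[records$infant_sex == sx]
    g <- records$ga_weeks[records$infant_sex == sx]
    weeks <- sort(unique(g))
    counts <- as.integer(table(factor(g, levels = weeks)))
    if (sum(counts) < min_stratum_n)
      stop(sprintf("reference construction failed: only %d records for sex '%s' (< min_stratum_n = %d) even after pooling",
                   sum(counts), sx, min_stratum_n), call. = FALSE)

    # contiguous pooling toward week 39: repeatedly merge the smallest
    # undersized group with its neighbour on the side closer to 39
    groups <- as.list(seq_along(weeks))
    repeat {
      sizes <- vapply(groups, function(ix) sum(counts[ix]), integer(1))
      small <- which(sizes < min_stratum_n)
      if (!length(small)) break
      j <- small[which.min(sizes[small])]
      centre <- vapply(groups, function(ix) mean(weeks[ix]), numeric(1))
      if (length(groups) == 1L) break
      if (j == 1L) k <- 2L
      else if (j == length(groups)) k <- j - 1L
      else k <- if (centre[j] < 39) j + 1L else j - 1L
      groups[[min(j, k)]] <- c(groups[[min(j, k)]], groups[[max(j, k)]])
      groups[[max(j, k)]] <- NULL
    }

    cut_g <- numeric(length(weeks)); n_g <- integer(length(weeks))
    for (ix in groups) {
      q <- stats::quantile(w[g %in% weeks[ix]], probs = 0.10, type = 7,
                           names = FALSE)
      cut_g[ix] <- max(500, q)
      n_g[ix] <- sum(counts[ix])
    }
    # monotone rearrangement: nondecreasing in gestational week
    cut_g <- sort(cut_g)
    rows[[sx]] <- data.frame(sex = sx, ga_weeks = weeks, cutoff_g = cut_g,
                             stratum_n = n_g, stringsAsFactors = FALSE)
  }
  ref <- list(cutoffs = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              min_stratum_n = as.integer(min_stratum_n),
              provenance = provenance)
  class(ref) <- "sga_reference"
  ref
}

#' @export
print.sga_reference <- function(x, ...) {
  cat(sprintf("SGA-10 reference (%s): %d sex x week cutoffs, min stratum n = %d\n",
              x$provenance, nrow(x$cutoffs), x$min_stratum_n))
  invisible(x)
}

#' Flag small-for-gestational-age (SGA-10) births
#'
#' TRUE iff birth weight is strictly below the reference cutoff for the
#' record's sex and gestational week (weight exactly at the cutoff is not
#' SGA). Records with unknown gestational age cannot be flagged and return
#' FALSE; their count is reported. Gestational weeks outside the reference
#' range for a sex are mapped to the nearest covered week, consistent with the
#' pooling used at construction.
#'
#' @param records registry rows (needs \code{infant_sex}, \code{ga_weeks},
#'   \code{birth_weight_g}).
#' @param ref an [build_sga_reference()] object.
#' @param quiet suppress the unknown-gestational-age count message.
#' @return Logical vector, one entry per record.
#' @export
flag_sga <- function(records, ref, quiet = FALSE) {
  stopifnot(inherits(ref, "sga_reference"))
  n <- nrow(records)
  out <- logical(n)
  unk <- is.na(records$ga_weeks)
  if (any(unk) && !quiet)
    message(sprintf("%d records with unknown gestational age left unflagged", sum(unk)))
  for (sx in unique(records$infant_sex[!unk])) {
    tab <- ref$cutoffs[ref$cutoffs$sex == sx, ]
    if (nrow(tab) == 0L)
      stop(sprintf("sex '%s' absent from the SGA reference", sx), call. = FALSE)
    idx <- which(!unk & records$infant_sex == sx)
    wk <- pmin(max(tab$ga_weeks), pmax(min(tab$ga_weeks), records$ga_weeks[idx]))
    cut <- tab$cutoff_g[match(wk, tab$ga_weeks)]
    if (anyNA(cut)) { # interior week missing from reference: nearest covered week
      for (j in which(is.na(cut))) {
        k <- which.min(abs(tab$ga_weeks - wk[j]))
        cut[j] <- tab$cutoff_g[k]
      }
    }
    out[idx] <- records$birth_weight_g[idx] < cut
  }
  out
}

#' Attach an \code{sga10} column to registry rows
#'
#' Convenience wrapper: builds (or reuses) a reference and adds the SGA flag
#' used by the calibration and regression stages. By default the reference is
#' built from known-status non-smokers.
#'
#' @param records viable registry rows.
#' @param ref optional prebuilt [build_sga_reference()] object.
#' @param min_stratum_n passed to [build_sga_reference()].
#' @return \code{records} with a logical \code{sga10} column; the reference is
#'   attached as attribute \code{sga_reference}.
#' @export
add_sga_flags <- function(records, ref = NULL, min_stratum_n = 50) {
  if (is.null(ref)) {
    base <- records[is_known(records$smoking) & records$smoking == "nonsmoker", ,
                    drop = FALSE]
    ref <- build_sga_reference(base, min_stratum_n = min_stratum_n,
                               provenance = "empirical: known-status nonsmokers")
  }
  records$sga10 <- flag_sga(records, ref, quiet = TRUE)
  attr(records, "sga_reference") <- ref
  records
}

#' Write / read an SGA reference CSV
#'
#' Columns \code{sex}, \code{ga_weeks}, \code{cutoff_g} (plus
#' \code{stratum_n} when available).
#'
#' @param ref an \code{sga_reference} object.
#' @param path file path.
#' @return \code{path} (write) or an \code{sga_reference} object (read).
#' @export
write_sga_reference <- function(ref, path) {
  utils::write.csv(ref$cutoffs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sga_reference
#' @export
read_sga_reference <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "ga_weeks", "cutoff_g")
  if (!all(need %in% names(tab)))
    stop("SGA reference CSV must have columns sex, ga_weeks, cutoff_g", call. = FALSE)
  if (is.null(tab$stratum_n)) tab$stratum_n <- NA_integer_
  ref <- list(cutoffs = tab[, c(need, "stratum_n")],
              min_stratum_n = NA_integer_, provenance = "user-supplied table")
  class(ref) <- "sga_reference"
  ref
}
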