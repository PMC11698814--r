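# Non-parametric tolerance limits and Equivalent Score bands.
#
# The outer tolerance limit (oTL) is the largest order statistic that is,
# with the requested confidence, below the coverage_p-th population
# quantile; the inner limit (iTL) is the smallest order statistic above it.
# Ranks come from exact binomial tail sums -- no normal approximation.
# Adjusted scores at or below the oTL are "abnormal" (ES 0); scores above
# the sample median are ES 4; the ranks strictly between define ES 1-3.

#' Order-statistic ranks for one-sided non-parametric tolerance limits
#'
#' `outer_rank` is the largest rank `r >= 1` such that
#' `P(Binomial(n, coverage_p) <= r - 1) <= 1 - confidence`; `inner_rank` is
#' the smallest rank with that CDF at least `confidence`.  Both use the
#' exact binomial distribution function.
#'
#' @param n Sample size.
#' @param coverage_p Population fraction to bound (default 0.05, the 5th
#'   centile).
#' @param confidence Confidence level (default 0.95).
#' @return List with `outer_rank` and `inner_rank` (1-based).
#' @examples
#' tl_ranks(522)
#' @export
tl_ranks <- function(n, coverage_p = 0.05, confidence = 0.95) {
  stopifnot_scalar_number(n, "n")
  stopifnot_scalar_number(coverage_p, "coverage_p")
  stopifnot_scalar_number(confidence, "confidence")
  n <- as.integer(n)
  if (coverage_p <= 0 || coverage_p >= 1 || confidence <= 0 ||
      confidence >= 1) {
    stop("coverage_p and confidence must lie in (0, 1)", call. = FALSE)
  }
  # feasibility: rank 1 requires P(X = 0) <= 1 - confidence
  if (stats::pbinom(0, n, coverage_p) > 1 - confidence + 1e-12) {
    n_min <- ceiling(log(1 - confidence) / log(1 - coverage_p))
    stop(sprintf(paste0("no feasible outer tolerance rank for n = %d ",
                        "(need n >= %d at coverage %.3g, confidence %.3g)"),
                 n, n_min, coverage_p, confidence), call. = FALSE)
  }
  # a tiny tolerance absorbs floating-point dust in the exact tail sums
  # (e.g. P(X <= 5) for n = 11, p = 1/2 is exactly 1/2)
  eps <- 1e-12
  cdf <- stats::pbinom(0:(n - 1), n, coverage_p)  # cdf[r] = P(X <= r - 1)
  outer_rank <- max(which(cdf <= 1 - confidence + eps))
  inner_rank <- min(which(cdf >= confidence - eps))
  list(outer_rank = outer_rank, inner_rank = inner_rank)
}

#' Compute outer and inner tolerance limits of adjusted scores
#'
#' Sorts the adjusted scores ascending and reads the values at the
#' [tl_ranks()] order statistics; ties are kept as-is (ranks index the
#' sorted multiset).
#'
#' @param adjusted Numeric vector of adjusted scores.
#' @inheritParams tl_ranks
#' @return An object of class `tolerance_limits` with fields `n`,
#'   `coverage_p`, `confidence`, `outer_rank`, `inner_rank`, `otl`, `itl`.
#' @export
compute_tls <- function(adjusted, coverage_p = 0.05, confidence = 0.95) {
  adjusted <- as.numeric(adjusted)
  if (anyNA(adjusted)) stop("adjusted scores contain NA", call. = FALSE)
  rk <- tl_ranks(length(adjusted), coverage_p, confidence)
  srt <- sort(adjusted)
  out <- list(n = length(adjusted), coverage_p = coverage_p,
              confidence = confidence,
              outer_rank = rk$outer_rank, inner_rank = rk$inner_rank,
              otl = srt[rk$outer_rank], itl = srt[rk$inner_rank])
  class(out) <- "tolerance_limits"
  out
}

#' @export
print.tolerance_limits <- function(x, ...) {
  cat(sprintf(
    "Non-parametric tolerance limits (n = %d, coverage %.3g, confidence %.3g)\n",
    x$n, x$coverage_p, x$confidence))
  cat(sprintf("  oTL = %.4g (rank %d), iTL = %.4g (rank %d)\n",
              x$otl, x$outer_rank, x$itl, x$inner_rank))
  invisible(x)
}

#' Derive Equivalent Score bands from adjusted scores
#'
#' Builds the 5-level Equivalent Score thresholds: `t0` is the outer
#' tolerance limit (ES 0, "abnormal", at or below it), `t3` the sample
#' median (ES 4, "normal", strictly above it; for even `n` the median is
#' the lower of the two middle order statistics so that "above the median"
#' has an exact sample meaning).  The default `"rank"` method places `t1`
#' and `t2` at the observed values that split the ranks strictly between
#' the outer rank and the median rank into three equal-count bins
#' (remainders to the lower bins).  The `"zscore"` method instead spaces
#' the inner thresholds equally on the z-score scale between the oTL and
#' the median.
#'
#' @param adjusted Numeric vector of adjusted scores (the same vector the
#'   limits were computed on).
#' @param tls A `tolerance_limits` object from [compute_tls()].
#' @param method `"rank"` (default) or `"zscore"`.
#' @return An `es_bands` object with `thresholds` `(t0, t1, t2, t3)`.
#' @export
es_bands <- function(adjusted, tls, method = c("rank", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(tls, "tolerance_limits"))
  adjusted <- as.numeric(adjusted)
  if (length(adjusted) != tls$n) {
    stop("`adjusted` must be the vector the tolerance limits were computed on",
         call. = FALSE)
  }
  srt <- sort(adjusted)
  n <- tls$n
  med_rank <- floor((n + 1) / 2)  # lower middle order statistic for even n
  k <- med_rank - tls$outer_rank
  if (k < 3L) {
    stop("degenerate bands: fewer than 3 ranks between the outer tolerance ",
         "limit and the median", call. = FALSE)
  }
  t0 <- tls$otl
  t3 <- srt[med_rank]
  if (method == "rank") {
    base <- k %/% 3L
    rem <- k %% 3L
    size1 <- base + (rem >= 1L)
    size2 <- base + (rem >= 2L)
    t1 <- srt[tls$outer_rank + size1]
    t2 <- srt[tls$outer_rank + size1 + size2]
  } else {
    mu <- mean(adjusted)
    sdv <- stats::sd(adjusted)
    z0 <- (t0 - mu) / sdv
    z3 <- (t3 - mu) / sdv
    t1 <- mu + (z0 + (z3 - z0) / 3) * sdv
    t2 <- mu + (z0 + 2 * (z3 - z0) / 3) * sdv
  }
  thresholds <- c(t0 = t0, t1 = t1, t2 = t2, t3 = unname(t3))
  if (any(diff(thresholds) <= 0)) {
    warning("tied Equivalent Score thresholds: an intermediate band is ",
            "empty (collapsed by ties in the adjusted scores)",
            call. = FALSE)
  }
  new_es_bands(thresholds, method = method, n = n)
}

new_es_bands <- function(thresholds, method = "rank", n = NA_integer_) {
  stopifnot(length(thresholds) == 4L, !is.unsorted(thresholds))
  out <- list(thresholds = stats::setNames(as.numeric(thresholds),
                                           c("t0", "t1", "t2", "t3")),
              labels = c("abnormal", "borderline", "low-end normal",
                         "normal", "normal"),
              method = method, n = n)
  class(out) <- "es_bands"
  out
}

#' Equivalent Score bands from published thresholds
#'
#' Encodes a printed threshold row (oTL and the upper edges of ES 1-3) as
#' the half-open intervals used throughout: ES 0 at or below `t0`, ES `k`
#' in `(t_{k-1}, t_k]`, ES 4 strictly above `t3`.
#'
#' @param t0,t1,t2,t3 Ascending cut points; `t0` is the outer tolerance
#'   limit, `t3` the median.
#' @return An `es_bands` object.
#' @export
es_bands_from_thresholds <- function(t0, t1, t2, t3) {
  new_es_bands(c(t0, t1, t2, t3), method = "published")
}

#' @export
print.es_bands <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("Equivalent Score bands (%s method)\n", x$method))
  cat(sprintf("  ES 0 (%s): <= %.4g\n", x$labels[1], th[1]))
  for (k in 1:3) {
    cat(sprintf("  ES %d (%s): (%.4g, %.4g]\n", k, x$labels[k + 1],
                th[k], th[k + 1]))
  }
  cat(sprintf("  ES 4 (%s): > %.4g\n", x$labels[5], th[4]))
  invisible(x)
}

#' Assign Equivalent Scores
#'
#' Total over the reals: values at a threshold resolve to the lower band
#' (at or below the oTL is ES 0; at the median is ES 3; strictly above the
#' median is ES 4).
#'
#' @param adjusted_value Numeric vector of adjusted scores.
#' @param bands An `es_bands` object.
#' @return Integer vector of Equivalent Scores, 0-4.
#' @examples
#' b <- es_bands_from_thresholds(42.35, 46.09, 48.87, 51.45)
#' assign_es(c(42.35, 47, 51.46), b)
#' @export
assign_es <- function(adjusted_value, bands) {
  stopifnot(inherits(bands, "es_bands"))
  th <- bands$thresholds
  out <- integer(length(adjusted_value))
  for (k in seq_along(th)) out <- out + (adjusted_value > th[k])
  as.integer(out)
}

#' Export a norm table
#'
#' Bundles tolerance limits and Equivalent Score bands into the JSON norm
#' resource format (`index_name`, sample size, coverage/confidence, ranks,
#' oTL/iTL, thresholds, method metadata).
#'
#' @param index_name `"ER"` or `"EA"`.
#' @param tls A `tolerance_limits`.
#' @param bands An `es_bands`.
#' @param path File path for [write_norm_table()].
#' @return `norm_table()` returns a list; `write_norm_table()` its path.
#' @export
norm_table <- function(index_name, tls, bands) {
  list(index_name = index_name, n = tls$n, coverage_p = tls$coverage_p,
       confidence = tls$confidence, outer_rank = tls$outer_rank,
       inner_rank = tls$inner_rank, otl = tls$otl, itl = tls$itl,
       thresholds = as.list(bands$thresholds),
       method = list(limits = "nonparametric order-statistic",
                     bands = bands$method))
}

#' @rdname norm_table
#' @export
write_norm_table <- function(index_name, tls, bands, path) {
  jsonlite::write_json(norm_table(index_name, tls, bands), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
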