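# Descriptive and associational statistics for normative cohorts, plus the
# a-priori power computation for multiple-regression norming studies.

#' Skewness/kurtosis normality flags
#'
#' Conventional moment estimators: skewness `m3 / m2^(3/2)` and excess
#' kurtosis `m4 / m2^2 - 3`.  A distribution is flagged abnormal when
#' absolute skewness reaches 1 or absolute excess kurtosis reaches 3 -- the
#' screening rule commonly applied to raw neuropsychological scores before
#' norming.
#'
#' @param values Numeric vector, length at least 4.
#' @return List with `skewness`, `kurtosis` (excess) and `abnormal`.
#' @export
normality_flags <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) {
    stop("constant input: skewness and kurtosis undefined", call. = FALSE)
  }
  skew <- mean((values - m)^3) / m2^1.5
  kurt <- mean((values - m)^4) / m2^2 - 3
  list(skewness = skew, kurtosis = kurt,
       abnormal = abs(skew) >= 1 || abs(kurt) >= 3)
}

#' Pearson associations over a cohort table
#'
#' Pearson correlations with two-sided t-based p-values for a set of column
#' pairs, using pairwise-complete observations (so MoCA, administered only
#' from age 50, is automatically restricted to that subgroup).  Pairs with
#' fewer than 3 complete cases are skipped with a warning.
#'
#' @param cohort Cohort data frame.
#' @param pairs Two-column character matrix / data frame of column-name
#'   pairs, or `NULL` for the default association set (age, education, MoCA,
#'   IRI total and subscales against both indices).
#' @return Data frame with columns `var1`, `var2`, `n`, `r`, `p`; the number
#'   of tests performed is attached as attribute `"n_tests"` (no multiplicity
#'   correction is applied).
#' @export
pearson_matrix <- function(cohort, pairs = NULL) {
  if (is.null(pairs)) {
    xs <- c("age", "education", "moca", "iri_total", "iri_pt", "iri_f",
            "iri_ec", "iri_pd")
    xs <- intersect(xs, names(cohort))
    pairs <- expand.grid(var1 = xs, var2 = c("er_raw", "ea_raw"),
                         stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("var1", "var2")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- cohort[[pairs$var1[i]]]
    y <- cohort[[pairs$var2[i]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) {
      warning(sprintf("skipping %s ~ %s: fewer than 3 complete cases",
                      pairs$var1[i], pairs$var2[i]), call. = FALSE)
      return(NULL)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pairs$var1[i], var2 = pairs$var2[i], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(var1 = character(0), var2 = character(0),
                      n = integer(0), r = numeric(0), p = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  out
}

#' Minimum sample size for a multiple-regression F test
#'
#' Solves the smallest denominator degrees of freedom `v` such that the
#' level-`alpha` F test with `u` numerator df and noncentrality
#' `lambda = f2 * (u + v + 1)` (Cohen's convention, as implemented by the
#' usual power tools) reaches the target power, then converts `v` to a
#' total sample size.
#'
#' Two bookkeeping conventions are supported for the conversion.  The
#' default, `count_intercept = FALSE`, quotes `N = u + v` rounded to the
#' nearest integer -- the convention under which published norming studies
#' in this family report their minimum N (with `u = 3`, `f2 = 0.05`,
#' `alpha = 0.05`, power 0.90 it yields 286).  `count_intercept = TRUE`
#' applies the textbook identity `N = u + v + 1` with `v` rounded up, which
#' is one or two participants more conservative.  An alternative
#' noncentrality convention `lambda = f2 * v` is available via
#' `lambda_convention = "error"`.
#'
#' @param u Numerator degrees of freedom (number of tested predictors).
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param alpha Test level.
#' @param power Target power.
#' @param lambda_convention `"total"` (`f2 * (u + v + 1)`, default) or
#'   `"error"` (`f2 * v`).
#' @param count_intercept See Details.
#' @return List of class `power_spec`: `u`, `f2`, `alpha`, `power`, `v`
#'   (continuous solution) and `n_required`.
#' @examples
#' required_n_f2(u = 3, f2 = 0.05, alpha = 0.05, power = 0.90)
#' @export
required_n_f2 <- function(u, f2, alpha = 0.05, power = 0.90,
                          lambda_convention = c("total", "error"),
                          count_intercept = FALSE) {
  lambda_convention <- match.arg(lambda_convention)
  stopifnot_scalar_number(u, "u")
  stopifnot_scalar_number(f2, "f2")
  if (f2 <= 0) stop("f2 must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1) {
    stop("need 0 < alpha < power < 1", call. = FALSE)
  }
  pw <- function(v) {
    lam <- if (lambda_convention == "total") f2 * (u + v + 1) else f2 * v
    stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = lam,
              lower.tail = FALSE)
  }
  if (pw(1e6) < power) {
    stop("power target unreachable: no v below 1e6 attains it",
         call. = FALSE)
  }
  v <- if (pw(1 + 1e-9) >= power) 1 else {
    stats::uniroot(function(v) pw(v) - power, c(1 + 1e-9, 1e6),
                   tol = 1e-9)$root
  }
  n <- if (count_intercept) u + ceiling(v) + 1 else round(u + v)
  out <- list(u = u, f2 = f2, alpha = alpha, power = power, v = v,
              n_required = as.integer(n),
              lambda_convention = lambda_convention,
              count_intercept = count_intercept)
  class(out) <- "power_spec"
  out
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf(
    "Multiple-regression power analysis: u = %g, f2 = %g, alpha = %g, power = %g\n",
    x$u, x$f2, x$alpha, x$power))
  cat(sprintf("  denominator df (continuous): %.2f\n", x$v))
  cat(sprintf("  minimum sample size: N = %d\n", x$n_required))
  invisible(x)
}
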