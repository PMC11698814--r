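test_that("normality flags apply the skewness/kurtosis screening rule", {
  set.seed(1)
  gauss <- rnorm(10000)
  fg <- normality_flags(gauss)
  expect_false(fg$abnormal)
  expect_lt(abs(fg$skewness), 0.1)
  expect_lt(abs(fg$kurtosis), 0.2)

  expo <- rexp(10000)
  fe <- normality_flags(expo)
  expect_lt(abs(fe$skewness - 2), 0.15)
  expect_true(fe$abnormal)

  expect_error(normality_flags(rep(3, 50)), "constant")
  expect_error(normality_flags(c(1, 2, 3)), "at least 4")
})

test_that("pearson_matrix computes pairwise-complete correlations", {
  df <- data.frame(er_raw = 1:10, ea_raw = 1:10, age = 10:1)
  res <- pearson_matrix(df, pairs = data.frame(var1 = c("er_raw", "age"),
                                               var2 = "ea_raw"))
  expect_equal(res$r[1], 1)
  expect_equal(res$r[2], -1)
  expect_equal(attr(res, "n_tests"), 2L)

  df$moca <- c(28, NA, NA, NA, NA, NA, NA, NA, NA, 25)
  expect_warning(
    res2 <- pearson_matrix(df, pairs = data.frame(var1 = "moca",
                                                  var2 = "er_raw")),
    "fewer than 3")
  expect_equal(nrow(res2), 0L)
})

test_that("cohort associations reproduce the published pattern", {
  coh <- fixture_big_cohort()
  res <- pearson_matrix(coh)
  get <- function(v1, v2) res$r[res$var1 == v1 & res$var2 == v2]
  # MoCA pairs are automatically restricted to the age >= 50 subgroup
  expect_equal(res$n[res$var1 == "moca"][1], sum(coh$age >= 50))
  expect_lt(abs(get("moca", "er_raw") - 0.450), 0.05)
  expect_lt(abs(get("moca", "ea_raw") - 0.383), 0.05)
  expect_lt(abs(get("iri_total", "er_raw") - 0.189), 0.05)
  expect_lt(abs(get("iri_total", "ea_raw") - 0.232), 0.05)
  # sign pattern: age negative, education/cognition/empathy positive
  expect_lt(get("age", "er_raw"), 0)
  expect_lt(get("age", "ea_raw"), 0)
  expect_gt(get("education", "er_raw"), 0)
  expect_gt(get("education", "ea_raw"), 0)
  # subscale structure: both indices load on Fantasy; Perspective Taking
  # tracks authenticity discrimination much more than emotion labelling
  expect_gt(get("iri_f", "er_raw"), 0.2)
  expect_gt(get("iri_pt", "ea_raw"), 0.2)
  expect_lt(get("iri_pt", "er_raw"), get("iri_pt", "ea_raw") / 2)
})

test_that("required_n_f2 reproduces the published minimum sample size", {
  ps <- required_n_f2(u = 3, f2 = 0.05, alpha = 0.05, power = 0.90)
  expect_lte(abs(ps$n_required - 286), 1)
  # conservative bookkeeping counts the intercept and rounds v up
  cons <- required_n_f2(u = 3, f2 = 0.05, alpha = 0.05, power = 0.90,
                        count_intercept = TRUE)
  expect_gte(cons$n_required, ps$n_required)
  expect_lte(cons$n_required - ps$n_required, 3)
})

test_that("required sample size is monotone in effect size and power", {
  ns_f2 <- vapply(c(0.02, 0.05, 0.10), function(f2) {
    required_n_f2(3, f2)$n_required
  }, integer(1))
  expect_true(all(diff(ns_f2) < 0))
  ns_pw <- vapply(c(0.80, 0.90, 0.95), function(p) {
    required_n_f2(3, 0.05, power = p)$n_required
  }, integer(1))
  expect_true(all(diff(ns_pw) > 0))
  # the error-df noncentrality convention asks for slightly more
  expect_gt(required_n_f2(3, 0.05, lambda_convention = "error")$n_required,
            required_n_f2(3, 0.05)$n_required)
})

test_that("u = 1 agrees with an independent noncentral-t computation", {
  ps <- required_n_f2(u = 1, f2 = 0.05, alpha = 0.05, power = 0.90)
  # two-sided single-predictor t test: delta = sqrt(f2 (v + 2)), df = v
  pow_t <- function(v) {
    d <- sqrt(0.05 * (v + 2))
    q <- qt(0.975, v)
    pt(q, v, ncp = d, lower.tail = FALSE) + pt(-q, v, ncp = d)
  }
  v <- uniroot(function(v) pow_t(v) - 0.90, c(2, 1e5))$root
  expect_lte(abs(ps$n_required - round(1 + v)), 2)
})

test_that("independent columns rarely exceed the 4/sqrt(n) bound", {
  set.seed(42)
  n <- 200
  hits <- vapply(1:100, function(i) {
    df <- data.frame(er_raw = rnorm(n), ea_raw = rnorm(n), age = rnorm(n),
                     education = rnorm(n))
    res <- pearson_matrix(df)
    all(abs(res$r) < 4 / sqrt(n))
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
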