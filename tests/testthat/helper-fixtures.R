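# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture_manifest <- function() {
  if (is.null(.fixtures$manifest)) {
    .fixtures$manifest <- build_manifest(seed = 1)
  }
  .fixtures$manifest
}

# Large calibrated cohort with item-level responses (the study-scale
# simulation used for moment checks).
fixture_big_cohort <- function() {
  if (is.null(.fixtures$big)) {
    .fixtures$big <- simulate_cohort(20000, seed = 11,
                                     config = default_generator_config(),
                                     items = TRUE,
                                     manifest = fixture_manifest())
  }
  .fixtures$big
}

# A generator configuration whose ER index uses the published adjustment
# constants exactly (quadratic age slope -0.002, partial sex gap -1.636,
# no education effect).
fixture_published_effect_config <- function() {
  cfg <- default_generator_config()
  cfg$score_model$er$beta_age2 <- -0.002
  cfg$score_model$er$beta_edu <- 0
  cfg$score_model$er$beta_sex <- -2 * 0.818
  cfg
}

# Parameter-recovery replicates: select_model() on normative-size cohorts
# drawn from the default calibrated generator.  Cached because both the
# module tests and the acceptance suite use them.
fixture_recovery_fits <- function(n_rep = 20, n = 522) {
  key <- sprintf("rec_%d_%d", n_rep, n)
  if (is.null(.fixtures[[key]])) {
    cfg <- default_generator_config()
    fits <- lapply(seq_len(n_rep), function(i) {
      coh <- simulate_cohort(n, seed = 5000 + i, config = cfg,
                             covariates = FALSE)
      m <- select_model(coh, "ER")
      list(retained = sort(m$fit_diagnostics$retained),
           beta_age2 = m$beta_age2, sex_offset = m$sex_offset)
    })
    .fixtures[[key]] <- fits
  }
  .fixtures[[key]]
}

# Exhaustive binomial-CDF oracle for tolerance ranks: cumulative sums of the
# pmf computed term by term from the multiplicative recurrence
# b_{k} = b_{k-1} (n-k+1)/k p/(1-p); independent of pbinom().
oracle_tl_ranks <- function(n, p = 0.05, conf = 0.95) {
  kmax <- min(n, 250L)
  terms <- numeric(kmax + 1L)
  terms[1] <- (1 - p)^n
  for (k in seq_len(kmax)) {
    terms[k + 1] <- terms[k] * (n - k + 1) / k * p / (1 - p)
  }
  cdf <- cumsum(terms)                # cdf[k+1] = P(X <= k)
  eps <- 1e-12
  outer_ok <- which(cdf[seq_len(min(n, kmax + 1L))] <= 1 - conf + eps)
  inner_ok <- which(cdf[seq_len(kmax + 1L)] >= conf - eps)
  list(outer_rank = if (length(outer_ok)) max(outer_ok) else NA_integer_,
       inner_rank = min(inner_ok))
}
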