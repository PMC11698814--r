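# Printed correction-grid anchors for the published adjustment equations.
# The EA male row as printed skips the age-45 entry and carries one
# inconsistent value at the age-40 slot; only equation-consistent cells are
# asserted.
published_er_grid <- list(
  ages = seq(25, 85, 5),
  M = c(-1.56, -1.01, -0.36, 0.40, 1.25, 2.20, 3.25, 4.40, 5.65, 7.00,
        8.45, 10.00, 11.65),
  F = c(-3.19, -2.64, -1.99, -1.24, -0.39, 0.56, 1.61, 2.76, 4.01, 5.36,
        6.81, 8.36, 10.01)
)
published_ea_grid <- list(
  ages = seq(25, 85, 5),
  M = c(-1.95, -1.40, -0.75, NA, NA, 1.80, 2.85, 4.00, 5.25, 6.60, 8.05,
        9.60, 11.25),
  F = c(-2.79, -2.24, -1.59, -0.84, 0.01, 0.96, 2.01, 3.16, 4.41, 5.76,
        7.21, 8.76, 10.41)
)

test_that("published adjustment models reproduce the printed grids", {
  g_er <- correction_grid(published_adjustment_model("ER"))
  expect_equal(g_er$age, published_er_grid$ages)
  expect_equal(g_er$M, published_er_grid$M)
  expect_equal(g_er$F, published_er_grid$F)

  g_ea <- correction_grid(published_adjustment_model("EA"))
  keep <- !is.na(published_ea_grid$M)
  expect_equal(g_ea$M[keep], published_ea_grid$M[keep])
  expect_equal(g_ea$F, published_ea_grid$F)
})

test_that("adjustment satisfies centering and antisymmetry identities", {
  er <- published_adjustment_model("ER")
  a0 <- sqrt(er$centering_c)
  expect_equal(adjust_score(42, a0, "M", er), 42 + 0.818, tolerance = 1e-12)
  expect_equal(adjust_score(42, a0, "F", er), 42 - 0.818, tolerance = 1e-12)

  g <- correction_grid(er, digits = NULL)
  expect_equal(g$M - g$F, rep(2 * 0.818, nrow(g)), tolerance = 1e-12)

  # corrections increase with age past the centering age
  ea <- published_adjustment_model("EA")
  gg <- correction_grid(ea, ages = 43:88, digits = NULL)
  expect_true(all(diff(gg$M) > 0))
})

test_that("adjust_score applies the published equations with range checks", {
  er <- published_adjustment_model("ER")
  expect_equal(display_round(adjust_score(0, 25, "M", er)), -1.56)
  ea <- published_adjustment_model("EA")
  expect_equal(display_round(adjust_score(50, 85, "M", ea)), 61.25)

  expect_error(adjust_score(50, 92, "M", er), "validity range")
  expect_error(adjust_score(50, 16, "F", er), "validity range")
  expect_error(adjust_score(65, 40, "M", er), "\\[0, 60\\]")
  expect_error(adjust_score(50, 40, "x", er), "sex")
})

test_that("select_model recovers a quadratic age and sex structure", {
  cfg <- fixture_published_effect_config()
  coh <- simulate_cohort(5000, seed = 42, config = cfg, covariates = FALSE)
  m <- select_model(coh, "ER")
  expect_setequal(m$fit_diagnostics$retained, c("age2", "sexcode"))
  expect_lt(abs(m$beta_age2 - 0.002) / 0.002, 0.10)
  expect_gt(m$centering_c, 0)
  expect_equal(m$centering_c, mean(coh$age^2))

  expect_error(select_model(coh[1:20, ], "ER"), "at least 30")
})

test_that("a cohort without demographic effects yields the identity", {
  cfg <- default_generator_config()
  for (ix in c("er", "ea")) {
    cfg$score_model[[ix]][c("beta_age2", "beta_edu", "beta_sex")] <-
      list(0, 0, 0)
  }
  coh <- simulate_cohort(2000, seed = 314, config = cfg, covariates = FALSE)
  m <- select_model(coh, "ER")
  expect_length(m$fit_diagnostics$retained, 0)
  expect_equal(adjust_score(c(30, 45, 60), c(20, 50, 80),
                            c("M", "F", "M"), m),
               c(30, 45, 60))
})

test_that("fitting normative-size cohorts recovers the generating values", {
  cfg <- default_generator_config()
  fits <- fixture_recovery_fits()
  use_b <- vapply(fits, function(f) "age2" %in% f$retained, logical(1))
  use_s <- vapply(fits, function(f) "sexcode" %in% f$retained, logical(1))
  betas <- vapply(fits[use_b], `[[`, numeric(1), "beta_age2")
  offs <- vapply(fits[use_s], `[[`, numeric(1), "sex_offset")
  gen_beta <- -cfg$score_model$er$beta_age2
  gen_off <- -cfg$score_model$er$beta_sex / 2
  se_beta <- sd(betas) / sqrt(length(betas))
  se_off <- sd(offs) / sqrt(length(offs))
  expect_lt(abs(mean(betas) - gen_beta), 2 * se_beta)
  expect_lt(abs(mean(offs) - gen_off), 2 * se_off)
})

test_that("refitting a published-constants cohort recovers the sex offset", {
  cfg <- fixture_published_effect_config()
  coh <- simulate_cohort(20000, seed = 77, config = cfg, covariates = FALSE)
  m <- select_model(coh, "ER")
  expect_lt(abs(m$sex_offset - 0.818), 0.1)
  expect_lt(abs(m$beta_age2 - 0.002), 0.0002)
})

test_that("adjustment models round-trip through JSON", {
  er <- published_adjustment_model("ER")
  fp <- tempfile(fileext = ".json")
  write_adjustment_model(er, fp)
  er2 <- read_adjustment_model(fp)
  expect_equal(adjust_score(48, 63, "F", er2), adjust_score(48, 63, "F", er))
  expect_equal(er2$centering_c, er$centering_c)
  unlink(fp)

  coh <- simulate_cohort(1000, seed = 9, covariates = FALSE)
  m <- select_model(coh, "EA")
  fp2 <- tempfile(fileext = ".json")
  write_adjustment_model(m, fp2)
  m2 <- read_adjustment_model(fp2)
  expect_equal(adjust_score(40, 55, "M", m2, education = 13),
               adjust_score(40, 55, "M", m, education = 13))
  unlink(fp2)
})
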