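test_that("demographic sampling reproduces the published stratification", {
  cfg <- default_generator_config()
  c522 <- simulate_cohort(522, seed = 7, config = cfg, covariates = FALSE)
  expect_equal(nrow(c522), 522L)
  # marginal sex split approaches 216 M / 306 F
  expect_lt(abs(mean(c522$sex == "M") - 216 / 522), 0.03)
  expect_true(all(c522$age >= 17 & c522$age <= 88))
  expect_true(all(c522$education >= 5 & c522$education <= 24))

  expect_equal(nrow(simulate_cohort(0, seed = 1, config = cfg)), 0L)

  c50k <- simulate_cohort(50000, seed = 1, config = cfg, covariates = FALSE)
  expect_lt(abs(mean(c50k$age) - 39.97), 0.5)

  bad <- cfg
  bad$strata <- bad$strata[0, ]
  expect_error(sample_demographics(bad), "empty strata")
})

test_that("score generation follows the centred latent model", {
  cfg <- default_generator_config()
  # degenerate generator: no effects, vanishing noise -> constant scores
  deg <- cfg
  for (ix in c("er", "ea")) {
    deg$score_model[[ix]] <- list(intercept = 47.3, beta_age2 = 0,
                                  beta_edu = 0, beta_sex = 0,
                                  sigma_resid = 1e-9)
  }
  coh <- simulate_cohort(200, seed = 3, config = deg, covariates = FALSE)
  expect_true(all(coh$er_raw == 47L))
  expect_true(all(coh$ea_raw == 47L))

  # heavy ceiling truncation triggers the calibration warning
  trunc <- cfg
  trunc$score_model$er$intercept <- 62
  trunc$score_model$er$sigma_resid <- 1
  expect_warning(simulate_cohort(2000, seed = 4, config = trunc,
                                 covariates = FALSE),
                 "truncated")

  # identical master seed reproduces the cohort; item simulation does not
  # disturb the score stream
  a <- simulate_cohort(300, seed = 12, config = cfg)
  b <- simulate_cohort(300, seed = 12, config = cfg, items = TRUE)
  expect_equal(a, structure(b, responses = NULL))
})

test_that("the calibrated generator reproduces the published moments", {
  coh <- fixture_big_cohort()
  expect_lt(abs(mean(coh$er_raw) - 51.17), 0.15)
  expect_lt(abs(cor(coh$age, coh$er_raw) - (-0.498)), 0.03)
  expect_lt(abs(cor(coh$age, coh$ea_raw) - (-0.450)), 0.03)
  expect_lt(abs(cor(coh$education, coh$er_raw) - 0.142), 0.03)
  expect_lt(abs(cor(coh$education, coh$ea_raw) - 0.161), 0.03)
  expect_lt(abs(mean(coh$ea_raw) - 50.17), 0.15)
  # published score ranges are plausible: almost no mass below them
  expect_lt(mean(coh$er_raw < 31), 0.01)
  expect_lt(mean(coh$ea_raw < 33), 0.01)
})

test_that("calibration solves null and infeasible targets correctly", {
  tg <- ear_reference_targets()
  tg$er[c("r_age", "r_edu")] <- list(0, 0)
  tg$er$sex_gap <- 0
  tg$er$sd <- 5
  cfg <- calibrate_generator(targets = tg, refine = 1)
  expect_lt(abs(cfg$score_model$er$beta_age2), 1e-4)
  expect_lt(abs(cfg$score_model$er$beta_edu), 0.02)
  expect_lt(abs(cfg$score_model$er$beta_sex), 0.15)
  expect_equal(cfg$score_model$er$sigma_resid, 5, tolerance = 0.05)

  bad <- ear_reference_targets()
  # correlations this strong cannot coexist with the target variance
  bad$ea$r_age <- -0.95
  bad$ea$r_edu <- 0.9
  expect_error(calibrate_generator(targets = bad, refine = 0),
               "infeasible.*EA")
})

test_that("stronger quadratic age slopes strengthen the age correlation", {
  cfg <- default_generator_config()
  rs <- vapply(c(-0.001, -0.002, -0.003), function(b) {
    cc <- cfg
    cc$score_model$er$beta_age2 <- b
    coh <- simulate_cohort(10000, seed = 21, config = cc,
                           covariates = FALSE)
    cor(coh$age, coh$er_raw)
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("covariates respect the protocol structure", {
  coh <- fixture_big_cohort()
  expect_true(all(is.na(coh$moca[coh$age < 50])))
  expect_true(all(!is.na(coh$moca[coh$age >= 50])))
  expect_true(all(coh$moca >= 0 & coh$moca <= 30, na.rm = TRUE))
  expect_equal(coh$iri_total,
               coh$iri_pt + coh$iri_f + coh$iri_ec + coh$iri_pd)
  expect_true(all(coh$iri_pt >= 0 & coh$iri_pt <= 28))
})

test_that("item-level responses score back to the stored indices exactly", {
  coh <- fixture_big_cohort()
  resp <- attr(coh, "responses")
  m <- fixture_manifest()
  sub <- emotion_subscores(resp, m)
  sub <- sub[match(coh$participant_id, sub$participant_id), ]
  expect_equal(sub$er_index, coh$er_raw)
  expect_equal(sub$ea_index, coh$ea_raw)

  # per-participant agreement with the reference scorer on a subsample
  for (pid in coh$participant_id[c(1, 500, 19999)]) {
    rs <- score_responses(resp[resp$participant_id == pid, -1], m)
    expect_equal(rs$er_index, coh$er_raw[coh$participant_id == pid])
    expect_equal(rs$ea_index, coh$ea_raw[coh$participant_id == pid])
  }

  # extreme abilities hit the floor/ceiling exactly
  ext <- data.frame(participant_id = c("lo", "hi"), er_raw = c(0L, 60L),
                    ea_raw = c(0L, 60L), stringsAsFactors = FALSE)
  r <- simulate_responses(ext, m, default_generator_config())
  s_hi <- score_responses(r[r$participant_id == "hi", -1], m)
  s_lo <- score_responses(r[r$participant_id == "lo", -1], m)
  expect_equal(c(s_hi$er_index, s_hi$ea_index), c(60L, 60L))
  expect_equal(c(s_lo$er_index, s_lo$ea_index), c(0L, 0L))
})

test_that("per-emotion accuracies match their calibration targets", {
  coh <- fixture_big_cohort()
  sub <- emotion_subscores(attr(coh, "responses"), fixture_manifest())
  targets <- c(happiness = 9.29, surprise = 9.46, anger = 7.96,
               fear = 6.54, sadness = 9.07, disgust = 8.82)
  for (e in names(targets)) {
    expect_lt(abs(mean(sub[[e]]) - targets[[e]]), 0.15)
  }
  expect_lt(abs(mean(sub$fear) - 6.54), 0.1)
  # fear errors are biased towards surprise
  resp <- attr(coh, "responses")
  m <- fixture_manifest()
  fear_items <- m$stimulus_id[m$emotion == "fear"]
  fr <- resp[resp$stimulus_id %in% fear_items &
               resp$chosen_emotion != "fear", ]
  expect_gt(mean(fr$chosen_emotion == "surprise"), 0.4)
})

test_that("configs and cohorts round-trip through YAML and CSV", {
  cfg <- default_generator_config()
  fy <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, fy)
  cfg2 <- read_generator_config(fy)
  a <- simulate_cohort(100, seed = 5, config = cfg, covariates = FALSE)
  b <- simulate_cohort(100, seed = 5, config = cfg2, covariates = FALSE)
  expect_equal(a, b)

  coh <- simulate_cohort(50, seed = 6, config = cfg)
  fc <- tempfile(fileext = ".csv")
  write_cohort(coh, fc)
  back <- read_cohort(fc)
  expect_equal(back$er_raw, coh$er_raw)
  expect_equal(back$moca, coh$moca)
  expect_true(all(is.na(back$moca[back$age < 50])))
  unlink(c(fy, fc))
})
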