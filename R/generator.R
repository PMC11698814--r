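# Synthetic normative-cohort generator, moment-calibrated to the published
# descriptives of the EAR normative sample (demographic stratification table,
# index means/SDs, demographic correlations, per-emotion accuracies).

# ---------------------------------------------------------------------------
# Demographic stratification

#' Demographic stratification of the EAR normative sample
#'
#' Cell counts (males, females) of the published age-band by education-band
#' stratification table of the normative cohort.  Used as the default
#' sampling weights for [sample_demographics()]; within a sampled cell, age
#' and education are drawn uniformly over the band (the within-band
#' distributions are not published).
#'
#' @return Data frame with columns `age_lo`, `age_hi`, `edu_lo`, `edu_hi`,
#'   `sex`, `count` and normalised `weight`.
#' @export
ear_strata <- function() {
  age_lo <- c(17, 26, 36, 46, 56, 66, 76)
  age_hi <- c(25, 35, 45, 55, 65, 75, 88)
  edu_lo <- c(5, 6, 14, 17)
  edu_hi <- c(5, 13, 16, 24)
  # rows: education bands; cols: age bands
  m <- rbind(c(0, 0, 0, 0, 0, 0, 0),
             c(11, 20, 19, 23, 27, 2, 3),
             c(19, 11, 4, 9, 0, 0, 0),
             c(15, 17, 10, 12, 11, 3, 0))
  f <- rbind(c(0, 0, 0, 0, 1, 0, 1),
             c(14, 13, 24, 29, 28, 4, 2),
             c(37, 14, 10, 5, 5, 0, 0),
             c(38, 27, 16, 23, 13, 0, 0))
  grid <- expand.grid(e = 1:4, a = 1:7, sex = c("M", "F"),
                      stringsAsFactors = FALSE)
  grid$count <- ifelse(grid$sex == "M", m[cbind(grid$e, grid$a)],
                       f[cbind(grid$e, grid$a)])
  grid <- grid[grid$count > 0, , drop = FALSE]
  out <- data.frame(age_lo = age_lo[grid$a], age_hi = age_hi[grid$a],
                    edu_lo = edu_lo[grid$e], edu_hi = edu_hi[grid$e],
                    sex = grid$sex, count = grid$count,
                    stringsAsFactors = FALSE)
  out$weight <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

# Exact first- and second-order moments of (age, age^2, education, sexcode)
# under the stratified sampling scheme: integer-uniform within band,
# independence of age and education within a cell.  sexcode is +1/2 male,
# -1/2 female (deviation coding).
strata_moments <- function(strata = ear_strata()) {
  pow_mean <- function(lo, hi, k) {
    vapply(seq_along(lo), function(i) mean((lo[i]:hi[i])^k), numeric(1))
  }
  w <- strata$weight
  A1 <- pow_mean(strata$age_lo, strata$age_hi, 1)
  A2 <- pow_mean(strata$age_lo, strata$age_hi, 2)
  A3 <- pow_mean(strata$age_lo, strata$age_hi, 3)
  A4 <- pow_mean(strata$age_lo, strata$age_hi, 4)
  E1 <- pow_mean(strata$edu_lo, strata$edu_hi, 1)
  E2 <- pow_mean(strata$edu_lo, strata$edu_hi, 2)
  S <- ifelse(strata$sex == "M", 0.5, -0.5)
  m <- function(x) sum(w * x)
  mu <- c(A = m(A1), A2 = m(A2), E = m(E1), S = m(S))
  list(
    mean_age = mu[["A"]], mean_age2 = mu[["A2"]], mean_edu = mu[["E"]],
    mean_sex = mu[["S"]],
    var_age = m(A2) - mu[["A"]]^2,
    var_age2 = m(A4) - mu[["A2"]]^2,
    var_edu = m(E2) - mu[["E"]]^2,
    var_sex = m(S^2) - mu[["S"]]^2,
    cov_age2_age = m(A3) - mu[["A2"]] * mu[["A"]],
    cov_age2_edu = m(A2 * E1) - mu[["A2"]] * mu[["E"]],
    cov_age_edu = m(A1 * E1) - mu[["A"]] * mu[["E"]],
    cov_age2_sex = m(A2 * S) - mu[["A2"]] * mu[["S"]],
    cov_age_sex = m(A1 * S) - mu[["A"]] * mu[["S"]],
    cov_edu_sex = m(E1 * S) - mu[["E"]] * mu[["S"]]
  )
}

# ---------------------------------------------------------------------------
# Calibration targets

#' Published calibration targets for the synthetic generator
#'
#' Descriptive moments and associations of the EAR normative sample that the
#' generator is calibrated against: index means/SDs, age and education
#' correlations, the male-female raw-score gaps implied by the published sex
#' adjustment offsets, per-emotion accuracies, and the MoCA/IRI covariate
#' moments and correlations.
#'
#' @return A nested list of targets; pass (possibly modified) to
#'   [calibrate_generator()].
#' @export
ear_reference_targets <- function() {
  list(
    er = list(mean = 51.17, sd = 5.13, r_age = -0.498, r_edu = 0.142,
              sex_gap = -2 * 0.818),
    ea = list(mean = 50.17, sd = 5.00, r_age = -0.450, r_edu = 0.161,
              sex_gap = -2 * 0.420),
    emotion_means = c(happiness = 9.29, surprise = 9.46, anger = 7.96,
                      fear = 6.54, sadness = 9.07, disgust = 8.82),
    moca = list(mean = 27.95, sd = 2.03, r_er = 0.450, r_ea = 0.383),
    iri = list(mean = 66.4, sd = 13.19, r_er = 0.189, r_ea = 0.232)
  )
}

# Solve the latent-model coefficients for one index from moment targets.
# Latent: Y = intercept + b_a2 (A2 - E A2) + b_e (E - E E) + b_s S + eps.
# The sex gap pins b_s; the two covariance targets give a 2x2 linear system
# in (b_a2, b_e); the residual SD follows from the variance decomposition.
solve_index_coefs <- function(tg, mom, label) {
  b_s <- tg$sex_gap
  rhs <- c(tg$r_age * tg$sd * sqrt(mom$var_age) - b_s * mom$cov_age_sex,
           tg$r_edu * tg$sd * sqrt(mom$var_edu) - b_s * mom$cov_edu_sex)
  A <- rbind(c(mom$cov_age2_age, mom$cov_age_edu),
             c(mom$cov_age2_edu, mom$var_edu))
  b <- solve(A, rhs)
  var_xb <- b[1]^2 * mom$var_age2 + b[2]^2 * mom$var_edu +
    b_s^2 * mom$var_sex +
    2 * b[1] * b[2] * mom$cov_age2_edu +
    2 * b[1] * b_s * mom$cov_age2_sex +
    2 * b[2] * b_s * mom$cov_edu_sex
  sig2 <- tg$sd^2 - var_xb
  if (sig2 <= 0) {
    stop(sprintf(paste0("infeasible calibration targets for %s: implied ",
                        "residual variance %.3f < 0 (sd target %.2f too ",
                        "small for the requested correlations)"),
                 label, sig2, tg$sd), call. = FALSE)
  }
  list(intercept = tg$mean, beta_age2 = b[1], beta_edu = b[2], beta_sex = b_s,
       sigma_resid = sqrt(sig2))
}

# ---------------------------------------------------------------------------
# Calibration

#' Calibrate the synthetic cohort generator
#'
#' Moment-matching calibration: latent-model coefficients for the ER and EA
#' indices are solved in closed form from the target means, SDs, demographic
#' correlations and sex gaps given the exact moments of the stratified
#' demographic distribution, then refined over a small number of large
#' simulation passes to absorb the effect of rounding scores to integers and
#' truncating to the 0-60 scale.  Per-emotion item difficulties are fitted by
#' a logit-scale fixed point so simulated per-emotion accuracies match their
#' targets, and MoCA/IRI loadings are solved from the simulated index
#' correlation structure.
#'
#' The refinement simulations run under a fixed internal seed, so the
#' returned configuration is a deterministic function of the targets.
#'
#' @param targets Target list, see [ear_reference_targets()].
#' @param strata Stratification table, see [ear_strata()].
#' @param n_sim Size of each refinement simulation.
#' @param refine Number of refinement passes (0 = closed-form solution only).
#' @return A `generator_config` object.
#' @export
calibrate_generator <- function(targets = ear_reference_targets(),
                                strata = ear_strata(),
                                n_sim = 50000L, refine = 3L) {
  if (nrow(strata) == 0L) stop("empty strata table", call. = FALSE)
  mom <- strata_moments(strata)
  cfg <- list(
    n = 0L, seed = 1L,
    strata = strata,
    moments = mom,
    score_model = list(
      er = solve_index_coefs(targets$er, mom, "ER"),
      ea = solve_index_coefs(targets$ea, mom, "EA")
    ),
    emotion_difficulty = targets$emotion_means / 10,
    item_model = list(
      logits = stats::qlogis(targets$emotion_means / 10),
      fear_to_surprise = 0.6
    ),
    covariate_model = NULL,
    targets = targets
  )
  class(cfg) <- "generator_config"

  internal_seed <- 987654321L
  tg <- targets
  work <- tg[c("er", "ea")]  # running (bias-corrected) moment targets
  sim <- NULL
  for (pass in seq_len(refine + 1L)) {
    cfg$n <- as.integer(n_sim)
    cfg$seed <- substream_seed(internal_seed, pass)
    sim <- sample_scores(sample_demographics(cfg), cfg,
                         covariates = FALSE)
    if (pass > refine) break
    for (ix in c("er", "ea")) {
      y <- sim[[paste0(ix, "_raw")]]
      t0 <- tg[[ix]]
      # the sex-gap target is the partial (demographics-held-fixed)
      # coefficient, as published; estimate it from the true-model fit
      gap_sim <- unname(stats::coef(stats::lm(
        y ~ I(sim$age^2) + sim$education +
          ifelse(sim$sex == "M", 0.5, -0.5)))[4])
      # accumulate one Newton-type correction per moment, then re-solve the
      # closed-form system from the corrected targets
      w <- work[[ix]]
      w$mean <- w$mean + (t0$mean - mean(y))
      w$sd <- sqrt(max(w$sd^2 + (t0$sd^2 - stats::var(y)), 0.25))
      w$r_age <- w$r_age + (t0$r_age - stats::cor(sim$age, y))
      w$r_edu <- w$r_edu + (t0$r_edu - stats::cor(sim$education, y))
      w$sex_gap <- w$sex_gap + (t0$sex_gap - gap_sim)
      work[[ix]] <- w
      cfg$score_model[[ix]] <- solve_index_coefs(w, mom, toupper(ix))
    }
  }

  # Item difficulties: logit fixed point over the simulated ER distribution.
  er_tab <- tabulate(sim$er_raw + 1L, nbins = 61L) / length(sim$er_raw)
  a <- stats::qlogis(tg$emotion_means / 10)
  for (it in 1:12) {
    tl <- tilt_table(a)
    means <- er_subscore_means(a, tl, er_tab)
    a <- a + (stats::qlogis(tg$emotion_means / 10) -
                stats::qlogis(pmin(pmax(means / 10, 1e-6), 1 - 1e-6)))
  }
  cfg$item_model$logits <- a

  # Covariate loadings from the simulated index correlation structure.
  z_er <- (sim$er_raw - mean(sim$er_raw)) / stats::sd(sim$er_raw)
  z_ea <- (sim$ea_raw - mean(sim$ea_raw)) / stats::sd(sim$ea_raw)
  rho <- stats::cor(z_er, z_ea)
  old <- sim$age >= 50
  rho50 <- stats::cor(z_er[old], z_ea[old])
  solve_loadings <- function(r1, r2, rho) {
    as.numeric(solve(rbind(c(1, rho), c(rho, 1)), c(r1, r2)))
  }
  cm <- tg$moca
  cl <- solve_loadings(cm$r_er, cm$r_ea, rho50)
  quad50 <- cl[1]^2 + cl[2]^2 + 2 * rho50 * cl[1] * cl[2]
  if (quad50 >= 1) stop("infeasible MoCA correlation targets", call. = FALSE)
  it <- tg$iri
  L <- solve_loadings(it$r_er * it$sd, it$r_ea * it$sd, rho)
  lambda_g <- 2.2
  var_load <- L[1]^2 + L[2]^2 + 2 * rho * L[1] * L[2]
  s2 <- (it$sd^2 - var_load - 16 * lambda_g^2) / 4
  if (s2 <= 0) {
    lambda_g <- sqrt(max((it$sd^2 - var_load - 4) / 16, 0.01))
    s2 <- 1
  }
  cfg$covariate_model <- list(
    er_mean = mean(sim$er_raw), er_sd = stats::sd(sim$er_raw),
    ea_mean = mean(sim$ea_raw), ea_sd = stats::sd(sim$ea_raw),
    rho = rho,
    moca = list(mean = cm$mean, sd = cm$sd,
                er_mean = mean(sim$er_raw[old]),
                er_sd = stats::sd(sim$er_raw[old]),
                ea_mean = mean(sim$ea_raw[old]),
                ea_sd = stats::sd(sim$ea_raw[old]),
                c_er = cl[1], c_ea = cl[2],
                c_resid = sqrt(1 - quad50)),
    iri = list(sub_mean = tg$iri$mean / 4,
               l_er = L[1], l_ea = L[2],
               pt_share = 0.6,   # share of the EA loading carried by PT
               lambda_g = lambda_g, resid_sd = sqrt(s2))
  )
  cfg$n <- 0L
  cfg$seed <- 1L
  validate_generator_config(cfg)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("EAR synthetic-cohort generator configuration\n")
  for (ix in c("er", "ea")) {
    sm <- x$score_model[[ix]]
    cat(sprintf(
      "  %s: intercept %.2f, beta_age2 %.3g, beta_edu %.3g, beta_sex %.3f, sigma %.3f\n",
      toupper(ix), sm$intercept, sm$beta_age2, sm$beta_edu, sm$beta_sex,
      sm$sigma_resid))
  }
  cat("  item success (logit):",
      paste(sprintf("%s %.2f", names(x$item_model$logits),
                    x$item_model$logits), collapse = ", "), "\n")
  cat(sprintf("  strata cells: %d (n counts total %d)\n",
              nrow(x$strata), sum(x$strata$count)))
  invisible(x)
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (nrow(cfg$strata) == 0L) stop("empty strata table", call. = FALSE)
  if (abs(sum(cfg$strata$weight) - 1) > 1e-8) {
    stop("strata weights must sum to 1", call. = FALSE)
  }
  p <- stats::plogis(cfg$item_model$logits)
  if (any(p <= 0 | p >= 1)) {
    stop("item success probabilities must lie in (0, 1)", call. = FALSE)
  }
  for (ix in c("er", "ea")) {
    if (cfg$score_model[[ix]]$sigma_resid <= 0) {
      stop("sigma_resid must be positive", call. = FALSE)
    }
  }
  invisible(cfg)
}

# Cached default configuration (deterministic; see calibrate_generator).
.earnorms_cache <- new.env(parent = emptyenv())

#' Default calibrated generator configuration
#'
#' Returns (and caches) the result of [calibrate_generator()] under the
#' published reference targets.
#' @return A `generator_config`.
#' @export
default_generator_config <- function() {
  if (is.null(.earnorms_cache$default_config)) {
    .earnorms_cache$default_config <- calibrate_generator()
  }
  .earnorms_cache$default_config
}

# ---------------------------------------------------------------------------
# Sampling

#' Sample demographic skeletons
#'
#' Draws `config$n` participants from the stratified demographic
#' distribution: a stratum (age band x education band x sex) is sampled with
#' its published frequency, then age and education are drawn integer-uniform
#' within the band.
#'
#' @param config A `generator_config` with `n` and `seed` set (see
#'   [simulate_cohort()] for the usual entry point).
#' @return Data frame `participant_id`, `age`, `education`, `sex`.
#' @export
sample_demographics <- function(config) {
  validate_generator_config(config)
  n <- config$n
  if (n == 0L) {
    return(data.frame(participant_id = character(0), age = integer(0),
                      education = integer(0), sex = character(0),
                      stringsAsFactors = FALSE))
  }
  st <- config$strata
  with_seed(substream_seed(config$seed, 1L), {
    idx <- sample.int(nrow(st), n, replace = TRUE, prob = st$weight)
    age <- st$age_lo[idx] +
      floor(stats::runif(n) * (st$age_hi[idx] - st$age_lo[idx] + 1L))
    edu <- st$edu_lo[idx] +
      floor(stats::runif(n) * (st$edu_hi[idx] - st$edu_lo[idx] + 1L))
  })
  data.frame(participant_id = sprintf("P%06d", seq_len(n)),
             age = as.integer(pmin(pmax(age, 17L), 88L)),
             education = as.integer(pmin(pmax(edu, 5L), 24L)),
             sex = st$sex[idx], stringsAsFactors = FALSE)
}

#' Sample raw scores (and covariates) onto demographic skeletons
#'
#' Each index is generated from a Gaussian latent variable
#' `intercept + beta_age2 (age^2 - c) + beta_edu (edu - m) + beta_sex s + e`
#' with deviation-coded sex (`+1/2` male, `-1/2` female, so the male-female
#' raw gap equals `beta_sex`), rounded to the nearest integer and truncated
#' to 0-60.  MoCA (participants aged 50 or over only) and IRI subscale
#' scores are generated as Gaussian covariates loaded on the standardized
#' indices, scaled to their published moments.
#'
#' @param skeletons Output of [sample_demographics()].
#' @param config A `generator_config`.
#' @param covariates Generate MoCA/IRI columns? Default `TRUE`.
#' @return `skeletons` with columns `er_raw`, `ea_raw` and, if requested,
#'   `moca`, `iri_total`, `iri_pt`, `iri_f`, `iri_ec`, `iri_pd` appended.
#' @export
sample_scores <- function(skeletons, config, covariates = TRUE) {
  validate_generator_config(config)
  n <- nrow(skeletons)
  out <- skeletons
  if (n == 0L) {
    for (cl in c("er_raw", "ea_raw")) out[[cl]] <- integer(0)
    return(out)
  }
  mom <- config$moments
  sexcode <- ifelse(skeletons$sex == "M", 0.5, -0.5)
  with_seed(substream_seed(config$seed, 2L), {
    for (ix in c("er", "ea")) {
      sm <- config$score_model[[ix]]
      latent <- sm$intercept +
        sm$beta_age2 * (skeletons$age^2 - mom$mean_age2) +
        sm$beta_edu * (skeletons$education - mom$mean_edu) +
        sm$beta_sex * sexcode +
        stats::rnorm(n, 0, sm$sigma_resid)
      clipped <- mean(latent < -0.5 | latent > 60.5)
      if (clipped > 0.20) {
        warning(sprintf(
          "calibration: %.1f%% of latent %s scores truncated at the 0-60 bounds",
          100 * clipped, toupper(ix)), call. = FALSE)
      }
      out[[paste0(ix, "_raw")]] <-
        as.integer(pmin(pmax(round(latent), 0), 60))
    }
  })
  if (covariates && !is.null(config$covariate_model)) {
    out <- sample_covariates(out, config)
  }
  out
}

# MoCA and IRI covariates; plumbing for the association analyses, scaled to
# the published covariate moments and correlation targets.
sample_covariates <- function(cohort, config) {
  cm <- config$covariate_model
  n <- nrow(cohort)
  with_seed(substream_seed(config$seed, 3L), {
    # IRI: four 0-28 subscales; Fantasy carries the ER loading and part of
    # the EA loading, Perspective Taking the rest of the EA loading; a common
    # empathy factor spreads shared variance across all four subscales.
    z_er <- (cohort$er_raw - cm$er_mean) / cm$er_sd
    z_ea <- (cohort$ea_raw - cm$ea_mean) / cm$ea_sd
    ir <- cm$iri
    g <- stats::rnorm(n)
    sub <- function(load_er, load_ea) {
      pmin(pmax(round(ir$sub_mean + load_er * z_er + load_ea * z_ea +
                        ir$lambda_g * g +
                        stats::rnorm(n, 0, ir$resid_sd)), 0), 28)
    }
    pt <- sub(0, ir$pt_share * ir$l_ea)
    fa <- sub(ir$l_er, (1 - ir$pt_share) * ir$l_ea)
    ec <- sub(0, 0)
    pd <- sub(0, 0)
    cohort$iri_pt <- as.integer(pt)
    cohort$iri_f <- as.integer(fa)
    cohort$iri_ec <- as.integer(ec)
    cohort$iri_pd <- as.integer(pd)
    cohort$iri_total <- as.integer(pt + fa + ec + pd)

    # MoCA: only administered from age 50, standardized within that subgroup.
    mo <- cm$moca
    old <- cohort$age >= 50
    moca <- rep(NA_integer_, n)
    if (any(old)) {
      z1 <- (cohort$er_raw[old] - mo$er_mean) / mo$er_sd
      z2 <- (cohort$ea_raw[old] - mo$ea_mean) / mo$ea_sd
      lat <- mo$mean + mo$sd * (mo$c_er * z1 + mo$c_ea * z2 +
                                  mo$c_resid * stats::rnorm(sum(old)))
      moca[old] <- as.integer(pmin(pmax(round(lat), 0), 30))
    }
    cohort$moca <- moca
  })
  cohort
}

# ---------------------------------------------------------------------------
# Item-level simulation

# For an ER total k in 1..59, the per-emotion success probabilities are the
# base difficulties tilted on the logit scale by t(k), where t solves
# sum_e 10 plogis(a_e + t) = k.  Returns the 61-entry lookup (k = 0..60).
tilt_table <- function(logits) {
  vapply(0:60, function(k) {
    if (k == 0L) return(-Inf)
    if (k == 60L) return(Inf)
    stats::uniroot(function(t) sum(10 * stats::plogis(logits + t)) - k,
                   interval = c(-40, 40), tol = 1e-10)$root
  }, numeric(1))
}

er_subscore_means <- function(logits, tilt, er_freq) {
  ks <- 0:60
  q <- stats::plogis(outer(logits, tilt, "+"))  # 6 x 61
  q[, 1] <- 0
  q[, 61] <- 1
  as.numeric(q %*% (10 * er_freq))
}

#' Simulate item-level responses for a cohort
#'
#' Generates one trial response per stimulus and participant such that
#' scoring them with [score_responses()] reproduces the participant's stored
#' `er_raw` and `ea_raw` exactly.  Emotion correctness is drawn per item with
#' ability-tilted per-emotion success probabilities (harder emotions such as
#' fear stay hardest at every ability level), then a minimal weighted repair
#' step enforces the exact total.  Incorrect responses to fear items are
#' biased towards "surprise", reflecting the fear-surprise confusion typical
#' of facial-emotion data; other errors are uniform over the remaining
#' alternatives.  Authenticity correctness uses a single per-participant
#' accuracy `ea_raw/60`, repaired to the exact total in the same way.
#'
#' @param cohort Cohort data frame with `participant_id`, `er_raw`, `ea_raw`.
#' @param manifest An `ear_manifest`.
#' @param config A `generator_config` (for item difficulties and the
#'   confusion weight); its `seed` drives the draw.
#' @return Long data frame: `participant_id`, `stimulus_id`,
#'   `chosen_emotion`, `authenticity_judgment`.
#' @export
simulate_responses <- function(cohort, manifest = build_manifest(seed = 1L),
                               config = default_generator_config()) {
  validate_manifest(manifest)
  n <- nrow(cohort)
  if (n == 0L) {
    return(data.frame(participant_id = character(0),
                      stimulus_id = character(0),
                      chosen_emotion = character(0),
                      authenticity_judgment = character(0),
                      stringsAsFactors = FALSE))
  }
  logits <- config$item_model$logits[ear_emotions()]
  tilt <- tilt_table(logits)
  emo_item <- manifest$emotion
  auth_item <- manifest$authenticity
  emo_idx <- match(emo_item, ear_emotions())
  n_item <- nrow(manifest)

  with_seed(substream_seed(config$seed, 4L), {
    # ability-tilted success probabilities, participants x items
    q_emo <- stats::plogis(outer(tilt[cohort$er_raw + 1L], logits[emo_idx],
                                 "+"))
    q_emo[cohort$er_raw == 0L, ] <- 0
    q_emo[cohort$er_raw == 60L, ] <- 1
    hit_er <- matrix(stats::runif(n * n_item) < q_emo, n, n_item)
    q_ea <- cohort$ea_raw / 60
    hit_ea <- matrix(stats::runif(n * n_item) <
                       matrix(q_ea, n, n_item), n, n_item)

    repair <- function(hits, k, w_up, w_down) {
      d <- k - sum(hits)
      if (d > 0) {
        cand <- which(!hits)
        w <- w_up[cand]
        if (all(w <= 0)) w <- rep(1, length(cand))
        sel <- if (length(cand) == 1L) cand else
          sample(cand, d, prob = pmax(w, 1e-12))
        hits[sel] <- TRUE
      } else if (d < 0) {
        cand <- which(hits)
        w <- w_down[cand]
        if (all(w <= 0)) w <- rep(1, length(cand))
        sel <- if (length(cand) == 1L) cand else
          sample(cand, -d, prob = pmax(w, 1e-12))
        hits[sel] <- FALSE
      }
      hits
    }
    for (i in seq_len(n)) {
      qi <- q_emo[i, ]
      hit_er[i, ] <- repair(hit_er[i, ], cohort$er_raw[i], qi, 1 - qi)
      hit_ea[i, ] <- repair(hit_ea[i, ], cohort$ea_raw[i],
                            rep(q_ea[i], n_item), rep(1 - q_ea[i], n_item))
    }

    # response labels
    chosen <- matrix(rep(emo_item, each = n), n, n_item)
    wrong <- which(!hit_er)
    if (length(wrong)) {
      item_of <- ((wrong - 1L) %/% n) + 1L
      true_emo <- emo_item[item_of]
      pick <- character(length(wrong))
      u <- stats::runif(length(wrong))
      for (e in ear_emotions()) {
        sel <- true_emo == e
        if (!any(sel)) next
        alt <- setdiff(ear_emotions(), e)
        if (e == "fear") {
          p_conf <- config$item_model$fear_to_surprise
          others <- setdiff(alt, "surprise")
          br <- c(p_conf, p_conf + cumsum(rep((1 - p_conf) / 4, 4)))
          lab <- c("surprise", others)
          pick[sel] <- lab[findInterval(u[sel], c(0, br),
                                        rightmost.closed = TRUE)]
        } else {
          pick[sel] <- alt[ceiling(u[sel] * 5)]
        }
      }
      chosen[wrong] <- pick
    }
    auth_true <- matrix(rep(auth_item, each = n), n, n_item)
    auth_resp <- ifelse(hit_ea, auth_true,
                        ifelse(auth_true == "authentic", "posed",
                               "authentic"))
  })
  data.frame(
    participant_id = rep(cohort$participant_id, times = n_item),
    stimulus_id = rep(manifest$stimulus_id, each = n),
    chosen_emotion = as.vector(chosen),
    authenticity_judgment = as.vector(auth_resp),
    stringsAsFactors = FALSE
  )
}

#' Simulate item responses for a single participant
#'
#' Convenience wrapper around [simulate_responses()] for one participant row.
#' @param participant One-row data frame (or list) with `participant_id`,
#'   `er_raw`, `ea_raw`.
#' @inheritParams simulate_responses
#' @return Data frame of 60 trial responses.
#' @export
sample_item_level <- function(participant, manifest = build_manifest(seed = 1L),
                              config = default_generator_config()) {
  df <- as.data.frame(participant, stringsAsFactors = FALSE)
  simulate_responses(df[1, , drop = FALSE], manifest, config)
}

# ---------------------------------------------------------------------------
# Cohort entry point and IO

#' Simulate a synthetic normative cohort
#'
#' @param n Number of participants.
#' @param seed Master seed; all stages draw from deterministic substreams of
#'   it.
#' @param config A `generator_config`; defaults to the published-target
#'   calibration.
#' @param items Also simulate item-level responses (attached as attribute
#'   `"responses"`)?
#' @param covariates Generate MoCA/IRI columns?
#' @param manifest Manifest used when `items = TRUE`.
#' @return Cohort data frame; when `items = TRUE` the long response table is
#'   attached as `attr(, "responses")`.
#' @examples
#' coh <- simulate_cohort(200, seed = 42)
#' summary(coh$er_raw)
#' @export
simulate_cohort <- function(n, seed = 1L, config = default_generator_config(),
                            items = FALSE, covariates = TRUE,
                            manifest = build_manifest(seed = 1L)) {
  config$n <- as.integer(n)
  config$seed <- as.integer(seed)
  cohort <- sample_scores(sample_demographics(config), config,
                          covariates = covariates)
  if (items) {
    attr(cohort, "responses") <- simulate_responses(cohort, manifest, config)
  }
  cohort
}

#' Cohort CSV round trip
#'
#' Cohorts are exchanged as CSV with columns `participant_id`, `age`,
#' `education`, `sex`, `er_raw`, `ea_raw`, `moca`, `iri_total`, `iri_pt`,
#' `iri_f`, `iri_ec`, `iri_pd`; absent covariates are empty fields.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("participant_id", "age", "education", "sex", "er_raw", "ea_raw",
            "moca", "iri_total", "iri_pt", "iri_f", "iri_ec", "iri_pd")
  for (cl in setdiff(cols, names(cohort))) cohort[[cl]] <- NA
  utils::write.csv(cohort[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname cohort-io
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generator configuration YAML round trip
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @name config-io
NULL

#' @rdname config-io
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  x <- unclass(config)
  x$strata <- as.list(x$strata)
  x$targets <- NULL
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname config-io
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$strata <- as.data.frame(x$strata, stringsAsFactors = FALSE)
  # guard against serialisation rounding
  x$strata$weight <- x$strata$weight / sum(x$strata$weight)
  for (nm in c("logits")) {
    x$item_model[[nm]] <- unlist(x$item_model[[nm]])
  }
  x$emotion_difficulty <- unlist(x$emotion_difficulty)
  class(x) <- "generator_config"
  validate_generator_config(x)
  x
}
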