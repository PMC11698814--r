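# Regression-based demographic adjustment of EAR raw scores
# (Capitani-style norming: fit raw score on transformed demographic
# predictors, retain the significant ones, correct each raw score by the
# negated predicted demographic deviation).

transform_value <- function(term, age, education) {
  switch(term,
         age = age,
         age2 = age^2,
         log_age = log(age),
         education = education,
         log_education = log(education),
         stop("unknown predictor transform: ", term, call. = FALSE))
}

#' Fit and select a demographic adjustment model
#'
#' Fits a multiple linear regression of the raw index score on candidate
#' demographic transforms and deviation-coded sex, retains the predictors
#' significant at `alpha`, and refits on the retained set.  Because the age
#' transforms (and likewise the education transforms) are nearly collinear,
#' only the best-fitting single transform per family (largest marginal
#' correlation with the raw score) enters the multiple model; this keeps the
#' fit well conditioned and mirrors standard norming practice of choosing
#' one transform of each background variable.
#'
#' The returned model stores *correction* coefficients: the negated fitted
#' coefficients, centred on the cohort means of the transforms, so that the
#' adjustment compensates the demographic effect (corrections are positive
#' at older ages when performance declines with age).
#'
#' @param cohort Cohort data frame with `age`, `education`, `sex` and the
#'   raw score column (`er_raw`/`ea_raw`).
#' @param index_name `"ER"` or `"EA"`.
#' @param candidates Candidate predictor transforms; sex is always a
#'   candidate.
#' @param alpha Retention level for predictor p-values.
#' @return An `adjustment_model` object.
#' @export
select_model <- function(cohort, index_name = c("ER", "EA"),
                         candidates = c("age", "age2", "log_age",
                                        "education", "log_education"),
                         alpha = 0.05) {
  index_name <- match.arg(index_name)
  ycol <- if (index_name == "ER") "er_raw" else "ea_raw"
  if (!ycol %in% names(cohort)) {
    stop("cohort lacks column ", ycol, call. = FALSE)
  }
  if (nrow(cohort) < 30L) {
    stop("cohort size must be at least 30 to fit an adjustment model",
         call. = FALSE)
  }
  y <- cohort[[ycol]]
  if (anyNA(y)) stop("missing raw scores in cohort", call. = FALSE)

  fam <- list(age = intersect(candidates, c("age", "age2", "log_age")),
              edu = intersect(candidates, c("education", "log_education")))
  sexcode <- ifelse(cohort$sex == "M", 0.5, -0.5)
  # best-fitting single transform per family: largest R^2 of the multiple
  # model containing that transform plus the other background variables
  pick_best <- function(terms, others) {
    if (length(terms) <= 1L) return(terms)
    r2 <- vapply(terms, function(tm) {
      xs <- cbind(transform_value(tm, cohort$age, cohort$education), others)
      summary(stats::lm(y ~ xs))$r.squared
    }, numeric(1))
    names(which.max(r2))
  }
  age_t <- pick_best(fam$age,
                     cbind(if (length(fam$edu)) cohort$education, sexcode))
  edu_t <- pick_best(fam$edu, cbind(
    if (length(age_t)) transform_value(age_t, cohort$age, cohort$education),
    sexcode))
  chosen <- c(age_t, edu_t)
  X <- as.data.frame(c(
    lapply(stats::setNames(chosen, chosen), function(tm) {
      transform_value(tm, cohort$age, cohort$education)
    }),
    list(sexcode = sexcode)
  ), check.names = FALSE)

  if (ncol(X) > 1L) {
    kp <- kappa(scale(as.matrix(X)), exact = TRUE)
    if (!is.finite(kp) || kp > 100) {
      stop("candidate predictor set is too collinear (condition number ",
           round(kp, 1), "); drop redundant transforms", call. = FALSE)
    }
  }

  fit_full <- stats::lm(y ~ ., data = X)
  pv <- summary(fit_full)$coefficients[-1, 4]
  retained <- names(pv)[pv < alpha]
  if (length(retained)) {
    fit <- stats::lm(y ~ ., data = X[, retained, drop = FALSE])
  } else {
    fit <- stats::lm(y ~ 1)
  }
  coefs <- stats::coef(fit)[-1]

  terms <- list()
  for (tm in setdiff(retained, "sexcode")) {
    terms[[tm]] <- list(
      coef = -unname(coefs[tm]),
      center = mean(transform_value(tm, cohort$age, cohort$education))
    )
  }
  sex_offset <- if ("sexcode" %in% retained) -unname(coefs["sexcode"]) / 2
                else 0
  new_adjustment_model(
    index_name = index_name,
    terms = terms,
    sex_offset = sex_offset,
    age_range = range(cohort$age),
    fit_diagnostics = list(
      r_squared = summary(fit)$r.squared,
      p_values = pv,
      retained = retained,
      n = nrow(cohort)
    )
  )
}

new_adjustment_model <- function(index_name, terms, sex_offset, age_range,
                                 fit_diagnostics = NULL,
                                 provenance = "fitted") {
  m <- list(index_name = index_name, terms = terms, sex_offset = sex_offset,
            age_range = age_range, fit_diagnostics = fit_diagnostics,
            provenance = provenance)
  m$beta_age2 <- if (!is.null(terms$age2)) terms$age2$coef else 0
  m$centering_c <- if (!is.null(terms$age2)) terms$age2$center else NA_real_
  if (!is.null(terms$age2) && m$centering_c <= 0) {
    stop("centering constant must be positive", call. = FALSE)
  }
  allowed <- c("age", "age2", "log_age", "education", "log_education")
  if (!all(names(terms) %in% allowed)) {
    stop("retained predictors must be among: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  class(m) <- "adjustment_model"
  m
}

#' Published EAR adjustment models
#'
#' The adjustment equations of the published norms: correction
#' `0.002 (age^2 - 1811.257)` for both indices, plus a sex offset of
#' `+0.818` (ER) or `+0.420` (EA) for males and the negative for females.
#' The sign convention makes corrections positive at older ages, matching
#' the published correction grids (which compensate the age-related
#' performance decline).  Valid for ages 17-88, the age range of the
#' normative sample.
#'
#' @param index_name `"ER"` or `"EA"`.
#' @return An `adjustment_model`.
#' @examples
#' adjust_score(50, age = 85, sex = "M", model = published_adjustment_model("EA"))
#' @export
published_adjustment_model <- function(index_name = c("ER", "EA")) {
  index_name <- match.arg(index_name)
  new_adjustment_model(
    index_name = index_name,
    terms = list(age2 = list(coef = 0.002, center = 1811.257)),
    sex_offset = if (index_name == "ER") 0.818 else 0.420,
    age_range = c(17, 88),
    provenance = "EAR Italian adult norms, version 1.0"
  )
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf("EAR %s adjustment model (%s)\n", x$index_name, x$provenance))
  if (!length(x$terms) && x$sex_offset == 0) {
    cat("  identity adjustment (no predictors retained)\n")
    return(invisible(x))
  }
  for (tm in names(x$terms)) {
    cat(sprintf("  + %.6g * (%s - %.6g)\n", x$terms[[tm]]$coef, tm,
                x$terms[[tm]]$center))
  }
  if (x$sex_offset != 0) {
    cat(sprintf("  %+.3f if male / %+.3f if female\n", x$sex_offset,
                -x$sex_offset))
  }
  cat(sprintf("  valid ages: %d-%d\n", x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Demographically adjust a raw score
#'
#' `adjusted = raw + sum(coef * (transform - center)) + sex offset`, the sex
#' offset added for males and subtracted for females.  At
#' `age = sqrt(centering constant)` the age correction vanishes and the
#' adjustment reduces to the sex offset alone.
#'
#' @param raw Raw score(s), 0-60.
#' @param age Age(s) in years; must lie within the model's validity range.
#' @param sex `"M"` or `"F"` (recycled).
#' @param model An `adjustment_model`.
#' @param education Years of education; required only when the model retains
#'   an education transform.
#' @return Adjusted score(s), full precision.
#' @export
adjust_score <- function(raw, age, sex, model, education = NULL) {
  stopifnot(inherits(model, "adjustment_model"))
  if (any(raw < 0 | raw > 60)) {
    stop("raw scores must lie in [0, 60]", call. = FALSE)
  }
  if (any(age < model$age_range[1] | age > model$age_range[2])) {
    stop(sprintf("age outside the norms' validity range [%d, %d]",
                 model$age_range[1], model$age_range[2]), call. = FALSE)
  }
  if (!all(sex %in% c("M", "F"))) {
    stop('sex must be "M" or "F"', call. = FALSE)
  }
  needs_edu <- any(grepl("education", names(model$terms)))
  if (needs_edu && is.null(education)) {
    stop("model retains an education term; supply `education`",
         call. = FALSE)
  }
  adj <- raw
  for (tm in names(model$terms)) {
    adj <- adj + model$terms[[tm]]$coef *
      (transform_value(tm, age, education) - model$terms[[tm]]$center)
  }
  adj + ifelse(sex == "M", model$sex_offset, -model$sex_offset)
}

#' Correction grid by age and sex
#'
#' Tabulates the adjustment term (the correction added to a raw score) over
#' a set of ages for both sexes, reproducing the layout of the published
#' grids.  Displayed values follow the published rounding convention
#' (3-decimal intermediate, then 2 decimals, halves away from zero); pass
#' `digits = NULL` for full precision.
#'
#' @param model An `adjustment_model` without education terms.
#' @param ages Ages to tabulate.
#' @param digits Display decimals (default 2), or `NULL` for none.
#' @return Data frame with columns `age`, `M`, `F`.
#' @examples
#' correction_grid(published_adjustment_model("ER"))
#' @export
correction_grid <- function(model, ages = seq(25, 85, by = 5), digits = 2) {
  if (!length(ages)) stop("`ages` must be non-empty", call. = FALSE)
  if (any(grepl("education", names(model$terms)))) {
    stop("correction grids are defined for age/sex models only",
         call. = FALSE)
  }
  term <- function(sex) {
    adj <- adjust_score(rep(0, length(ages)), ages, rep(sex, length(ages)),
                        model)
    if (is.null(digits)) adj else display_round(adj, digits)
  }
  # grids may extend past the cohort age range for display; bypass the range
  # check by widening temporarily
  model$age_range <- range(c(model$age_range, ages))
  data.frame(age = ages, M = term("M"), F = term("F"))
}

#' Adjustment model JSON round trip
#'
#' @param model An `adjustment_model`.
#' @param path File path.
#' @name adjustment-io
NULL

#' @rdname adjustment-io
#' @export
write_adjustment_model <- function(model, path) {
  stopifnot(inherits(model, "adjustment_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname adjustment-io
#' @export
read_adjustment_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  new_adjustment_model(index_name = x$index_name,
                       terms = lapply(x$terms, as.list),
                       sex_offset = x$sex_offset,
                       age_range = unlist(x$age_range),
                       fit_diagnostics = x$fit_diagnostics,
                       provenance = x$provenance %||% "loaded")
}
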