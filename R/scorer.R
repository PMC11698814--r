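# Clinical scoring front-end: apply the published EAR norms (adjustment
# constants and Equivalent Score thresholds) to individual raw scores.

norms_checksum <- function(x) {
  vals <- c(x$er$adjustment$beta_age2, x$er$adjustment$centering_c,
            x$er$adjustment$sex_offset, unlist(x$er$thresholds),
            x$ea$adjustment$beta_age2, x$ea$adjustment$centering_c,
            x$ea$adjustment$sex_offset, unlist(x$ea$thresholds))
  sum(round(abs(vals) * 1000)) %% 1000000007
}

#' Published EAR norms
#'
#' Loads the versioned norms resource shipped with the package: the
#' adjustment constants for both indices and the published Equivalent Score
#' thresholds (ER: oTL 42.35, inner edges 46.09 / 48.87, median 51.45;
#' EA: 41.25, 45.09 / 47.77, 50.62), encoded as half-open intervals with
#' printed two-decimal edges as inclusive upper bounds.
#'
#' @param path Optional path to an alternative norms JSON resource.
#' @return A `published_norms` object.
#' @examples
#' norms <- published_norms()
#' norms$er$bands
#' @export
published_norms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ear_norms_v1.json", package = "earnorms",
                        mustWork = TRUE)
  }
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  build_norms(x)
}

build_norms <- function(x) {
  mk_model <- function(ix) {
    a <- x[[ix]]$adjustment
    new_adjustment_model(
      index_name = toupper(ix),
      terms = list(age2 = list(coef = a$beta_age2, center = a$centering_c)),
      sex_offset = a$sex_offset,
      age_range = unlist(x$age_range),
      provenance = x$provenance
    )
  }
  mk_bands <- function(ix) {
    th <- unlist(x[[ix]]$thresholds)
    if (any(diff(th) <= 0)) {
      stop("published thresholds must be strictly increasing", call. = FALSE)
    }
    es_bands_from_thresholds(th[1], th[2], th[3], th[4])
  }
  if (!is.null(x$checksum) && x$checksum != norms_checksum(x)) {
    stop("norms resource checksum mismatch: file corrupted or edited",
         call. = FALSE)
  }
  out <- list(
    version = x$version,
    provenance = x$provenance,
    age_range = unlist(x$age_range),
    education_range = unlist(x$education_range),
    caution_age = x$caution_age %||% 65,
    er = list(adjustment = mk_model("er"), bands = mk_bands("er")),
    ea = list(adjustment = mk_model("ea"), bands = mk_bands("ea"))
  )
  class(out) <- "published_norms"
  out
}

#' @export
print.published_norms <- function(x, ...) {
  cat(sprintf("EAR published norms, version %s\n", x$version))
  cat(" ", x$provenance, "\n")
  print(x$er$adjustment)
  print(x$er$bands)
  print(x$ea$adjustment)
  print(x$ea$bands)
  invisible(x)
}

#' Write a norms resource
#'
#' Serialises a `published_norms` object back to the JSON resource format
#' (with recomputed checksum), so that exported and reloaded norms produce
#' identical reports.
#'
#' @param norms A `published_norms` object.
#' @param path File path.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "published_norms"))
  enc <- function(ix) {
    m <- norms[[ix]]$adjustment
    list(adjustment = list(beta_age2 = m$beta_age2,
                           centering_c = m$centering_c,
                           sex_offset = m$sex_offset),
         thresholds = as.list(norms[[ix]]$bands$thresholds))
  }
  x <- list(version = norms$version, provenance = norms$provenance,
            age_range = as.list(norms$age_range),
            education_range = as.list(norms$education_range),
            caution_age = norms$caution_age,
            er = enc("er"), ea = enc("ea"))
  x$checksum <- norms_checksum(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Score an individual against the published EAR norms
#'
#' Adjusts the raw ER and EA indices for age and sex, assigns Equivalent
#' Scores against the published thresholds, and returns an interpretive
#' report with the standard qualitative labels (0 "abnormal", 1
#' "borderline", 2 "low-end normal", 3-4 "normal").  Ages outside the
#' norms' validity range produce a report with a prominent warning and no
#' adjusted/Equivalent scores; ages above the caution threshold (default
#' 65) carry a standing caution, since elderly participants are sparsely
#' represented in the normative sample.
#'
#' @param er_raw,ea_raw Integer raw scores, 0-60.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param norms A `published_norms` object.
#' @param education Optional years of education; values outside the
#'   normative range add a warning to the report.
#' @return An `individual_report` object.
#' @examples
#' score_individual(er_raw = 50, ea_raw = 45, age = 63, sex = "F")
#' @export
score_individual <- function(er_raw, ea_raw, age, sex,
                             norms = published_norms(), education = NULL) {
  for (v in list(er_raw = er_raw, ea_raw = ea_raw)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v > 60 || v != round(v)) {
      stop("raw scores must be single integers in [0, 60]", call. = FALSE)
    }
  }
  if (!sex %in% c("M", "F")) stop('sex must be "M" or "F"', call. = FALSE)
  warnings <- character(0)
  in_range <- age >= norms$age_range[1] && age <= norms$age_range[2]
  if (!in_range) {
    warnings <- c(warnings, sprintf(
      "age %g outside the normative range [%d, %d]: norms not applicable, Equivalent Scores withheld",
      age, norms$age_range[1], norms$age_range[2]))
  } else if (age > norms$caution_age) {
    warnings <- c(warnings, sprintf(
      "age %g above %d: elderly are sparsely represented in the normative sample; interpret adjusted scores with caution",
      age, norms$caution_age))
  }
  if (!is.null(education) &&
      (education < norms$education_range[1] ||
         education > norms$education_range[2])) {
    warnings <- c(warnings, sprintf(
      "education %g outside the normative range [%d, %d]",
      education, norms$education_range[1], norms$education_range[2]))
  }

  one <- function(ix, raw) {
    if (!in_range) {
      return(list(raw = raw, adjusted = NA_real_, es = NA_integer_,
                  label = NA_character_))
    }
    adj <- adjust_score(raw, age, sex, norms[[ix]]$adjustment)
    es <- assign_es(adj, norms[[ix]]$bands)
    list(raw = raw, adjusted = adj, es = es,
         label = norms[[ix]]$bands$labels[es + 1L])
  }
  out <- list(age = age, sex = sex, education = education,
              er = one("er", er_raw), ea = one("ea", ea_raw),
              warnings = warnings, norms_version = norms$version)
  class(out) <- "individual_report"
  out
}

#' @export
print.individual_report <- function(x, ...) {
  cat("EAR individual report (norms version", x$norms_version, ")\n")
  cat(sprintf("  age %g, sex %s%s\n", x$age, x$sex,
              if (is.null(x$education)) ""
              else sprintf(", education %g y", x$education)))
  for (ix in c("er", "ea")) {
    r <- x[[ix]]
    if (is.na(r$adjusted)) {
      cat(sprintf("  %s: raw %d, adjusted --, ES withheld\n", toupper(ix),
                  r$raw))
    } else {
      cat(sprintf("  %s: raw %d, adjusted %.2f, ES %d (%s)\n", toupper(ix),
                  r$raw, r$adjusted, r$es, r$label))
    }
  }
  for (w in x$warnings) cat("  ! ", w, "\n", sep = "")
  invisible(x)
}

#' Batch-score a cohort table
#'
#' Appends adjusted-score and Equivalent Score columns to a cohort data
#' frame (columns `age`, `sex`, `er_raw`, `ea_raw`).  Rows with ages
#' outside the normative range get `NA` in the appended columns.
#'
#' @param cohort Cohort data frame.
#' @param norms A `published_norms` object.
#' @return The cohort with `er_adj`, `er_es`, `ea_adj`, `ea_es` appended.
#' @export
score_cohort <- function(cohort, norms = published_norms()) {
  ok <- cohort$age >= norms$age_range[1] & cohort$age <= norms$age_range[2]
  for (ix in c("er", "ea")) {
    adj <- rep(NA_real_, nrow(cohort))
    if (any(ok)) {
      adj[ok] <- adjust_score(cohort[[paste0(ix, "_raw")]][ok],
                              cohort$age[ok], cohort$sex[ok],
                              norms[[ix]]$adjustment)
    }
    cohort[[paste0(ix, "_adj")]] <- adj
    es <- rep(NA_integer_, nrow(cohort))
    es[ok] <- assign_es(adj[ok], norms[[ix]]$bands)
    cohort[[paste0(ix, "_es")]] <- es
  }
  cohort
}
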