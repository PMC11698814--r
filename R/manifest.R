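# EAR test data model: stimulus manifest and deterministic scoring.

#' Build an EAR stimulus manifest
#'
#' The EAR test presents 60 brief videos of facial expressions: 10 per basic
#' emotion (happiness, surprise, sadness, anger, fear, disgust), and within
#' each emotion 5 authentic (event-elicited) and 5 posed expressions, for a
#' total of 30 authentic and 30 posed stimuli.  `build_manifest()` creates a
#' synthetic manifest with that structure.  Stimulus identifiers are opaque;
#' durations are optional metadata drawn from per-emotion log-normal
#' distributions (fear expressions are short, sadness long) and never enter
#' scoring.
#'
#' @param seed Integer seed; the manifest (item order and durations) is
#'   deterministic given the seed.
#' @param durations Named numeric vector of per-emotion mean durations in
#'   seconds, or `NULL` to omit duration metadata.  The default mirrors the
#'   stimulus set the norms were collected with (overall mean about 3.05 s;
#'   fear about 1.69 s, sadness about 7.91 s).
#' @return A data frame of class `ear_manifest` with columns `stimulus_id`,
#'   `emotion`, `authenticity` and (optionally) `duration_s`.
#' @examples
#' m <- build_manifest(seed = 1)
#' table(m$emotion, m$authenticity)
#' @export
build_manifest <- function(seed = 1L,
                           durations = c(happiness = 2.18, surprise = 2.18,
                                         sadness = 7.91, anger = 2.18,
                                         fear = 1.69, disgust = 2.18)) {
  emotions <- ear_emotions()
  spec <- expand.grid(slot = 1:5,
                      authenticity = c("authentic", "posed"),
                      emotion = emotions,
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    ord <- sample.int(nrow(spec))
    spec <- spec[ord, , drop = FALSE]
    spec$stimulus_id <- sprintf("stim_%02d", seq_len(nrow(spec)))
    if (!is.null(durations)) {
      if (is.null(names(durations)) || !all(emotions %in% names(durations))) {
        stop("`durations` must be a named vector covering all six emotions",
             call. = FALSE)
      }
      mu <- durations[spec$emotion]
      sdlog <- 0.45
      d <- stats::rlnorm(nrow(spec), meanlog = log(mu) - sdlog^2 / 2,
                         sdlog = sdlog)
      spec$duration_s <- round(pmin(pmax(d, 0.79), 13.66), 2)
    }
  })
  out <- spec[, c("stimulus_id", "emotion", "authenticity",
                  intersect("duration_s", names(spec)))]
  rownames(out) <- NULL
  class(out) <- c("ear_manifest", "data.frame")
  validate_manifest(out)
  out
}

validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("stimulus_id", "emotion", "authenticity") %in%
                  names(manifest)))
  if (nrow(manifest) != 60L) {
    stop("a full EAR manifest contains exactly 60 stimuli, got ",
         nrow(manifest), call. = FALSE)
  }
  if (anyDuplicated(manifest$stimulus_id)) {
    stop("duplicated stimulus_id in manifest", call. = FALSE)
  }
  tab <- table(factor(manifest$emotion, levels = ear_emotions()),
               factor(manifest$authenticity,
                      levels = c("authentic", "posed")))
  if (!all(tab == 5L)) {
    stop("manifest must contain 5 authentic and 5 posed stimuli per emotion",
         call. = FALSE)
  }
  invisible(manifest)
}

#' Score a complete set of EAR trial responses
#'
#' One point is attributed for each correct emotion identification (ER index)
#' and each correct authenticity classification (EA index); both indices
#' range 0-60.  The protocol is only scored when complete: all 60 stimuli
#' must be answered exactly once, since the norms assume the full 0-60 scale.
#'
#' @param responses Data frame with columns `stimulus_id`, `chosen_emotion`
#'   (one of the six emotion labels) and `authenticity_judgment`
#'   (`"authentic"` or `"posed"`), one row per stimulus.
#' @param manifest An `ear_manifest`, as from [build_manifest()].
#' @return An object of class `raw_scores`: a list with `er_index`,
#'   `ea_index` and `per_emotion_er` (named integer vector of per-emotion
#'   correct identifications, each 0-10, summing to `er_index`).
#' @examples
#' m <- build_manifest(seed = 1)
#' perfect <- data.frame(stimulus_id = m$stimulus_id,
#'                       chosen_emotion = m$emotion,
#'                       authenticity_judgment = m$authenticity)
#' score_responses(perfect, m)
#' @export
score_responses <- function(responses, manifest) {
  validate_manifest(manifest)
  need <- c("stimulus_id", "chosen_emotion", "authenticity_judgment")
  if (!is.data.frame(responses) || !all(need %in% names(responses))) {
    stop("`responses` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  dup <- unique(responses$stimulus_id[duplicated(responses$stimulus_id)])
  if (length(dup)) {
    stop("duplicated responses for stimulus_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  missing_ids <- setdiff(manifest$stimulus_id, responses$stimulus_id)
  if (length(missing_ids)) {
    stop("missing responses for stimulus_id: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(responses$stimulus_id, manifest$stimulus_id)
  if (length(unknown)) {
    stop("responses for unknown stimulus_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_emo <- setdiff(unique(responses$chosen_emotion), ear_emotions())
  if (length(bad_emo)) {
    stop("chosen_emotion outside the 6-alternative set: ",
         paste(bad_emo, collapse = ", "), call. = FALSE)
  }
  bad_auth <- setdiff(unique(responses$authenticity_judgment),
                      c("authentic", "posed"))
  if (length(bad_auth)) {
    stop("authenticity_judgment must be 'authentic' or 'posed', got: ",
         paste(bad_auth, collapse = ", "), call. = FALSE)
  }

  idx <- match(responses$stimulus_id, manifest$stimulus_id)
  emo_true <- manifest$emotion[idx]
  auth_true <- manifest$authenticity[idx]
  er_hit <- responses$chosen_emotion == emo_true
  ea_hit <- responses$authenticity_judgment == auth_true
  per_emotion <- vapply(ear_emotions(),
                        function(e) sum(er_hit & emo_true == e),
                        integer(1))
  out <- list(er_index = sum(er_hit),
              ea_index = sum(ea_hit),
              per_emotion_er = per_emotion)
  class(out) <- "raw_scores"
  out
}

#' @export
print.raw_scores <- function(x, ...) {
  cat("EAR raw scores\n")
  cat(sprintf("  ER index: %d / 60\n", x$er_index))
  cat(sprintf("  EA index: %d / 60\n", x$ea_index))
  cat("  per-emotion ER:",
      paste(sprintf("%s %d", names(x$per_emotion_er), x$per_emotion_er),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-emotion correct-identification counts for many participants
#'
#' Aggregated, vectorised companion to [score_responses()] for item-level
#' tables covering a whole cohort.
#'
#' @param responses Long data frame with a `participant_id` column plus the
#'   three response columns of [score_responses()].
#' @param manifest An `ear_manifest`.
#' @return Data frame with one row per participant: `participant_id`,
#'   `er_index`, `ea_index`, and one column per emotion.
#' @export
emotion_subscores <- function(responses, manifest) {
  validate_manifest(manifest)
  idx <- match(responses$stimulus_id, manifest$stimulus_id)
  if (anyNA(idx)) stop("responses contain unknown stimulus_id", call. = FALSE)
  emo_true <- manifest$emotion[idx]
  er_hit <- responses$chosen_emotion == emo_true
  ea_hit <- responses$authenticity_judgment == manifest$authenticity[idx]
  pid <- factor(responses$participant_id,
                levels = unique(responses$participant_id))
  out <- data.frame(participant_id = levels(pid),
                    er_index = as.integer(tapply(er_hit, pid, sum)),
                    ea_index = as.integer(tapply(ea_hit, pid, sum)),
                    stringsAsFactors = FALSE)
  for (e in ear_emotions()) {
    out[[e]] <- as.integer(tapply(er_hit & emo_true == e, pid, sum))
  }
  rownames(out) <- NULL
  out
}

#' Read and write manifests and response tables
#'
#' Manifests are exchanged as JSON arrays of stimulus records; responses as
#' CSV with columns `stimulus_id`, `chosen_emotion`, `authenticity_judgment`.
#'
#' @param manifest An `ear_manifest`.
#' @param path File path.
#' @return `read_manifest()` returns an `ear_manifest`; `read_responses()` a
#'   response data frame.
#' @name manifest-io
NULL

#' @rdname manifest-io
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  jsonlite::write_json(as.data.frame(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname manifest-io
#' @export
read_manifest <- function(path) {
  out <- jsonlite::fromJSON(path)
  class(out) <- c("ear_manifest", "data.frame")
  validate_manifest(out)
  out
}

#' @rdname manifest-io
#' @export
read_responses <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
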