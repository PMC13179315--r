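#' Construct a speech/silence interval tier for one speaker
#'
#' An interval tier is the basic annotation unit of the package: a single
#' speaker's timeline partitioned into labelled intervals of kind `"speech"`
#' or `"silence"`. Times are in seconds; intervals are half-open `[start,
#' end)`, so two intervals are adjacent exactly when `prev$end == next$start`.
#'
#' @param speaker_id Character scalar identifying the speaker.
#' @param intervals Data frame with columns `start`, `end` (seconds) and
#'   `kind` (`"speech"` or `"silence"`). Rows need not cover the full
#'   timeline; uncovered time counts as silence.
#' @param total_duration Total duration of the recording in seconds. Defaults
#'   to the largest interval end.
#'
#' @return An object of class `interval_tier`: a list with elements
#'   `speaker_id`, `intervals` (a tibble sorted by start) and
#'   `total_duration`.
#' @export
#' @examples
#' interval_tier("S1", data.frame(
#'   start = c(0, 1, 1.5), end = c(1, 1.5, 2),
#'   kind = c("speech", "silence", "speech")), total_duration = 2)
interval_tier <- function(speaker_id, intervals, total_duration = NULL) {
  stopifnot(is.character(speaker_id), length(speaker_id) == 1L)
  intervals <- tibble::as_tibble(intervals)
  stopifnot(all(c("start", "end", "kind") %in% names(intervals)))
  intervals <- intervals[order(intervals$start), c("start", "end", "kind")]
  if (is.null(total_duration)) {
    total_duration <- if (nrow(intervals)) max(intervals$end) else 0
  }
  tier <- structure(
    list(speaker_id = speaker_id,
         intervals = intervals,
         total_duration = as.numeric(total_duration)),
    class = "interval_tier")
  validate_tier(tier)
  tier
}

#' Validate an interval tier
#'
#' Checks the structural invariants: sorted, non-overlapping intervals with
#' `end > start`, all inside `[0, total_duration]`, and kinds restricted to
#' speech/silence.
#'
#' @param tier An `interval_tier`.
#' @return The tier, invisibly; errors on violation.
#' @export
validate_tier <- function(tier) {
  stopifnot(inherits(tier, "interval_tier"))
  iv <- tier$intervals
  if (!nrow(iv)) return(invisible(tier))
  if (!all(iv$kind %in% c("speech", "silence")))
    stop("interval kinds must be 'speech' or 'silence'", call. = FALSE)
  if (any(iv$end <= iv$start))
    stop("every interval must satisfy end > start", call. = FALSE)
  if (is.unsorted(iv$start))
    stop("intervals must be sorted by start", call. = FALSE)
  if (any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-9))
    stop("intervals overlap within tier '", tier$speaker_id, "'", call. = FALSE)
  if (min(iv$start) < -1e-9 || max(iv$end) > tier$total_duration + 1e-9)
    stop("intervals fall outside [0, total_duration]", call. = FALSE)
  invisible(tier)
}

#' @export
print.interval_tier <- function(x, ...) {
  n_sp <- sum(x$intervals$kind == "speech")
  cat(sprintf("<interval_tier> speaker '%s': %d intervals (%d speech), %.2f s\n",
              x$speaker_id, nrow(x$intervals), n_sp, x$total_duration))
  invisible(x)
}

#' Construct a two-speaker dyad annotation
#'
#' Bundles the two interval tiers of one dyad in one conversational context
#' together with its metadata. The two tiers must belong to different
#' speakers and share the same total duration.
#'
#' @param dyad_id Character scalar.
#' @param group Group label, one of `"ASD"` or `"non-ASD"`.
#' @param context Conversational context, one of `"Introduction"`,
#'   `"Tangram"`, `"Discussion"`.
#' @param tier_a,tier_b `interval_tier` objects for the two speakers.
#' @return An object of class `dyad_annotation`.
#' @export
dyad_annotation <- function(dyad_id, group, context, tier_a, tier_b) {
  group <- match.arg(group, c("ASD", "non-ASD"))
  context <- match.arg(context, c("Introduction", "Tangram", "Discussion"))
  stopifnot(inherits(tier_a, "interval_tier"), inherits(tier_b, "interval_tier"))
  if (identical(tier_a$speaker_id, tier_b$speaker_id))
    stop("the two tiers must have distinct speaker ids", call. = FALSE)
  if (abs(tier_a$total_duration - tier_b$total_duration) > 1e-6)
    stop("both tiers must share total_duration", call. = FALSE)
  structure(
    list(dyad_id = as.character(dyad_id), group = group, context = context,
         tier_a = tier_a, tier_b = tier_b),
    class = "dyad_annotation")
}

#' @export
print.dyad_annotation <- function(x, ...) {
  cat(sprintf("<dyad_annotation> dyad '%s' (%s, %s), speakers '%s'/'%s', %.1f s\n",
              x$dyad_id, x$group, x$context,
              x$tier_a$speaker_id, x$tier_b$speaker_id,
              x$tier_a$total_duration))
  invisible(x)
}

#' Enforce the minimum-silence rule on a tier
#'
#' Absorbs every internal silence shorter than `min_silence_s` into the
#' surrounding speech, merging the adjacent speech intervals. This enforces
#' the convention that a talkspurt boundary requires a silence of at least
#' 200 ms; shorter silent stretches are treated as part of continuous speech.
#' Leading and trailing silence is never absorbed, and silences of exactly
#' `min_silence_s` are kept. The operation is idempotent.
#'
#' @param tier An `interval_tier`.
#' @param min_silence_s Minimum silence duration in seconds (default 0.200).
#' @return A normalised `interval_tier`.
#' @export
normalise_tier <- function(tier, min_silence_s = 0.200) {
  validate_tier(tier)
  iv <- tier$intervals
  if (!nrow(iv)) return(tier)
  # canonicalise: fill gaps with silence, merge same-kind neighbours
  iv <- fill_and_merge(iv, tier$total_duration)
  sp <- which(iv$kind == "speech")
  if (length(sp) >= 2) {
    repeat {
      iv_sil <- which(iv$kind == "silence")
      first_sp <- min(which(iv$kind == "speech"))
      last_sp <- max(which(iv$kind == "speech"))
      internal <- iv_sil[iv_sil > first_sp & iv_sil < last_sp]
      short <- internal[(iv$end[internal] - iv$start[internal]) < min_silence_s - 1e-9]
      if (!length(short)) break
      iv$kind[short] <- "speech"
      iv <- fill_and_merge(iv, tier$total_duration)
    }
  }
  out <- tier
  out$intervals <- iv
  out
}

# fill uncovered time with silence and merge adjacent same-kind intervals
fill_and_merge <- function(iv, total_duration) {
  iv <- iv[order(iv$start), ]
  rows <- list()
  cursor <- 0
  for (i in seq_len(nrow(iv))) {
    if (iv$start[i] > cursor + 1e-9)
      rows[[length(rows) + 1L]] <- list(start = cursor, end = iv$start[i], kind = "silence")
    rows[[length(rows) + 1L]] <- as.list(iv[i, ])
    cursor <- max(cursor, iv$end[i])
  }
  if (cursor < total_duration - 1e-9)
    rows[[length(rows) + 1L]] <- list(start = cursor, end = total_duration, kind = "silence")
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  # merge runs of identical kind
  run <- cumsum(c(TRUE, out$kind[-1] != out$kind[-nrow(out)]))
  out <- dplyr::summarise(dplyr::group_by(out, run = run),
                          start = min(.data$start), end = max(.data$end),
                          kind = .data$kind[1], .groups = "drop")
  out[order(out$start), c("start", "end", "kind")]
}

#' Normalise both tiers of a dyad annotation
#'
#' @param annotation A `dyad_annotation`.
#' @inheritParams normalise_tier
#' @return The annotation with both tiers normalised.
#' @export
normalise_annotation <- function(annotation, min_silence_s = 0.200) {
  stopifnot(inherits(annotation, "dyad_annotation"))
  annotation$tier_a <- normalise_tier(annotation$tier_a, min_silence_s)
  annotation$tier_b <- normalise_tier(annotation$tier_b, min_silence_s)
  annotation
}

# total duration of speech in a tier
speech_duration <- function(tier) {
  iv <- tier$intervals
  sum(iv$end[iv$kind == "speech"] - iv$start[iv$kind == "speech"])
}
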