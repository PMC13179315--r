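#' Extract talkspurts from a normalised tier
#'
#' A talkspurt is a maximal stretch of one speaker's speech, bounded by
#' silences of at least the minimum silence length. The tier should have
#' been passed through [normalise_tier()] first so that sub-threshold
#' silences have been absorbed.
#'
#' @param tier An `interval_tier`.
#' @return A tibble with columns `speaker_id`, `start`, `end` (seconds),
#'   one row per talkspurt in temporal order.
#' @export
extract_talkspurts <- function(tier) {
  validate_tier(tier)
  iv <- fill_and_merge(tier$intervals, tier$total_duration)
  sp <- iv[iv$kind == "speech", ]
  tibble::tibble(speaker_id = rep(tier$speaker_id, nrow(sp)),
                 start = sp$start, end = sp$end)
}

#' Extract floor transfers and FTO values from a dyad annotation
#'
#' Processes the talkspurts of both speakers in onset order while tracking
#' the current floor holder. A talkspurt by the non-floor-holder that is
#' strictly contained in a single talkspurt of the floor holder is a
#' within-speaker overlap (typically a backchannel): the floor does not
#' change hands and no FTO is defined. Any other talkspurt by the
#' non-floor-holder transfers the floor; its Floor Transfer Offset is
#'
#' \deqn{FTO = onset(new) - end(last talkspurt of previous floor holder)}
#'
#' so silent gaps have FTO >= 0 and between-speaker overlaps FTO < 0.
#' Consecutive talkspurts by the same speaker are within-speaker pauses and
#' produce no transition.
#'
#' When both speakers' first talkspurts start simultaneously, the initial
#' floor is given to the speaker whose talkspurt ends later (ties broken by
#' lexicographically smaller speaker id).
#'
#' @param annotation A [dyad_annotation()] with normalised tiers.
#' @return A transition table: a tibble with columns `dyad_id`, `group`,
#'   `context`, `type` (`"gap"`, `"between_overlap"`, `"within_overlap"`),
#'   `fto_ms` (signed milliseconds, `NA` for within-overlaps),
#'   `prev_speaker`, `next_speaker`, `anchor_time_s` (end of the floor
#'   holder's last talkspurt), sorted by anchor time, with a `provenance`
#'   attribute recording counts and parameters.
#' @export
extract_transitions <- function(annotation) {
  stopifnot(inherits(annotation, "dyad_annotation"))
  ts <- dplyr::bind_rows(extract_talkspurts(annotation$tier_a),
                         extract_talkspurts(annotation$tier_b))
  empty <- tibble::tibble(dyad_id = character(), group = character(),
                          context = character(), type = character(),
                          fto_ms = numeric(), prev_speaker = character(),
                          next_speaker = character(), anchor_time_s = numeric())
  if (!nrow(ts)) return(as_transition_table(empty, annotation, n_talkspurts = 0L))
  ts <- ts[order(ts$start, -ts$end, ts$speaker_id), ]

  # initial floor holder
  first_start <- ts$start[1]
  starters <- ts[abs(ts$start - first_start) < 1e-12, ]
  floor_holder <- starters$speaker_id[1]  # latest end, then smaller id

  rows <- list()
  # ends of the floor holder's talkspurts seen so far, per speaker
  seen <- split(ts, ts$speaker_id)
  for (i in seq_len(nrow(ts))) {
    spk <- ts$speaker_id[i]
    if (identical(spk, floor_holder)) next
    t_start <- ts$start[i]; t_end <- ts$end[i]
    f_ts <- seen[[floor_holder]]
    if (is.null(f_ts) || !nrow(f_ts)) { floor_holder <- spk; next }
    contained <- any(f_ts$start < t_start - 1e-12 & f_ts$end > t_end + 1e-12)
    if (contained) {
      prior <- f_ts$end[f_ts$start < t_start - 1e-12]
      rows[[length(rows) + 1L]] <- list(
        type = "within_overlap", fto_ms = NA_real_,
        prev_speaker = floor_holder, next_speaker = spk,
        anchor_time_s = max(prior))
    } else {
      prior_ends <- f_ts$end[f_ts$start <= t_start + 1e-12]
      if (!length(prior_ends)) { floor_holder <- spk; next }
      anchor <- max(prior_ends)
      fto_s <- t_start - anchor
      rows[[length(rows) + 1L]] <- list(
        type = if (fto_s >= -1e-12) "gap" else "between_overlap",
        fto_ms = round(fto_s * 1000, 3),
        prev_speaker = floor_holder, next_speaker = spk,
        anchor_time_s = anchor)
      floor_holder <- spk
    }
  }
  if (!length(rows)) return(as_transition_table(empty, annotation,
                                                n_talkspurts = nrow(ts)))
  tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  tab$fto_ms[tab$type == "gap" & tab$fto_ms < 0] <- 0  # clamp -0 ties
  tab <- tibble::tibble(dyad_id = annotation$dyad_id, group = annotation$group,
                        context = annotation$context, tab)
  tab <- tab[order(tab$anchor_time_s), ]
  as_transition_table(tab, annotation, n_talkspurts = nrow(ts))
}

as_transition_table <- function(tab, annotation, n_talkspurts) {
  attr(tab, "provenance") <- list(
    dyad_id = annotation$dyad_id,
    n_talkspurts = n_talkspurts,
    n_transitions = nrow(tab),
    n_dropped_unlabelled_end = sum(!is.finite(tab$anchor_time_s)),
    pipeline = paste0("turnfto ", as.character(utils::packageVersion("turnfto"))))
  tab
}

#' Combine per-dyad transition tables into a corpus table
#'
#' @param tables A list of transition tables from [extract_transitions()].
#' @return A single tibble sorted by (dyad_id, context, anchor_time_s),
#'   provenance attributes merged.
#' @export
bind_transitions <- function(tables) {
  tab <- dplyr::bind_rows(tables)
  tab <- tab[order(tab$dyad_id, tab$context, tab$anchor_time_s), ]
  attr(tab, "provenance") <- list(
    n_transitions = nrow(tab),
    sources = lapply(tables, attr, "provenance"))
  tab
}

#' Drop within-speaker overlaps before FTO analysis
#'
#' Within-speaker overlaps entail no floor transfer and carry no FTO, so
#' they are excluded from turn-timing analysis. The number excluded is
#' recorded in the `provenance` attribute.
#'
#' @param table A transition table.
#' @return The table restricted to gap and between-overlap rows.
#' @export
filter_for_fto <- function(table) {
  keep <- table$type %in% c("gap", "between_overlap")
  out <- table[keep, ]
  prov <- attr(table, "provenance")
  prov$n_excluded_within <- sum(!keep)
  prov$n_retained <- sum(keep)
  attr(out, "provenance") <- prov
  out
}

#' Write / read a transition table as CSV with a provenance sidecar
#'
#' @param table A transition table.
#' @param path CSV output path; provenance is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  prov <- attr(table, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(tab, "provenance") <- jsonlite::read_json(side, simplifyVector = TRUE)
  tab
}
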