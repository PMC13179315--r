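#' Summary statistics of FTO by dyad, group and/or context
#'
#' Computes per-grouping transition counts and the mean, sample SD and
#' median of FTO in milliseconds — the shape of the paper-style
#' group-by-context summary table. The input must already have
#' within-speaker overlaps removed ([filter_for_fto()]).
#'
#' @param table A transition table of gap/between-overlap rows.
#' @param by Character vector of grouping columns (subset of
#'   `c("group", "context", "dyad_id")`); empty summarises the whole table.
#' @return A tibble with the grouping columns plus `n_transitions`,
#'   `mean_fto_ms`, `sd_fto_ms` (NA when n < 2) and `median_fto_ms`.
#' @export
summarise_fto <- function(table, by = c("group", "context")) {
  if (any(is.na(table$fto_ms)))
    stop("table contains within-overlap rows; apply filter_for_fto() first",
         call. = FALSE)
  grp <- dplyr::group_by(table, dplyr::across(dplyr::all_of(by)))
  dplyr::ungroup(dplyr::summarise(
    grp,
    n_transitions = dplyr::n(),
    mean_fto_ms = mean(.data$fto_ms),
    sd_fto_ms = if (dplyr::n() >= 2) stats::sd(.data$fto_ms) else NA_real_,
    median_fto_ms = stats::median(.data$fto_ms),
    .groups = "drop"))
}

#' Proportions of the three transition types
#'
#' Shares of within-speaker overlaps, between-speaker overlaps and silent
#' gaps per grouping, computed on the *unfiltered* transition table (within
#' overlaps included).
#'
#' @param table A transition table including within-overlap rows.
#' @param by Character vector of grouping columns.
#' @return A tibble with grouping columns, `type`, `n`, `proportion`;
#'   proportions sum to 1 within each grouping.
#' @export
type_proportions <- function(table, by = "group") {
  tab <- table
  tab$type <- factor(tab$type, levels = c("within_overlap", "between_overlap", "gap"))
  grp <- dplyr::group_by(tab, dplyr::across(dplyr::all_of(by)), .data$type,
                         .drop = FALSE)
  counts <- dplyr::summarise(grp, n = dplyr::n(), .groups = "drop_last")
  dplyr::ungroup(dplyr::mutate(counts, proportion = .data$n / sum(.data$n)))
}

#' Speaker balance of a dyad
#'
#' The absolute difference between the two speakers' percentage shares of
#' the dyad's combined speaking time, in percentage points. 0 means
#' perfectly balanced contributions; 100 means one speaker spoke
#' exclusively. The combined talkspurt duration of both speakers is used as
#' the denominator so that scores are comparable across contexts that
#' differ in how much silence they contain.
#'
#' @param annotation A [dyad_annotation()] with normalised tiers.
#' @return Balance score in percentage points, or `NA` (with a warning) if
#'   neither speaker spoke.
#' @export
speaker_balance <- function(annotation) {
  stopifnot(inherits(annotation, "dyad_annotation"))
  d1 <- speech_duration(annotation$tier_a)
  d2 <- speech_duration(annotation$tier_b)
  if (d1 + d2 <= 0) {
    warning("both tiers silent: speaker balance undefined for dyad '",
            annotation$dyad_id, "'")
    return(NA_real_)
  }
  abs(d1 - d2) / (d1 + d2) * 100
}

#' Tidy FTO export for density plots
#'
#' Emits the FTO values with their grouping keys plus the conventional
#' reference lines at 0 ms (no gap, no overlap), 200 ms (typical
#' transition) and 700 ms (unusually long), ready for plotting.
#'
#' @param table A transition table of gap/between-overlap rows.
#' @return A list with `data` (tibble of `dyad_id, group, context, fto_ms`)
#'   and `reference_lines_ms` (`c(0, 200, 700)`).
#' @export
export_density_data <- function(table) {
  if (any(is.na(table$fto_ms)))
    stop("table contains within-overlap rows; apply filter_for_fto() first",
         call. = FALSE)
  list(data = tibble::as_tibble(
         table[, c("dyad_id", "group", "context", "fto_ms")]),
       reference_lines_ms = c(0, 200, 700))
}

#' Per-dyad FTO summary ordered by mean FTO
#'
#' Convenience wrapper producing the per-dyad panel ordering used in
#' ridgeline/density displays: one row per dyad, sorted by mean FTO.
#'
#' @param table A transition table of gap/between-overlap rows.
#' @return A tibble sorted by descending `mean_fto_ms`.
#' @export
dyad_summary <- function(table) {
  out <- summarise_fto(table, by = c("dyad_id", "group"))
  out[order(-out$mean_fto_ms), ]
}
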