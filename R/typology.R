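#' Classify an FTO value into a perceptual transition category
#'
#' Partitions the signed FTO line into five categories motivated by
#' perception research on conversational silence: transitions shorter than
#' 100 ms in absolute value are perceived as seamless ("smooth"), while
#' gaps or overlaps of 700 ms or more are perceived as unusually long.
#'
#' \itemize{
#'   \item `long_overlap`: FTO <= -700 ms
#'   \item `overlap`: -700 < FTO <= -100 ms
#'   \item `smooth`: |FTO| < 100 ms
#'   \item `gap`: 100 <= FTO < 700 ms
#'   \item `long_gap`: FTO >= 700 ms
#' }
#'
#' @param fto_ms Numeric vector of signed FTO values in milliseconds.
#' @param smooth_ms,long_ms Category thresholds in ms (defaults 100 and 700);
#'   must satisfy `0 < smooth_ms < long_ms`.
#' @return A factor with levels `long_overlap, overlap, smooth, gap,
#'   long_gap` (ordered from most negative to most positive FTO).
#' @export
#' @examples
#' categorise_fto(c(-800, -300, 0, 99, 100, 699, 700))
categorise_fto <- function(fto_ms, smooth_ms = 100, long_ms = 700) {
  stopifnot(smooth_ms > 0, long_ms > smooth_ms)
  if (any(!is.finite(fto_ms)))
    stop("FTO values must be finite for categorisation", call. = FALSE)
  lev <- c("long_overlap", "overlap", "smooth", "gap", "long_gap")
  out <- character(length(fto_ms))
  out[fto_ms <= -long_ms] <- "long_overlap"
  out[fto_ms > -long_ms & fto_ms <= -smooth_ms] <- "overlap"
  out[abs(fto_ms) < smooth_ms] <- "smooth"
  out[fto_ms >= smooth_ms & fto_ms < long_ms] <- "gap"
  out[fto_ms >= long_ms] <- "long_gap"
  factor(out, levels = lev)
}

#' Proportions of perceptual transition categories
#'
#' Tabulates the five FTO categories of [categorise_fto()] within groups,
#' e.g. per diagnostic group, per context, or per dyad. Within-speaker
#' overlap rows (no FTO) must have been removed first with
#' [filter_for_fto()].
#'
#' @param table A transition table restricted to gap/between-overlap rows.
#' @param by Character vector of grouping columns (subset of
#'   `c("group", "context", "dyad_id")`); empty for corpus-wide proportions.
#' @inheritParams categorise_fto
#' @return A tibble with the grouping columns, `category`, `n` and
#'   `proportion`; proportions sum to 1 within each grouping. Groupings with
#'   no rows are absent.
#' @export
category_proportions <- function(table, by = "group",
                                 smooth_ms = 100, long_ms = 700) {
  if (any(is.na(table$fto_ms)))
    stop("table contains within-overlap rows; apply filter_for_fto() first",
         call. = FALSE)
  tab <- table
  tab$category <- categorise_fto(tab$fto_ms, smooth_ms, long_ms)
  grp <- dplyr::group_by(tab, dplyr::across(dplyr::all_of(by)), .data$category,
                         .drop = FALSE)
  counts <- dplyr::summarise(grp, n = dplyr::n(), .groups = "drop_last")
  out <- dplyr::mutate(counts, proportion = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  # drop groupings that have no transitions at all
  if (length(by)) {
    tot <- dplyr::summarise(dplyr::group_by(out, dplyr::across(dplyr::all_of(by))),
                            tot = sum(.data$n), .groups = "drop")
    keep <- tot[tot$tot > 0, by, drop = FALSE]
    out <- dplyr::semi_join(out, keep, by = by)
  }
  out
}

#' Wide-format category proportions for reporting
#'
#' One row per grouping, one column per category, shaped like a stacked-bar
#' summary table.
#'
#' @inheritParams category_proportions
#' @return A tibble with grouping columns and the five category proportion
#'   columns.
#' @export
category_proportions_wide <- function(table, by = "group",
                                      smooth_ms = 100, long_ms = 700) {
  long <- category_proportions(table, by, smooth_ms, long_ms)
  tidyr::pivot_wider(long[, c(by, "category", "proportion")],
                     names_from = "category", values_from = "proportion",
                     values_fill = 0)
}
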