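#' Read a two-speaker Praat TextGrid into a dyad annotation
#'
#' Parses a Praat TextGrid file (long or short text dialect, UTF-8 or UTF-16
#' with BOM) and extracts the two named interval tiers. Interval labels in
#' `silence_labels` (and blank labels) map to kind `"silence"`; every other
#' label maps to `"speech"`.
#'
#' @param path Path to the TextGrid file.
#' @param tier_names Character vector of length 2: the names of the two
#'   speaker tiers, in (speaker A, speaker B) order.
#' @param dyad_id Dyad identifier; defaults to the file name without
#'   extension.
#' @param group,context Dyad metadata (see [dyad_annotation()]).
#' @param silence_labels Labels counted as silence in addition to blank
#'   (default `c("", "sil", "<p>")`). Matching is exact after trimming
#'   whitespace.
#' @return A [dyad_annotation()].
#' @export
read_textgrid <- function(path, tier_names,
                          dyad_id = NULL,
                          group = "ASD", context = "Introduction",
                          silence_labels = c("", "sil", "<p>")) {
  stopifnot(length(tier_names) == 2L)
  if (is.null(dyad_id)) dyad_id <- sub("\\.[^.]*$", "", basename(path))
  tg <- parse_textgrid(path)
  tiers <- lapply(tier_names, function(nm) {
    hit <- which(vapply(tg$tiers, function(t) identical(t$name, nm), logical(1)))
    if (!length(hit))
      stop("tier '", nm, "' not found in ", path, " (tiers present: ",
           paste(vapply(tg$tiers, `[[`, "", "name"), collapse = ", "), ")",
           call. = FALSE)
    t <- tg$tiers[[hit[1]]]
    if (!identical(t$class, "IntervalTier"))
      stop("tier '", nm, "' is a point tier; interval tier required",
           call. = FALSE)
    lab <- trimws(t$labels)
    interval_tier(nm,
                  tibble::tibble(start = t$xmin, end = t$xmax,
                                 kind = ifelse(lab %in% c(silence_labels, ""),
                                               "silence", "speech")),
                  total_duration = tg$xmax)
  })
  dyad_annotation(dyad_id, group, context, tiers[[1]], tiers[[2]])
}

#' Write a dyad annotation as a Praat TextGrid
#'
#' Emits one interval tier per speaker, with speech intervals labelled
#' `"speech"` and silences blank. The annotation is validated before
#' writing; reading the file back reproduces the annotation to better than
#' 1 ms.
#'
#' @param annotation A [dyad_annotation()].
#' @param path Output file path.
#' @param format `"long"` (default) or `"short"` TextGrid text dialect.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(annotation, path, format = c("long", "short")) {
  format <- match.arg(format)
  stopifnot(inherits(annotation, "dyad_annotation"))
  validate_tier(annotation$tier_a)
  validate_tier(annotation$tier_b)
  xmax <- annotation$tier_a$total_duration
  tiers <- list(annotation$tier_a, annotation$tier_b)
  num <- function(x) formatC(x, format = "f", digits = 6, drop0trailing = TRUE)
  lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "")
  if (format == "long") {
    lines <- c(lines,
               paste0("xmin = ", num(0)), paste0("xmax = ", num(xmax)),
               "tiers? <exists>", paste0("size = ", length(tiers)), "item []:")
    for (k in seq_along(tiers)) {
      tier <- tiers[[k]]
      iv <- fill_and_merge(tier$intervals, tier$total_duration)
      lines <- c(lines,
                 sprintf("    item [%d]:", k),
                 '        class = "IntervalTier"',
                 sprintf('        name = "%s"', tier$speaker_id),
                 paste0("        xmin = ", num(0)),
                 paste0("        xmax = ", num(xmax)),
                 sprintf("        intervals: size = %d", nrow(iv)))
      for (i in seq_len(nrow(iv))) {
        lines <- c(lines,
                   sprintf("        intervals [%d]:", i),
                   paste0("            xmin = ", num(iv$start[i])),
                   paste0("            xmax = ", num(iv$end[i])),
                   sprintf('            text = "%s"',
                           if (iv$kind[i] == "speech") "speech" else ""))
      }
    }
  } else {
    lines <- c(lines, num(0), num(xmax), "<exists>", as.character(length(tiers)))
    for (tier in tiers) {
      iv <- fill_and_merge(tier$intervals, tier$total_duration)
      lines <- c(lines, '"IntervalTier"',
                 sprintf('"%s"', tier$speaker_id),
                 num(0), num(xmax), as.character(nrow(iv)))
      for (i in seq_len(nrow(iv))) {
        lines <- c(lines, num(iv$start[i]), num(iv$end[i]),
                   sprintf('"%s"', if (iv$kind[i] == "speech") "speech" else ""))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# -- TextGrid parsing ---------------------------------------------------------

# read the raw lines with BOM-based encoding detection
read_textgrid_lines <- function(path) {
  bom <- readBin(path, "raw", n = 3L)
  enc <- if (length(bom) >= 2 && bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF)) {
    "UTF-16BE"
  } else if (length(bom) >= 2 && bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE)) {
    "UTF-16LE"
  } else "UTF-8"
  con <- file(path, encoding = enc)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) && substr(lines[1], 1, 1) == "﻿")
    lines[1] <- sub("^﻿", "", lines[1])
  lines
}

parse_textgrid <- function(path) {
  lines <- read_textgrid_lines(path)
  if (!length(lines) || !grepl("ooTextFile", lines[1]))
    stop("not a Praat TextGrid file: ", path, call. = FALSE)
  if (length(lines) < 2 || !grepl("TextGrid", lines[2]))
    stop("not a Praat TextGrid file (wrong object class): ", path, call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[trimws(body) != ""]
  if (any(grepl("^\\s*item\\s*\\[", body))) parse_textgrid_long(body)
  else parse_textgrid_short(body)
}

tg_num <- function(line) as.numeric(sub("^[^=]*=\\s*", "", line))
tg_str <- function(line) {
  m <- regmatches(line, regexpr('"(?:[^"]|"")*"', line))
  if (!length(m)) return("")
  gsub('""', '"', substr(m, 2, nchar(m) - 1))
}

parse_textgrid_long <- function(body) {
  xmin <- tg_num(body[grep("^\\s*xmin\\s*=", body)[1]])
  xmax <- tg_num(body[grep("^\\s*xmax\\s*=", body)[1]])
  item_at <- grep("^\\s*item\\s*\\[[0-9]+\\]\\s*:", body)
  tiers <- vector("list", length(item_at))
  bounds <- c(item_at, length(body) + 1L)
  for (k in seq_along(item_at)) {
    blk <- body[item_at[k]:(bounds[k + 1L] - 1L)]
    cls <- tg_str(blk[grep("^\\s*class\\s*=", blk)[1]])
    nm <- tg_str(blk[grep("^\\s*name\\s*=", blk)[1]])
    if (!identical(cls, "IntervalTier")) {
      tiers[[k]] <- list(class = cls, name = nm)
      next
    }
    iv_at <- grep("^\\s*intervals\\s*\\[[0-9]+\\]\\s*:", blk)
    xmins <- xmaxs <- numeric(length(iv_at))
    labels <- character(length(iv_at))
    ivb <- c(iv_at, length(blk) + 1L)
    for (i in seq_along(iv_at)) {
      sub <- blk[iv_at[i]:(ivb[i + 1L] - 1L)]
      xmins[i] <- tg_num(sub[grep("^\\s*xmin\\s*=", sub)[1]])
      xmaxs[i] <- tg_num(sub[grep("^\\s*xmax\\s*=", sub)[1]])
      labels[i] <- tg_str(sub[grep("^\\s*text\\s*=", sub)[1]])
    }
    tiers[[k]] <- list(class = cls, name = nm, xmin = xmins, xmax = xmaxs,
                       labels = labels)
  }
  list(xmin = xmin, xmax = xmax, tiers = tiers)
}

parse_textgrid_short <- function(body) {
  toks <- trimws(body)
  # body: xmin xmax <exists> ntiers then per tier: class name xmin xmax n ...
  i <- 1L
  take <- function() { v <- toks[i]; i <<- i + 1L; v }
  xmin <- as.numeric(take()); xmax <- as.numeric(take())
  take() # <exists>
  ntier <- as.integer(take())
  tiers <- vector("list", ntier)
  for (k in seq_len(ntier)) {
    cls <- tg_str(take()); nm <- tg_str(take())
    take(); take() # tier xmin/xmax
    n <- as.integer(take())
    if (identical(cls, "IntervalTier")) {
      xmins <- xmaxs <- numeric(n); labels <- character(n)
      for (j in seq_len(n)) {
        xmins[j] <- as.numeric(take())
        xmaxs[j] <- as.numeric(take())
        labels[j] <- tg_str(take())
      }
      tiers[[k]] <- list(class = cls, name = nm, xmin = xmins, xmax = xmaxs,
                         labels = labels)
    } else {
      # point tier: time + label per point
      for (j in seq_len(n)) { take(); take() }
      tiers[[k]] <- list(class = cls, name = nm)
    }
  }
  list(xmin = xmin, xmax = xmax, tiers = tiers)
}

# -- interval CSV alternative -------------------------------------------------

#' Read dyad annotations from an interval CSV
#'
#' The CSV must have columns `dyad_id, speaker, start_s, end_s, kind` with
#' `kind` in speech/silence, plus optional `group` and `context` columns
#' (otherwise supplied as arguments). One annotation is returned per dyad id.
#'
#' @param path CSV file path.
#' @param group,context Metadata used when the CSV carries no such columns.
#' @param total_duration Recording duration in seconds; defaults to the
#'   largest `end_s` per dyad.
#' @return A list of [dyad_annotation()] objects.
#' @export
read_interval_csv <- function(path, group = "ASD", context = "Introduction",
                              total_duration = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dyad_id", "speaker", "start_s", "end_s", "kind")
  if (!all(need %in% names(df)))
    stop("interval CSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  lapply(split(df, df$dyad_id), function(d) {
    speakers <- unique(d$speaker)
    if (length(speakers) != 2L)
      stop("dyad '", d$dyad_id[1], "' must have exactly 2 speakers", call. = FALSE)
    dur <- if (is.null(total_duration)) max(d$end_s) else total_duration
    tiers <- lapply(speakers, function(s) {
      rows <- d[d$speaker == s, ]
      interval_tier(s, tibble::tibble(start = rows$start_s, end = rows$end_s,
                                      kind = rows$kind),
                    total_duration = dur)
    })
    dyad_annotation(d$dyad_id[1],
                    if ("group" %in% names(d)) d$group[1] else group,
                    if ("context" %in% names(d)) d$context[1] else context,
                    tiers[[1]], tiers[[2]])
  })
}

#' Write dyad annotations to an interval CSV
#'
#' @param annotations A [dyad_annotation()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_interval_csv <- function(annotations, path) {
  if (inherits(annotations, "dyad_annotation")) annotations <- list(annotations)
  rows <- dplyr::bind_rows(lapply(annotations, function(a) {
    dplyr::bind_rows(lapply(list(a$tier_a, a$tier_b), function(t) {
      tibble::tibble(dyad_id = a$dyad_id, group = a$group, context = a$context,
                     speaker = t$speaker_id,
                     start_s = t$intervals$start, end_s = t$intervals$end,
                     kind = t$intervals$kind)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a corpus metadata table
#'
#' The metadata CSV maps each dyad/context recording to its TextGrid file:
#' columns `dyad_id, group, context, path, tier_a, tier_b`.
#'
#' @param path Metadata CSV path.
#' @param base_dir Directory against which relative TextGrid paths are
#'   resolved; defaults to the metadata file's directory.
#' @return A tibble.
#' @export
read_metadata <- function(path, base_dir = dirname(path)) {
  md <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("dyad_id", "group", "context", "path", "tier_a", "tier_b")
  if (!all(need %in% names(md)))
    stop("metadata CSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  abs <- grepl("^(/|[A-Za-z]:)", md$path)
  md$path[!abs] <- file.path(base_dir, md$path[!abs])
  md
}
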