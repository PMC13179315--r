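# Independent brute-force reference for transition extraction, written
# directly from the floor-rule definition and kept free of any code shared
# with the package implementation.
#
# Input: data.frame of talkspurts (speaker, start, end), both speakers.
# Output: data.frame (type, fto_ms, prev_speaker, next_speaker, anchor_time_s).
oracle_transitions <- function(spurts) {
  spurts <- spurts[order(spurts$start, -spurts$end, spurts$speaker), ]
  out <- data.frame(type = character(), fto_ms = numeric(),
                    prev_speaker = character(), next_speaker = character(),
                    anchor_time_s = numeric(), stringsAsFactors = FALSE)
  if (nrow(spurts) == 0) return(out)
  # initial floor: earliest onset; simultaneous -> later end, then smaller id
  first <- spurts[spurts$start == min(spurts$start), ]
  first <- first[order(-first$end, first$speaker), ]
  floor <- first$speaker[1]
  for (i in seq_len(nrow(spurts))) {
    sp <- spurts$speaker[i]
    if (sp == floor) next
    st <- spurts$start[i]; en <- spurts$end[i]
    fl <- spurts[spurts$speaker == floor & spurts$start < st - 1e-12, ]
    # within-overlap: strictly contained in a single floor-holder talkspurt
    if (nrow(fl) && any(fl$start < st - 1e-12 & fl$end > en + 1e-12)) {
      out[nrow(out) + 1L, ] <- list("within_overlap", NA_real_, floor, sp,
                                    max(fl$end))
      next
    }
    fl2 <- spurts[spurts$speaker == floor & spurts$start <= st + 1e-12, ]
    if (!nrow(fl2)) { floor <- sp; next }
    anchor <- max(fl2$end)
    fto <- st - anchor
    type <- if (fto >= -1e-12) "gap" else "between_overlap"
    out[nrow(out) + 1L, ] <- list(type, round(max(fto, if (type == "gap") 0 else fto) * 1000, 3),
                                  floor, sp, anchor)
    floor <- sp
  }
  out
}

# talkspurt data.frame from a dyad annotation, via the tiers directly
spurts_of <- function(ann) {
  rows <- list()
  for (tier in list(ann$tier_a, ann$tier_b)) {
    iv <- tier$intervals
    sp <- iv[iv$kind == "speech", ]
    if (nrow(sp))
      rows[[length(rows) + 1L]] <- data.frame(speaker = tier$speaker_id,
                                              start = sp$start, end = sp$end)
  }
  do.call(rbind, rows)
}

# build a dyad annotation from two talkspurt lists (seconds)
ann_from_spurts <- function(a_spurts, b_spurts, dur = NULL,
                            group = "ASD", context = "Introduction",
                            dyad_id = "toy") {
  dur <- dur %||% (max(c(unlist(a_spurts), unlist(b_spurts), 1)) + 0.5)
  mk <- function(id, sp) {
    iv <- if (length(sp)) {
      do.call(rbind, lapply(sp, function(x)
        data.frame(start = x[1], end = x[2], kind = "speech")))
    } else data.frame(start = numeric(), end = numeric(), kind = character())
    interval_tier(id, iv, total_duration = dur)
  }
  dyad_annotation(dyad_id, group, context, mk("A", a_spurts), mk("B", b_spurts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random two-speaker timeline on a grid: up to max_per speaker talkspurts,
# same-speaker talkspurts separated by at least one grid cell
random_grid_timeline <- function(max_per = 3, grid = 0.1, horizon = 10) {
  pts <- seq(0, horizon, by = grid)
  draw_tier <- function() {
    k <- sample(0:max_per, 1)
    sp <- list()
    lo <- 1
    for (j in seq_len(k)) {
      if (lo >= length(pts) - 1) break
      s <- sample(lo:(length(pts) - 1), 1)
      e <- if (s + 1 >= length(pts)) length(pts)
           else sample((s + 1):length(pts), 1)
      sp[[length(sp) + 1L]] <- c(pts[s], pts[e])
      lo <- e + 2  # at least one empty cell between talkspurts
    }
    sp
  }
  list(a = draw_tier(), b = draw_tier())
}

expect_same_transitions <- function(ann) {
  got <- extract_transitions(ann)
  ref <- oracle_transitions(spurts_of(ann))
  # the table contract orders rows by anchor time (stable for ties)
  ref <- ref[order(ref$anchor_time_s), ]
  expect_equal(nrow(got), nrow(ref))
  if (nrow(ref)) {
    expect_equal(got$type, ref$type)
    expect_equal(got$fto_ms, ref$fto_ms, tolerance = 1e-9)
    expect_equal(got$prev_speaker, ref$prev_speaker)
    expect_equal(got$next_speaker, ref$next_speaker)
    expect_equal(got$anchor_time_s, ref$anchor_time_s, tolerance = 1e-9)
  }
  invisible(NULL)
}

# sign-consistent test configuration: the gap share of the mixture equals
# the ex-Gaussian's own probability of a non-negative draw, so the
# simulator's sign-conditional sampling reproduces the untruncated
# distribution and group contrasts in mu carry through to realised means
sign_consistent_cells <- function(mu_asd, mu_non, sigma = 150, tau = 400,
                                  p_within = 0.15,
                                  contexts = c("Introduction", "Tangram",
                                               "Discussion"),
                                  task_shift = c(0, 0, 0)) {
  rows <- list()
  for (g in c("ASD", "non-ASD")) {
    for (i in seq_along(contexts)) {
      mu <- (if (g == "ASD") mu_asd else mu_non) + task_shift[i]
      ppos <- 1 - pexgauss(0, mu, sigma, tau)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, context = contexts[i], mu = mu, sigma = sigma, tau = tau,
        p_within = p_within, p_between = (1 - p_within) * (1 - ppos),
        p_gap = (1 - p_within) * ppos)
    }
  }
  do.call(rbind, rows)
}
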