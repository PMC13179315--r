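test_that("sub-threshold internal silences are absorbed into speech", {
  tier <- interval_tier("S1", data.frame(
    start = c(0, 1.0, 1.15), end = c(1.0, 1.15, 2.0),
    kind = c("speech", "silence", "speech")), total_duration = 2)
  out <- normalise_tier(tier)
  sp <- out$intervals[out$intervals$kind == "speech", ]
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$start, sp$end), c(0, 2.0))

  # exactly 200 ms is kept
  tier2 <- interval_tier("S1", data.frame(
    start = c(0, 1.0, 1.2), end = c(1.0, 1.2, 2.0),
    kind = c("speech", "silence", "speech")), total_duration = 2)
  out2 <- normalise_tier(tier2)
  expect_equal(sum(out2$intervals$kind == "speech"), 2L)

  # leading and trailing silences survive regardless of length
  tier3 <- interval_tier("S1", data.frame(
    start = c(0, 0.05, 1.0), end = c(0.05, 1.0, 1.05),
    kind = c("silence", "speech", "silence")), total_duration = 1.05)
  out3 <- normalise_tier(tier3)
  expect_equal(out3$intervals$kind, c("silence", "speech", "silence"))
})

test_that("normalisation removes all short silences, is idempotent, and conserves time", {
  set.seed(42)
  for (rep in 1:5) {
    # speech blocks separated by random silences, many below 200 ms
    n <- 50
    gaps <- stats::runif(n, 0.01, 0.5)
    speech <- stats::runif(n + 1, 0.3, 1.5)
    starts <- cumsum(c(0.4, head(speech, -1) + gaps))
    tier <- interval_tier("S1", data.frame(
      start = starts, end = starts + speech, kind = "speech"),
      total_duration = max(starts + speech) + 0.3)
    out <- normalise_tier(tier)
    iv <- out$intervals
    sil <- iv[iv$kind == "silence", ]
    internal <- sil[sil$start > min(iv$start[iv$kind == "speech"]) &
                    sil$end < max(iv$end[iv$kind == "speech"]), ]
    expect_true(all(internal$end - internal$start >= 0.2 - 1e-9))
    # idempotent
    out2 <- normalise_tier(out)
    expect_equal(out2$intervals, out$intervals)
    # conservation: speech gained equals silences absorbed
    absorbed <- sum(pmin(gaps, Inf)[gaps < 0.2 - 1e-9])
    gained <- turnfto:::speech_duration(out) - sum(speech)
    expect_equal(gained, absorbed, tolerance = 1e-6)
  }
})

test_that("TextGrid round-trips are the identity and both dialects parse alike", {
  ann <- ann_from_spurts(list(c(0, 1.2), c(2.0, 3.0)), list(c(1.4, 1.9)),
                         dur = 3.5)
  for (fmt in c("long", "short")) {
    f <- withr::local_tempfile(fileext = ".TextGrid")
    write_textgrid(ann, f, fmt)
    back <- read_textgrid(f, c("A", "B"), dyad_id = "toy")
    expect_equal(back$tier_a$intervals[back$tier_a$intervals$kind == "speech", ],
                 tibble::tibble(start = c(0, 2.0), end = c(1.2, 3.0),
                                kind = c("speech", "speech")),
                 tolerance = 1e-3)
    expect_equal(back$tier_b$total_duration, 3.5, tolerance = 1e-3)
  }

  # simulated 10-min-style dyads round-trip through both dialects
  cfg <- sim_config(n_dyads = c(ASD = 1, "non-ASD" = 1),
                    context_duration_s = 60, seed = 11)
  corp <- simulate_corpus(cfg)
  for (ann in corp$annotations[1:2]) {
    t0 <- extract_transitions(ann)
    for (fmt in c("long", "short")) {
      f <- withr::local_tempfile(fileext = ".TextGrid")
      write_textgrid(ann, f, fmt)
      back <- read_textgrid(f, c("S1", "S2"), dyad_id = ann$dyad_id,
                            group = ann$group, context = ann$context)
      tb <- extract_transitions(back)
      expect_equal(tb$fto_ms, t0$fto_ms, tolerance = 1)  # <= 1 ms
      expect_equal(tb$type, t0$type)
    }
  }
})

test_that("a hand-written long-dialect TextGrid parses equal to the short dialect", {
  # independent templates, not produced by write_textgrid
  long_txt <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', '',
    'xmin = 0', 'xmax = 3', 'tiers? <exists>', 'size = 2', 'item []:',
    '    item [1]:', '        class = "IntervalTier"', '        name = "S1"',
    '        xmin = 0', '        xmax = 3', '        intervals: size = 3',
    '        intervals [1]:', '            xmin = 0', '            xmax = 1',
    '            text = "hello"',
    '        intervals [2]:', '            xmin = 1', '            xmax = 2',
    '            text = ""',
    '        intervals [3]:', '            xmin = 2', '            xmax = 3',
    '            text = "again"',
    '    item [2]:', '        class = "IntervalTier"', '        name = "S2"',
    '        xmin = 0', '        xmax = 3', '        intervals: size = 1',
    '        intervals [1]:', '            xmin = 0', '            xmax = 3',
    '            text = "sil"')
  short_txt <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', '',
    '0', '3', '<exists>', '2',
    '"IntervalTier"', '"S1"', '0', '3', '3',
    '0', '1', '"hello"', '1', '2', '""', '2', '3', '"again"',
    '"IntervalTier"', '"S2"', '0', '3', '1',
    '0', '3', '"sil"')
  f1 <- withr::local_tempfile(fileext = ".TextGrid")
  f2 <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(long_txt, f1); writeLines(short_txt, f2)
  a1 <- read_textgrid(f1, c("S1", "S2"), dyad_id = "x")
  a2 <- read_textgrid(f2, c("S1", "S2"), dyad_id = "x")
  expect_equal(a1$tier_a$intervals, a2$tier_a$intervals)
  expect_equal(a1$tier_b$intervals, a2$tier_b$intervals)
  # "sil" maps to silence, words map to speech
  expect_equal(a1$tier_b$intervals$kind, "silence")
  expect_equal(a1$tier_a$intervals$kind, c("speech", "silence", "speech"))
})

test_that("TextGrid reading reports missing tiers, point tiers and bad files", {
  ann <- ann_from_spurts(list(c(0, 1)), list(c(1.5, 2)), dur = 2.5)
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(ann, f)
  expect_error(read_textgrid(f, c("A", "S2")), "not found")
  point_txt <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', '',
    'xmin = 0', 'xmax = 3', 'tiers? <exists>', 'size = 1', 'item []:',
    '    item [1]:', '        class = "TextTier"', '        name = "pts"',
    '        xmin = 0', '        xmax = 3', '        points: size = 0')
  fp <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(point_txt, fp)
  expect_error(read_textgrid(fp, c("pts", "other")), "point tier|not found")
  fb <- withr::local_tempfile(fileext = ".txt")
  writeLines("this is not a textgrid", fb)
  expect_error(read_textgrid(fb, c("A", "B")), "TextGrid")
})

test_that("overlapping intervals within a tier are rejected", {
  expect_error(interval_tier("S1", data.frame(
    start = c(0, 0.5), end = c(1, 1.5), kind = "speech")), "overlap")
  expect_error(interval_tier("S1", data.frame(
    start = 0, end = 0, kind = "speech")), "end > start")
})

test_that("interval CSV round-trips annotations with metadata", {
  ann <- ann_from_spurts(list(c(0, 1)), list(c(1.5, 2)), dur = 2.5,
                         group = "non-ASD", context = "Tangram",
                         dyad_id = "d1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_interval_csv(ann, f)
  back <- read_interval_csv(f, total_duration = 2.5)
  expect_length(back, 1L)
  expect_equal(back[["d1"]]$group, "non-ASD")
  expect_equal(back[["d1"]]$context, "Tangram")
  expect_equal(
    extract_transitions(back[["d1"]])$fto_ms,
    extract_transitions(ann)$fto_ms)
})
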