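#' Configuration for the synthetic-conversation generator
#'
#' Fully specifies a simulated corpus of dyadic conversations: number of
#' dyads per diagnostic group, the conversational contexts and their
#' duration, per group-by-context ex-Gaussian FTO parameters and
#' transition-type mixtures, turn-duration distribution, dyad-level random
#' variation, and the seed.
#'
#' `cell_params` must contain one row per group x context with columns
#' `group, context, mu, sigma, tau` (ex-Gaussian FTO parameters, ms) and
#' `p_within, p_between, p_gap` (transition-type mixture, summing to 1).
#'
#' @param n_dyads Named integer vector: dyads per group, e.g.
#'   `c(ASD = 9, "non-ASD" = 14)`.
#' @param contexts Contexts to simulate.
#' @param context_duration_s Duration of each context in seconds
#'   (default 600, i.e. 10 minutes).
#' @param cell_params Tibble of per-cell parameters (see Details).
#' @param turn_meanlog,turn_sdlog Log-normal parameters of turn duration in
#'   seconds.
#' @param dyad_sd_mu SD (ms) of the dyad-level shift of the ex-Gaussian
#'   location `mu`, shared across contexts (a dyad random intercept).
#' @param dyad_sd_logit SD of the dyad-level perturbation of the
#'   within-overlap mixture weight on the logit scale.
#' @param within_dur_range Within-overlap (backchannel) duration range in
#'   seconds, uniform (default 0.2-0.8 s).
#' @param min_silence_s Minimum silence / clearance used throughout
#'   (default 0.2 s).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_dyads = c(ASD = 9, "non-ASD" = 14),
                       contexts = c("Introduction", "Tangram", "Discussion"),
                       context_duration_s = 600,
                       cell_params = default_cell_params(contexts),
                       turn_meanlog = log(2.2), turn_sdlog = 0.6,
                       dyad_sd_mu = 120, dyad_sd_logit = 0.3,
                       within_dur_range = c(0.2, 0.8),
                       min_silence_s = 0.2,
                       seed = 1L) {
  stopifnot(all(n_dyads >= 1), context_duration_s > 0,
            length(within_dur_range) == 2, within_dur_range[1] >= min_silence_s,
            diff(within_dur_range) >= 0, turn_sdlog > 0)
  cell_params <- tibble::as_tibble(cell_params)
  need <- c("group", "context", "mu", "sigma", "tau",
            "p_within", "p_between", "p_gap")
  if (!all(need %in% names(cell_params)))
    stop("cell_params needs columns ", paste(need, collapse = ", "), call. = FALSE)
  mix <- cell_params$p_within + cell_params$p_between + cell_params$p_gap
  if (any(abs(mix - 1) > 1e-6))
    stop("type mixtures must sum to 1", call. = FALSE)
  if (any(cell_params$p_within >= 1))
    stop("p_within must be < 1: a conversation needs floor transfers",
         call. = FALSE)
  if (any(cell_params$sigma <= 0) || any(cell_params$tau <= 0))
    stop("sigma and tau must be positive", call. = FALSE)
  for (g in names(n_dyads)) for (cx in contexts) {
    if (!any(cell_params$group == g & cell_params$context == cx))
      stop("cell_params missing row for ", g, " / ", cx, call. = FALSE)
  }
  # a turn must be able to host a within-overlap with clearance on both sides
  if (any(cell_params$p_within > 0)) {
    host <- within_dur_range[1] + 2 * min_silence_s
    if (stats::qlnorm(0.9, turn_meanlog, turn_sdlog) < host)
      stop("turn durations too short to host within-overlaps", call. = FALSE)
  }
  structure(list(n_dyads = n_dyads, contexts = contexts,
                 context_duration_s = context_duration_s,
                 cell_params = cell_params,
                 turn_meanlog = turn_meanlog, turn_sdlog = turn_sdlog,
                 dyad_sd_mu = dyad_sd_mu, dyad_sd_logit = dyad_sd_logit,
                 within_dur_range = within_dur_range,
                 min_silence_s = min_silence_s, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default per-cell simulation parameters
#'
#' The package's reference configuration for realistic corpora of autistic
#' (ASD-ASD) and non-autistic dyads across the Introduction, Tangram and
#' Discussion contexts. The ex-Gaussian FTO parameters per cell were chosen
#' so that (a) the distribution mean `mu + tau` equals the target cell mean,
#' (b) the probability of a positive draw equals the gap share of the cell's
#' floor transfers — which makes the simulator's sign-conditional sampling
#' reproduce the untruncated ex-Gaussian exactly — and (c) the implied
#' median is as close as possible to the target cell median. Matching (a)
#' and (b) exactly leaves the distribution SD below the target dispersion;
#' see the package vignette.
#'
#' @param contexts Which contexts to keep rows for.
#' @return A tibble of cell parameters (see [sim_config()]).
#' @export
default_cell_params <- function(contexts = c("Introduction", "Tangram",
                                             "Discussion")) {
  cp <- tibble::tribble(
    ~group,    ~context,       ~mu,    ~sigma, ~tau,
    "ASD",     "Introduction", -159.4, 219.7,  605.4,
    "ASD",     "Tangram",      -259.0, 231.1,  922.0,
    "ASD",     "Discussion",   -144.0, 198.5,  547.0,
    "non-ASD", "Introduction", -17.1,  164.2,  108.1,
    "non-ASD", "Tangram",      -231.5, 265.2,  547.5,
    "non-ASD", "Discussion",   -70.3,  252.6,  234.3)
  mixes <- tibble::tribble(
    ~group,    ~p_within, ~p_between, ~p_gap,
    "ASD",     0.181,     0.196,      0.623,
    "non-ASD", 0.249,     0.247,      0.504)
  out <- dplyr::left_join(cp, mixes, by = "group")
  out[out$context %in% contexts, ]
}

#' The paper-scale preset configuration
#'
#' A [sim_config()] at the scale of the study corpus: 9 ASD and 14 non-ASD
#' dyads, three 10-minute contexts, with the reference cell parameters of
#' [default_cell_params()].
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
paper_preset <- function(seed = 1L, ...) {
  sim_config(n_dyads = c(ASD = 9, "non-ASD" = 14),
             context_duration_s = 600, seed = seed, ...)
}

# mixture with the dyad's logit perturbation applied to the within weight
perturb_mixture <- function(p, logit_offset) {
  if (logit_offset == 0 || p[["p_within"]] %in% c(0, 1)) return(p)
  lw <- stats::qlogis(p[["p_within"]]) + logit_offset
  w <- stats::plogis(lw)
  rest <- 1 - p[["p_within"]]
  c(p_within = w,
    p_between = unname(p[["p_between"]] / rest * (1 - w)),
    p_gap = unname(p[["p_gap"]] / rest * (1 - w)))
}

ms_round <- function(x) round(x, 3)

#' Simulate one dyad in one context
#'
#' Builds a two-speaker talkspurt timeline by alternating floor holders.
#' Each floor turn draws a log-normal duration; each transition event draws
#' a type from the cell's mixture. Within-overlaps place a short talkspurt
#' of the listener strictly inside the current turn (with minimum-silence
#' clearance on both sides); gaps and between-overlaps draw an FTO from the
#' dyad's ex-Gaussian, resampling until the sign matches the drawn type
#' (FTO = 0 counts as a gap), and start the next speaker's turn at the
#' current turn's end plus the FTO. All talkspurt boundaries are rounded to
#' the millisecond grid, so the pipeline recovers the injected FTO values
#' exactly.
#'
#' @param config A [sim_config()].
#' @param dyad_id Dyad identifier.
#' @param group,context Which cell to simulate.
#' @param dyad_mu_offset Dyad-level shift of `mu` in ms.
#' @param dyad_logit_offset Dyad-level logit shift of the within-overlap
#'   weight.
#' @return A list with `annotation` (a [dyad_annotation()]) and `truth`
#'   (tibble of injected transitions in the same shape as
#'   [extract_transitions()] output). Uses the current RNG state; seed
#'   externally (or via [simulate_corpus()]) for reproducibility.
#' @export
simulate_dyad <- function(config, dyad_id, group, context,
                          dyad_mu_offset = 0, dyad_logit_offset = 0) {
  stopifnot(inherits(config, "sim_config"))
  cell <- config$cell_params[config$cell_params$group == group &
                             config$cell_params$context == context, ]
  if (nrow(cell) != 1) stop("no cell parameters for ", group, "/", context)
  mu <- cell$mu + dyad_mu_offset; sigma <- cell$sigma; tau <- cell$tau
  mix <- perturb_mixture(c(p_within = cell$p_within, p_between = cell$p_between,
                           p_gap = cell$p_gap), dyad_logit_offset)
  clr <- config$min_silence_s + 0.001  # clearance incl. ms-grid safety
  dur <- config$context_duration_s
  draw_turn <- function() stats::rlnorm(1, config$turn_meanlog, config$turn_sdlog)
  draw_fto_s <- function(sign) {
    # rejection sampling of the sign-conditional ex-Gaussian, in seconds
    for (i in 1:2000) {
      x <- rexgauss(1, mu, sigma, tau) / 1000
      if (sign > 0 && x >= 0) return(x)
      if (sign < 0 && x < 0) return(x)
    }
    if (sign > 0) abs(stats::rnorm(1, 0, sigma / 1000))
    else -abs(stats::rnorm(1, 0, sigma / 1000))
  }

  speakers <- c("S1", "S2")
  spurts <- list()  # list of c(speaker_idx, start, end)
  truth <- list()
  last_end <- c(0, 0)  # last talkspurt end per speaker (any kind)

  holder <- 1L
  t <- ms_round(stats::runif(1, 0.3, 1.0))
  L <- ms_round(draw_turn())
  spurts[[1]] <- c(holder, t, t + L)
  last_end[holder] <- t + L

  repeat {
    other <- 3L - holder
    ev <- sample(c("within", "between", "gap"), 1, prob = mix)
    turn_end <- t + L
    if (turn_end > dur) break
    if (ev == "within") {
      placed <- FALSE
      for (try in 1:50) {
        d <- ms_round(stats::runif(1, config$within_dur_range[1],
                                   config$within_dur_range[2]))
        w_lo <- max(t, last_end[other]) + clr
        w_hi <- turn_end - clr - d
        if (w_hi >= w_lo) {
          ws <- ms_round(stats::runif(1, w_lo, w_hi))
          spurts[[length(spurts) + 1L]] <- c(other, ws, ws + d)
          last_end[other] <- ws + d
          truth[[length(truth) + 1L]] <- list(
            type = "within_overlap", fto_ms = NA_real_,
            prev_speaker = speakers[holder], next_speaker = speakers[other],
            anchor_time_s = turn_end)
          placed <- TRUE
          break
        }
      }
      # turn too crowded to host another backchannel: skip the event
      next
    }
    # floor transfer
    s <- NA
    for (try in 1:2000) {
      fto <- ms_round(draw_fto_s(if (ev == "gap") 1 else -1))
      cand <- ms_round(turn_end + fto)
      ok <- cand >= last_end[other] + clr - 1e-9 &&
        (ev == "gap" || (-fto) <= L - 2 * clr)
      if (ok) { s <- cand; break }
    }
    if (is.na(s)) break  # cell too constrained; end the conversation
    L_next <- NA
    for (try in 1:200) {
      cand_L <- ms_round(draw_turn())
      # an overlapping incomer must outlast the current turn, else it would
      # be a within-overlap, not a floor transfer
      if (s + cand_L >= turn_end + clr) { L_next <- cand_L; break }
    }
    if (is.na(L_next)) break
    if (s + L_next > dur) break
    truth[[length(truth) + 1L]] <- list(
      type = if (fto >= 0) "gap" else "between_overlap",
      fto_ms = round(fto * 1000),
      prev_speaker = speakers[holder], next_speaker = speakers[other],
      anchor_time_s = turn_end)
    spurts[[length(spurts) + 1L]] <- c(other, s, s + L_next)
    last_end[other] <- s + L_next
    holder <- other
    t <- s; L <- L_next
  }

  sp <- do.call(rbind, spurts)
  tiers <- lapply(1:2, function(k) {
    rows <- sp[sp[, 1] == k, , drop = FALSE]
    iv <- if (nrow(rows)) {
      tibble::tibble(start = rows[, 2], end = rows[, 3], kind = "speech")
    } else tibble::tibble(start = numeric(), end = numeric(), kind = character())
    interval_tier(speakers[k], iv, total_duration = dur)
  })
  ann <- dyad_annotation(dyad_id, group, context, tiers[[1]], tiers[[2]])
  truth_tab <- if (length(truth)) {
    tt <- dplyr::bind_rows(lapply(truth, tibble::as_tibble))
    tibble::tibble(dyad_id = dyad_id, group = group, context = context, tt)
  } else {
    tibble::tibble(dyad_id = character(), group = character(),
                   context = character(), type = character(),
                   fto_ms = numeric(), prev_speaker = character(),
                   next_speaker = character(), anchor_time_s = numeric())
  }
  list(annotation = ann, truth = truth_tab[order(truth_tab$anchor_time_s), ])
}

#' Simulate a full corpus of dyads
#'
#' Draws dyad-level random effects, simulates every dyad in every context,
#' and optionally writes the corpus to disk as TextGrids plus a metadata
#' CSV — byte-identical in shape to a real annotated corpus.
#'
#' @param config A [sim_config()].
#' @param out_dir If non-NULL, directory to write TextGrids, `metadata.csv`,
#'   `truth.csv` and `config.json` into (created if needed).
#' @return A list with `annotations` (list of [dyad_annotation()]), `truth`
#'   (tibble of all injected transitions), and `dyad_params` (realised
#'   dyad-level effects).
#' @export
simulate_corpus <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- rep(names(config$n_dyads), config$n_dyads)
  ids <- sprintf("dyad%02d", seq_along(groups))
  dyad_params <- tibble::tibble(
    dyad_id = ids, group = groups,
    mu_offset = stats::rnorm(length(ids), 0, config$dyad_sd_mu),
    logit_offset = stats::rnorm(length(ids), 0, config$dyad_sd_logit))
  annotations <- list()
  truth <- list()
  for (i in seq_along(ids)) {
    for (cx in config$contexts) {
      sim <- simulate_dyad(config, ids[i], groups[i], cx,
                           dyad_mu_offset = dyad_params$mu_offset[i],
                           dyad_logit_offset = dyad_params$logit_offset[i])
      key <- paste(ids[i], cx, sep = "_")
      annotations[[key]] <- sim$annotation
      truth[[key]] <- sim$truth
    }
  }
  truth <- dplyr::bind_rows(truth)
  out <- list(annotations = annotations, truth = truth,
              dyad_params = dyad_params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    md <- dplyr::bind_rows(lapply(names(annotations), function(key) {
      a <- annotations[[key]]
      fn <- paste0(key, ".TextGrid")
      write_textgrid(a, file.path(out_dir, fn))
      tibble::tibble(dyad_id = a$dyad_id, group = a$group, context = a$context,
                     path = fn, tier_a = a$tier_a$speaker_id,
                     tier_b = a$tier_b$speaker_id)
    }))
    utils::write.csv(md, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    cfg <- config
    cfg$cell_params <- as.data.frame(cfg$cell_params)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    out$out_dir <- out_dir
  }
  out
}
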