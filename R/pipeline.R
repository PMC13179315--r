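#' Read and validate a pipeline configuration file
#'
#' The pipeline is driven by a single YAML file. Recognised fields (all
#' optional unless a stage needs them):
#'
#' \preformatted{
#' metadata: corpus/metadata.csv    # extract: dyad -> TextGrid map
#' out_dir: results                 # every stage writes here
#' seed: 1
#' min_silence_s: 0.2
#' silence_labels: ["", "sil", "<p>"]
#' typology: {smooth_ms: 100, long_ms: 700}
#' model: {subsets: [full, gaps_only, overlaps_only],
#'         chains: 4, iter: 4000, warmup: 2000, desk_scale: false}
#' simulate: {n_asd: 9, n_non_asd: 14, context_duration_s: 600}
#' }
#'
#' @param path YAML config path, or a list with the same structure.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$out_dir <- cfg$out_dir %||% "turnfto-output"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$min_silence_s <- cfg$min_silence_s %||% 0.2
  cfg$silence_labels <- cfg$silence_labels %||% c("", "sil", "<p>")
  cfg$typology <- utils::modifyList(list(smooth_ms = 100, long_ms = 700),
                                   cfg$typology %||% list())
  if (with(cfg$typology, smooth_ms <= 0 || long_ms <= smooth_ms))
    stop("typology thresholds must satisfy 0 < smooth_ms < long_ms",
         call. = FALSE)
  cfg$model <- utils::modifyList(
    list(subsets = c("full", "gaps_only", "overlaps_only"),
         chains = 4L, iter = 4000L, warmup = 2000L, desk_scale = FALSE),
    cfg$model %||% list())
  if (!is.null(cfg$metadata) && !file.exists(cfg$metadata))
    stop("metadata file not found: ", cfg$metadata, call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

write_provenance <- function(cfg, stage, extra = list()) {
  prov <- c(list(stage = stage,
                 package = paste0("turnfto ",
                                  as.character(utils::packageVersion("turnfto"))),
                 seed = cfg$seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra)
  jsonlite::write_json(prov,
                       file.path(cfg$out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Pipeline stage: simulate a synthetic corpus
#'
#' Writes TextGrids, metadata, ground truth and provenance under
#' `<out_dir>/corpus/`, then points the config's `metadata` field at the
#' result so the extract stage can run on it directly.
#'
#' @param cfg A [pipeline_config()].
#' @return The updated config, invisibly.
#' @export
pipeline_simulate <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_opts <- cfg$simulate %||% list()
  config <- sim_config(
    n_dyads = c(ASD = sim_opts$n_asd %||% 9,
                "non-ASD" = sim_opts$n_non_asd %||% 14),
    context_duration_s = sim_opts$context_duration_s %||% 600,
    seed = cfg$seed)
  corpus_dir <- file.path(cfg$out_dir, "corpus")
  simulate_corpus(config, out_dir = corpus_dir)
  cfg$metadata <- file.path(corpus_dir, "metadata.csv")
  write_provenance(cfg, "simulate",
                   list(n_dyads = as.list(config$n_dyads),
                        context_duration_s = config$context_duration_s))
  message("simulate: corpus written to ", corpus_dir)
  invisible(cfg)
}

#' Pipeline stage: extract transitions from an annotated corpus
#'
#' Reads every TextGrid listed in the metadata CSV, normalises tiers with
#' the minimum-silence rule, extracts transitions, and writes
#' `transitions.csv` (all transitions) and `transitions_fto.csv` (gaps and
#' between-overlaps only) with counts logged to provenance.
#'
#' @param cfg A [pipeline_config()].
#' @return The combined transition table, invisibly.
#' @export
pipeline_extract <- function(cfg) {
  if (is.null(cfg$metadata)) stop("config needs a 'metadata' path", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  md <- read_metadata(cfg$metadata)
  tables <- lapply(seq_len(nrow(md)), function(i) {
    ann <- read_textgrid(md$path[i], c(md$tier_a[i], md$tier_b[i]),
                         dyad_id = md$dyad_id[i], group = md$group[i],
                         context = md$context[i],
                         silence_labels = cfg$silence_labels)
    extract_transitions(normalise_annotation(ann, cfg$min_silence_s))
  })
  tab <- bind_transitions(tables)
  fto <- filter_for_fto(tab)
  write_transitions(tab, file.path(cfg$out_dir, "transitions.csv"))
  write_transitions(fto, file.path(cfg$out_dir, "transitions_fto.csv"))
  counts <- table(factor(tab$type,
                         c("gap", "between_overlap", "within_overlap")))
  write_provenance(cfg, "extract",
                   list(n_recordings = nrow(md),
                        n_transitions = nrow(tab),
                        n_gap = unname(counts[["gap"]]),
                        n_between_overlap = unname(counts[["between_overlap"]]),
                        n_within_overlap_excluded =
                          unname(counts[["within_overlap"]]),
                        n_retained_for_fto = nrow(fto)))
  message(sprintf(
    "extract: %d transitions from %d recordings (%d within-overlaps excluded)",
    nrow(tab), nrow(md), nrow(tab) - nrow(fto)))
  invisible(tab)
}

#' Pipeline stage: descriptive summaries
#'
#' Computes group-by-context FTO summary tables, transition-type and
#' perceptual-category proportions, the per-dyad summary, and the tidy
#' density export, writing each as CSV under `out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of the summary tibbles, invisibly.
#' @export
pipeline_summarise <- function(cfg) {
  tab <- read_transitions(file.path(cfg$out_dir, "transitions.csv"))
  fto <- filter_for_fto(tab)
  out <- list(
    fto_by_group = summarise_fto(fto, "group"),
    fto_by_group_context = summarise_fto(fto, c("group", "context")),
    fto_by_dyad = dyad_summary(fto),
    type_proportions = type_proportions(tab, "group"),
    category_proportions = category_proportions_wide(
      fto, c("group", "context"),
      smooth_ms = cfg$typology$smooth_ms, long_ms = cfg$typology$long_ms),
    density_data = export_density_data(fto)$data)
  for (nm in names(out))
    utils::write.csv(as.data.frame(out[[nm]]),
                     file.path(cfg$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  write_provenance(cfg, "summarise", list(tables = names(out)))
  message("summarise: ", length(out), " tables written to ", cfg$out_dir)
  invisible(out)
}

#' Pipeline stage: fit the multilevel ex-Gaussian models
#'
#' Fits the configured subsets (full, gaps-only, overlaps-only) and writes
#' one posterior-summary CSV per subset containing the overall group
#' contrast, per-context group contrasts and within-group context
#' contrasts, with the robustness flag applied to each.
#'
#' @param cfg A [pipeline_config()].
#' @return Named list of summary tibbles, invisibly.
#' @export
pipeline_fit <- function(cfg) {
  tab <- read_transitions(file.path(cfg$out_dir, "transitions.csv"))
  fto <- filter_for_fto(tab)
  summaries <- list()
  for (subset in cfg$model$subsets) {
    spec <- model_spec(subset, chains = cfg$model$chains,
                       iter = cfg$model$iter, warmup = cfg$model$warmup,
                       seed = cfg$seed, desk_scale = cfg$model$desk_scale)
    fit <- fit_hierarchical(fto, spec)
    contrasts <- c("group", paste0("group@", fit$task_levels))
    if (length(fit$task_levels) > 1) {
      for (g in fit$group_levels) {
        pairs <- utils::combn(fit$task_levels, 2)
        contrasts <- c(contrasts,
                       apply(pairs, 2, function(p)
                         paste0(p[2], "-", p[1], "@", g)))
      }
    }
    summ <- dplyr::bind_rows(lapply(unique(contrasts), summarise_contrast,
                                    fit = fit))
    summ$robust <- vapply(seq_len(nrow(summ)),
                          function(i) is_robust(summ[i, ]), logical(1))
    utils::write.csv(as.data.frame(summ),
                     file.path(cfg$out_dir, paste0("model_", subset, ".csv")),
                     row.names = FALSE)
    summaries[[subset]] <- summ
    message("fit: subset '", subset, "' done (",
            length(fit$data$y), " observations)")
  }
  write_provenance(cfg, "fit",
                   list(subsets = cfg$model$subsets,
                        sampler = cfg$model[c("chains", "iter", "warmup",
                                              "desk_scale")]))
  invisible(summaries)
}

#' Run the full pipeline
#'
#' `simulate` (optional) then `extract`, `summarise` and `fit`.
#'
#' @param cfg A [pipeline_config()] (or path to one).
#' @param simulate Start from a synthetic corpus instead of an existing
#'   metadata file?
#' @return Named list with the outputs of each stage, invisibly.
#' @export
pipeline_run <- function(cfg, simulate = is.null(cfg$metadata)) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  if (simulate) cfg <- pipeline_simulate(cfg)
  tab <- pipeline_extract(cfg)
  summ <- pipeline_summarise(cfg)
  fits <- pipeline_fit(cfg)
  invisible(list(transitions = tab, summaries = summ, models = fits))
}
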