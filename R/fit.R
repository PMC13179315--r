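#' Specify a multilevel ex-Gaussian FTO model
#'
#' Defines which FTO subset is modelled, the fixed-effect structure (always
#' Group x Context with treatment coding, reference levels ASD and
#' Introduction), the dyad-level random structure (random intercept plus
#' random context slopes, independent), and the sampler settings.
#'
#' `subset = "gaps_only"` keeps strictly positive FTO values;
#' `"overlaps_only"` keeps strictly negative values and models their
#' magnitude (|FTO|) so the right-skewed ex-Gaussian applies, flipping
#' contrast signs back on report. FTO = 0 rows belong to neither one-sided
#' subset.
#'
#' @param subset One of `"full"`, `"gaps_only"`, `"overlaps_only"`.
#' @param chains,iter,warmup MCMC settings. The default (4 chains of 4000
#'   iterations, 2000 warmup) matches common practice for these models;
#'   `desk_scale = TRUE` switches to a reduced 2 x 1000/500 setting for
#'   quick pipelines, which is *not* intended for publication-grade
#'   inference.
#' @param seed Integer seed controlling the MCMC reproducibly.
#' @param desk_scale Use the reduced sampler settings?
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(subset = c("full", "gaps_only", "overlaps_only"),
                       chains = 4, iter = 4000, warmup = 2000,
                       seed = 1, desk_scale = FALSE) {
  subset <- match.arg(subset)
  if (desk_scale) { chains <- 2; iter <- 1000; warmup <- 500 }
  stopifnot(chains >= 1, iter > warmup, warmup >= 1)
  structure(list(subset = subset, chains = as.integer(chains),
                 iter = as.integer(iter), warmup = as.integer(warmup),
                 seed = as.integer(seed), desk_scale = desk_scale),
            class = "model_spec")
}

# JAGS program, hierarchically centred: dyad-by-context cell means are drawn
# around the fixed-effect cell means, which mixes far better under Gibbs
# sampling than the non-centred parameterisation. The latent exponential
# component e[i] makes the ex-Gaussian likelihood exact.
jags_model_multi <- "
model {
  for (i in 1:N) {
    e[i] ~ dexp(inv_tau)
    y[i] ~ dnorm(m[dyad[i], task[i]] + e[i], prec)
  }
  for (j in 1:ND) {
    m[j, 1] ~ dnorm(eta[g[j], 1], prec_u0)
    for (t in 2:NT) {
      m[j, t] ~ dnorm(eta[g[j], t] + m[j, 1] - eta[g[j], 1], prec_ut)
    }
  }
  bt[1] <- 0
  bgt[1] <- 0
  for (t in 2:NT) {
    bt[t] ~ dnorm(0, 1e-6)
    bgt[t] ~ dnorm(0, 1e-6)
  }
  b0 ~ dnorm(0, 1e-6)
  bg ~ dnorm(0, 1e-6)
  for (gi in 1:2) {
    for (t in 1:NT) {
      eta[gi, t] <- b0 + bg * (gi - 1) + bt[t] + bgt[t] * (gi - 1)
    }
  }
  sigma ~ dnorm(0, 4e-6) T(0,)
  prec <- pow(sigma, -2)
  tau ~ dnorm(0, 4e-6) T(0,)
  inv_tau <- 1 / tau
  sd_u0 ~ dnorm(0, 4e-6) T(0,)
  prec_u0 <- pow(sd_u0, -2)
  sd_ut ~ dnorm(0, 4e-6) T(0,)
  prec_ut <- pow(sd_ut, -2)
}"

jags_model_single <- "
model {
  for (i in 1:N) {
    e[i] ~ dexp(inv_tau)
    y[i] ~ dnorm(m[dyad[i]] + e[i], prec)
  }
  for (j in 1:ND) {
    m[j] ~ dnorm(b0 + bg * (g[j] - 1), prec_u0)
  }
  b0 ~ dnorm(0, 1e-6)
  bg ~ dnorm(0, 1e-6)
  sigma ~ dnorm(0, 4e-6) T(0,)
  prec <- pow(sigma, -2)
  tau ~ dnorm(0, 4e-6) T(0,)
  inv_tau <- 1 / tau
  sd_u0 ~ dnorm(0, 4e-6) T(0,)
  prec_u0 <- pow(sd_u0, -2)
}"

#' Fit the Bayesian multilevel ex-Gaussian model of FTO
#'
#' Fits `FTO ~ Group * Context + (1 + Context | Dyad)` with an ex-Gaussian
#' likelihood by MCMC. Priors are weakly informative and centred at zero:
#' Normal(0, 1000 ms) on the intercept and all fixed-effect coefficients,
#' half-Normal(0, 500 ms) on the residual Gaussian SD, the exponential mean
#' and the random-effect SDs. Only the location `mu` of the ex-Gaussian
#' carries the regression structure; `sigma` and `tau` are global. Random
#' intercepts and context slopes are independent zero-mean normals.
#'
#' Tables with a single context are fitted with the group-only reduction of
#' the same model (no context terms).
#'
#' @param table A transition table (see [extract_transitions()]); rows with
#'   `NA` FTO (within-speaker overlaps) are dropped automatically.
#' @param spec A [model_spec()].
#' @param quiet Suppress JAGS progress output (default TRUE).
#' @return An object of class `exgauss_hfit`: posterior draws
#'   (`coda::mcmc.list`), the spec, factor-level bookkeeping, and
#'   convergence diagnostics (`rhat`, `ess` per monitored parameter).
#'   A warning is issued if any split R-hat exceeds 1.01.
#' @export
fit_hierarchical <- function(table, spec = model_spec(), quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  tab <- table[!is.na(table$fto_ms), ]
  flipped <- FALSE
  if (spec$subset == "gaps_only") {
    tab <- tab[tab$fto_ms > 0, ]
  } else if (spec$subset == "overlaps_only") {
    tab <- tab[tab$fto_ms < 0, ]
    flipped <- TRUE
  }
  if (!nrow(tab)) stop("subset '", spec$subset, "' is empty", call. = FALSE)
  y <- if (flipped) -tab$fto_ms else tab$fto_ms

  group_levels <- c("ASD", "non-ASD")
  task_levels <- intersect(c("Introduction", "Tangram", "Discussion"),
                           unique(tab$context))
  dyads <- sort(unique(tab$dyad_id))
  dyad_idx <- match(tab$dyad_id, dyads)
  g_of_dyad <- match(tab$group[match(dyads, tab$dyad_id)], group_levels)
  if (any(is.na(g_of_dyad))) stop("unknown group label", call. = FALSE)
  if (min(table(factor(g_of_dyad, levels = 1:2))) < 2)
    stop("need at least 2 dyads per group", call. = FALSE)
  nt <- length(task_levels)

  data <- list(y = y, dyad = dyad_idx, g = g_of_dyad,
               N = length(y), ND = length(dyads))
  if (nt > 1) {
    data$task <- match(tab$context, task_levels)
    data$NT <- nt
    model_string <- jags_model_multi
    monitors <- c("b0", "bg", "bt", "bgt", "sigma", "tau", "sd_u0", "sd_ut", "m")
  } else {
    model_string <- jags_model_single
    monitors <- c("b0", "bg", "sigma", "tau", "sd_u0", "m")
  }

  # block-updating of the normal linear substructure (JAGS glm module)
  # mixes far better than single-site Gibbs for the fixed effects
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (spec$seed * 1009L + ch) %% .Machine$integer.max)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = max(100L, spec$warmup %/% 2L),
                          quiet = quiet)
  stats::update(jm, spec$warmup)
  draws <- rjags::coda.samples(jm, monitors, n.iter = spec$iter - spec$warmup)

  core <- intersect(c("b0", "bg", "bt[2]", "bt[3]", "bgt[2]", "bgt[3]",
                      "sigma", "tau", "sd_u0", "sd_ut"),
                    coda::varnames(draws))
  diag <- tryCatch({
    gd <- coda::gelman.diag(draws[, core, drop = FALSE],
                            autoburnin = FALSE, multivariate = FALSE)
    data.frame(parameter = core, rhat = gd$psrf[, 1],
               ess = as.numeric(coda::effectiveSize(draws[, core, drop = FALSE])))
  }, error = function(e) data.frame(parameter = core, rhat = NA_real_,
                                    ess = NA_real_))
  if (any(is.finite(diag$rhat) & diag$rhat > 1.01))
    warning("some R-hat values exceed 1.01; consider longer chains:\n",
            paste(sprintf("  %s: %.3f", diag$parameter, diag$rhat),
                  collapse = "\n"))

  structure(list(draws = draws, spec = spec, flipped = flipped,
                 group_levels = group_levels, task_levels = task_levels,
                 dyads = dyads, g_of_dyad = g_of_dyad,
                 data = list(y = y, dyad = dyad_idx,
                             task = if (nt > 1) data$task else rep(1L, length(y)),
                             group = tab$group, context = tab$context),
                 diagnostics = diag),
            class = "exgauss_hfit")
}

#' @export
print.exgauss_hfit <- function(x, ...) {
  cat(sprintf("<exgauss_hfit> subset '%s': %d obs, %d dyads, %d context(s)\n",
              x$spec$subset, length(x$data$y), length(x$dyads),
              length(x$task_levels)))
  cat(sprintf("  %d chains x %d post-warmup iterations; max R-hat %.3f\n",
              x$spec$chains, x$spec$iter - x$spec$warmup,
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))))
  invisible(x)
}

# stack mcmc.list into a matrix, keeping a chain id column
draws_matrix <- function(fit) {
  do.call(rbind, lapply(fit$draws, as.matrix))
}

# per-chain draws of a derived scalar given a function over the draw matrix
derived_chains <- function(fit, f) {
  lapply(fit$draws, function(ch) f(as.matrix(ch)))
}

# posterior draws of the fixed-effect group difference (non-ASD - ASD)
# within task t (index into fit$task_levels)
group_diff_draws <- function(mat, fit, t) {
  d <- mat[, "bg"]
  if (length(fit$task_levels) > 1 && t > 1)
    d <- d + mat[, sprintf("bgt[%d]", t)]
  if (fit$flipped) -d else d
}

#' Posterior summary of a model contrast
#'
#' Summarises the posterior distribution of a named contrast of the fixed
#' effects: posterior mean difference (delta), equal-tailed 95% credible
#' interval, the posterior probability that delta exceeds zero, and
#' convergence diagnostics for the derived quantity. For overlaps-only fits
#' the sign is reported on the original (negative) FTO scale.
#'
#' Supported contrast names:
#' \itemize{
#'   \item `"group"` — non-ASD minus ASD, averaged over the contexts in the
#'     model (the overall group effect).
#'   \item `"group@<context>"` — group difference within one context, e.g.
#'     `"group@Tangram"`.
#'   \item `"<contextA>-<contextB>@<group>"` — context difference within one
#'     group, e.g. `"Tangram-Introduction@non-ASD"`.
#' }
#'
#' @param fit An `exgauss_hfit`.
#' @param contrast Contrast name (see Details).
#' @param prob Credible-interval mass (default 0.95, equal-tailed).
#' @return A one-row tibble: `contrast, delta_mean, ci_low, ci_high,
#'   p_gt_zero, rhat, ess`.
#' @export
summarise_contrast <- function(fit, contrast = "group", prob = 0.95) {
  stopifnot(inherits(fit, "exgauss_hfit"))
  f <- contrast_fun(fit, contrast)
  chains <- derived_chains(fit, f)
  d <- unlist(chains, use.names = FALSE)
  a <- (1 - prob) / 2
  qs <- unname(stats::quantile(d, c(a, 1 - a)))
  diag <- tryCatch({
    ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
    list(rhat = if (length(chains) > 1)
           coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1] else NA_real_,
         ess = as.numeric(coda::effectiveSize(ml)))
  }, error = function(e) list(rhat = NA_real_, ess = NA_real_))
  tibble::tibble(contrast = contrast, delta_mean = mean(d),
                 ci_low = qs[1], ci_high = qs[2],
                 p_gt_zero = mean(d > 0),
                 rhat = diag$rhat, ess = diag$ess)
}

# build the draw-matrix -> delta function for a named contrast
contrast_fun <- function(fit, contrast) {
  tl <- fit$task_levels
  sgn <- if (fit$flipped) -1 else 1
  if (identical(contrast, "group")) {
    return(function(mat) {
      d <- mat[, "bg"]
      if (length(tl) > 1) {
        extra <- sapply(2:length(tl), function(t) mat[, sprintf("bgt[%d]", t)])
        d <- d + rowSums(cbind(extra)) / length(tl)
      }
      sgn * d
    })
  }
  if (grepl("^group@", contrast)) {
    task <- sub("^group@", "", contrast)
    t <- match(task, tl)
    if (is.na(t)) stop("unknown context '", task, "'", call. = FALSE)
    return(function(mat) group_diff_draws(mat, fit, t))
  }
  m <- regmatches(contrast, regexec("^([^-@]+)-([^-@]+)@(.+)$", contrast))[[1]]
  if (length(m) == 4) {
    ta <- match(m[2], tl); tb <- match(m[3], tl)
    gi <- match(m[4], fit$group_levels)
    if (is.na(ta) || is.na(tb) || is.na(gi))
      stop("unknown contrast '", contrast, "'", call. = FALSE)
    return(function(mat) {
      eff <- function(t) {
        if (t == 1) rep(0, nrow(mat))
        else {
          v <- mat[, sprintf("bt[%d]", t)]
          if (gi == 2) v <- v + mat[, sprintf("bgt[%d]", t)]
          v
        }
      }
      sgn * (eff(ta) - eff(tb))
    })
  }
  stop("unknown contrast '", contrast, "'", call. = FALSE)
}

#' Apply the robustness criterion to a posterior contrast
#'
#' An effect is considered robust when its 95% credible interval excludes
#' zero — or includes it only by a small margin — *and* the posterior
#' probability of the effect's direction, `max(P(delta > 0), P(delta < 0))`,
#' is at least `p_threshold`.
#'
#' @param summary A one-row summary from [summarise_contrast()].
#' @param p_threshold Directional posterior-probability threshold
#'   (default 0.89).
#' @param margin_fraction Zero may intrude into the CI by at most this
#'   fraction of the CI width (default 0.02) and still count as "only
#'   narrowly" included.
#' @return Logical scalar.
#' @export
is_robust <- function(summary, p_threshold = 0.89, margin_fraction = 0.02) {
  stopifnot(all(c("ci_low", "ci_high", "p_gt_zero") %in% names(summary)))
  lo <- summary$ci_low[1]; hi <- summary$ci_high[1]
  p <- summary$p_gt_zero[1]
  excludes <- lo > 0 || hi < 0
  narrow <- !excludes && min(abs(lo), abs(hi)) <= margin_fraction * (hi - lo)
  (excludes || narrow) && max(p, 1 - p) >= p_threshold
}

#' Posterior predictive check of an ex-Gaussian FTO model
#'
#' Replicates datasets from the fitted model (same dyad/context design, new
#' Gaussian and exponential noise) and compares summary statistics of the
#' replicates with the observed data. Reported tail areas are
#' `P(T(y_rep) >= T(y))`; values near 0 or 1 flag misfit of that statistic.
#'
#' @param fit An `exgauss_hfit`.
#' @param n_rep Number of posterior draws used (default 200).
#' @param seed Seed for the replication noise.
#' @return A list with `stats` (tibble: statistic, observed, rep_mean,
#'   tail_area) and `replicates` (matrix of replicate statistics).
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = 1) {
  stopifnot(inherits(fit, "exgauss_hfit"))
  mat <- draws_matrix(fit)
  idx <- round(seq(1, nrow(mat), length.out = min(n_rep, nrow(mat))))
  y <- fit$data$y
  nt <- length(fit$task_levels)
  m_cols <- if (nt > 1) {
    sprintf("m[%d,%d]", fit$data$dyad, fit$data$task)
  } else sprintf("m[%d]", fit$data$dyad)
  stat_names <- c("mean", "sd", "median", "p_smooth", "p_long")
  obs_stats <- ppc_stats(y)
  reps <- withr::with_seed(seed, {
    t(vapply(idx, function(r) {
      mu_i <- mat[r, m_cols]
      yrep <- stats::rnorm(length(y), mu_i, mat[r, "sigma"]) +
        stats::rexp(length(y), rate = 1 / mat[r, "tau"])
      ppc_stats(yrep)
    }, numeric(length(stat_names))))
  })
  colnames(reps) <- stat_names
  tail_area <- vapply(stat_names, function(s)
    mean(reps[, s] >= obs_stats[[s]]), numeric(1))
  list(stats = tibble::tibble(statistic = stat_names,
                              observed = as.numeric(obs_stats[stat_names]),
                              rep_mean = colMeans(reps),
                              tail_area = as.numeric(tail_area)),
       replicates = reps)
}

ppc_stats <- function(y) {
  c(mean = mean(y), sd = stats::sd(y), median = stats::median(y),
    p_smooth = mean(abs(y) < 100), p_long = mean(abs(y) >= 700))
}
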