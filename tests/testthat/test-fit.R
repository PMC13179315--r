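# minimal fit-shaped object whose draws are fully under test control
fake_fit <- function(draw_chains, flipped = FALSE) {
  structure(list(
    draws = coda::mcmc.list(lapply(draw_chains, function(d)
      coda::mcmc(matrix(d, ncol = 1, dimnames = list(NULL, "bg"))))),
    spec = model_spec("full", chains = length(draw_chains), iter = 2,
                      warmup = 1),
    flipped = flipped,
    group_levels = c("ASD", "non-ASD"),
    task_levels = "Introduction"),
    class = "exgauss_hfit")
}

small_corpus <- function(mu_asd, mu_non, seed, n_dyads = 3,
                         context_duration_s = 150, contexts = "Introduction",
                         dyad_sd_mu = 80) {
  cells <- sign_consistent_cells(mu_asd, mu_non, sigma = 150, tau = 400,
                                 p_within = 0.1, contexts = contexts)
  cfg <- sim_config(n_dyads = c(ASD = n_dyads, "non-ASD" = n_dyads),
                    contexts = contexts,
                    context_duration_s = context_duration_s,
                    cell_params = cells, dyad_sd_mu = dyad_sd_mu,
                    dyad_sd_logit = 0, seed = seed)
  corp <- simulate_corpus(cfg)
  filter_for_fto(bind_transitions(lapply(corp$annotations,
                                         extract_transitions)))
}

test_that("contrast summaries match brute-force quantiles on fixed draws", {
  # degenerate draws
  sm <- summarise_contrast(fake_fit(list(rep(-204, 50), rep(-204, 50))))
  expect_equal(sm$delta_mean, -204)
  expect_equal(sm$ci_low, -204)
  expect_equal(sm$ci_high, -204)
  expect_equal(sm$p_gt_zero, 0)

  # symmetric draws: P(delta > 0) near 1/2
  set.seed(1)
  z <- stats::rnorm(20000)
  sm2 <- summarise_contrast(fake_fit(list(z[1:10000], z[10001:20000])))
  expect_lt(abs(sm2$p_gt_zero - 0.5), 0.02)

  # 100 fixed draws against direct quantile computation
  set.seed(2)
  d <- stats::rnorm(100, 50, 30)
  sm3 <- summarise_contrast(fake_fit(list(d[1:50], d[51:100])))
  expect_equal(sm3$delta_mean, mean(d))
  expect_equal(sm3$ci_low, unname(stats::quantile(d, 0.025)))
  expect_equal(sm3$ci_high, unname(stats::quantile(d, 0.975)))
  expect_equal(sm3$p_gt_zero, mean(d > 0))

  # flipped (overlaps-only) fits report on the original scale
  sm4 <- summarise_contrast(fake_fit(list(d[1:50], d[51:100]), flipped = TRUE))
  expect_equal(sm4$delta_mean, -mean(d))
  expect_equal(sm4$ci_low, unname(-stats::quantile(d, 0.975)))
})

test_that("the robustness criterion reproduces its defining cases", {
  mk <- function(lo, hi, p) tibble::tibble(contrast = "group",
                                           delta_mean = (lo + hi) / 2,
                                           ci_low = lo, ci_high = hi,
                                           p_gt_zero = p, rhat = 1, ess = 1000)
  # CI clear of zero, directional probability 1: robust
  expect_true(is_robust(mk(-339, -66, 0)))
  # CI broadly spanning zero with p = 0.81: not robust
  expect_false(is_robust(mk(-150, 250, 0.81)))
  # CI only narrowly including zero with p = 0.92: robust
  expect_true(is_robust(mk(-5, 400, 0.92)))
  # narrow inclusion but weak direction: not robust
  expect_false(is_robust(mk(-5, 400, 0.85)))
  # clear CI but p below threshold cannot happen for equal-tailed 95% CIs,
  # the conjunction still guards against asymmetric summaries
  expect_false(is_robust(mk(10, 400, 0.80)))
})

test_that("a group shift injected into a small corpus is recovered with correct direction", {
  fto <- small_corpus(mu_asd = 0, mu_non = -250, seed = 31)
  fit <- suppressWarnings(
    fit_hierarchical(fto, model_spec("full", chains = 2, iter = 1200,
                                     warmup = 500, seed = 3)))
  sm <- summarise_contrast(fit, "group")
  expect_lt(sm$delta_mean, 0)          # non-ASD minus ASD
  expect_lt(sm$p_gt_zero, 0.05)
  expect_gt(sm$ci_low, -250 - 400)     # interval in a sane range
  expect_lt(sm$ci_high, 150)
})

test_that("doubling iterations moves the contrast by less than Monte-Carlo error", {
  fto <- small_corpus(mu_asd = 0, mu_non = -250, seed = 32)
  f1 <- suppressWarnings(fit_hierarchical(
    fto, model_spec("full", chains = 2, iter = 900, warmup = 400, seed = 7)))
  f2 <- suppressWarnings(fit_hierarchical(
    fto, model_spec("full", chains = 2, iter = 1400, warmup = 400, seed = 8)))
  s1 <- summarise_contrast(f1, "group")
  s2 <- summarise_contrast(f2, "group")
  mcse <- sqrt((s1$ci_high - s1$ci_low)^2 / 16 / s1$ess +
               (s2$ci_high - s2$ci_low)^2 / 16 / s2$ess)
  expect_lt(abs(s1$delta_mean - s2$delta_mean), 5 * mcse + 10)
})

test_that("one-sided subsets partition the data and flip overlaps coherently", {
  fto <- small_corpus(mu_asd = 0, mu_non = 0, seed = 33)
  fto$fto_ms[1] <- 0  # force an exact-zero row
  spec_g <- model_spec("gaps_only", chains = 2, iter = 600, warmup = 300,
                       seed = 1)
  spec_o <- model_spec("overlaps_only", chains = 2, iter = 600, warmup = 300,
                       seed = 1)
  fg <- suppressWarnings(fit_hierarchical(fto, spec_g))
  fo <- suppressWarnings(fit_hierarchical(fto, spec_o))
  # gaps (fto > 0) + overlaps (fto < 0) + zeros = all FTO rows
  expect_equal(length(fg$data$y) + length(fo$data$y) + sum(fto$fto_ms == 0),
               nrow(fto))
  expect_true(all(fg$data$y > 0))
  expect_true(all(fo$data$y > 0))  # magnitudes after the sign flip
  expect_true(fo$flipped)

  # a table with no negative FTOs cannot support an overlaps-only model
  gaps_only_tab <- fto[fto$fto_ms > 0, ]
  expect_error(fit_hierarchical(gaps_only_tab, spec_o), "empty")
  one_dyad <- fto[fto$dyad_id == fto$dyad_id[1], ]
  expect_error(fit_hierarchical(one_dyad, spec_g), "2 dyads")
})

test_that("posterior predictive checks pass on well-specified data and flag contamination", {
  fto <- small_corpus(mu_asd = -50, mu_non = -50, seed = 34,
                      context_duration_s = 200)
  fit <- suppressWarnings(fit_hierarchical(
    fto, model_spec("full", chains = 2, iter = 1000, warmup = 500, seed = 2)))
  ppc <- posterior_predictive_check(fit, n_rep = 150, seed = 1)
  for (s in c("mean", "sd", "median"))
    expect_true(ppc$stats$tail_area[ppc$stats$statistic == s] > 0.02 &&
                ppc$stats$tail_area[ppc$stats$statistic == s] < 0.98,
                label = paste("tail area for", s))

  # contaminate with a far right tail the ex-Gaussian cannot produce:
  # the SD check must become extreme
  contaminated <- fto
  contaminated$fto_ms[1:3] <- c(100000, 110000, 120000)
  fit2 <- suppressWarnings(fit_hierarchical(
    contaminated, model_spec("full", chains = 2, iter = 1000, warmup = 500,
                             seed = 2)))
  ppc2 <- posterior_predictive_check(fit2, n_rep = 150, seed = 1)
  sd_tail <- ppc2$stats$tail_area[ppc2$stats$statistic == "sd"]
  expect_true(sd_tail < 0.05 || sd_tail > 0.95)
})
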