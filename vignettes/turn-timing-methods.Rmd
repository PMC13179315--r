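---
title: "Turn-timing analysis with turnfto: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turn-timing analysis with turnfto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnfto)
```

## The measurement problem

In dyadic conversation, speakers exchange the floor with remarkable temporal
precision. The standard quantity for studying this coordination is the
**Floor Transfer Offset (FTO)**: the signed time between the end of one
speaker's turn and the onset of the next speaker's turn. Positive FTOs are
silent *gaps*; negative FTOs are *between-speaker overlaps*. A third event
type, the *within-speaker overlap* (typically a backchannel such as
"mm-hm"), is speech by the listener fully contained in the current speaker's
talkspurt: the floor never changes hands, no FTO is defined, and such events
are excluded from timing analysis by standard practice.

`turnfto` implements the full chain from raw two-speaker speech/silence
annotations to group-level Bayesian inference:

1. **Annotation IO** — Praat TextGrid (long and short text dialects,
   UTF-8/UTF-16) or a plain interval CSV; blank labels and a configurable
   label set (`""`, `"sil"`, `"<p>"`) count as silence, everything else as
   speech.
2. **Normalisation** — a minimum-silence rule: internal silences shorter
   than 200 ms are absorbed into surrounding speech, so that talkspurts are
   bounded only by silences of at least 200 ms. The rule is idempotent and
   conserves total annotated time; leading and trailing silences are never
   absorbed.
3. **Turn extraction** — talkspurts of both speakers are processed in onset
   order while tracking the floor holder; each floor transfer is emitted
   with its FTO (ms), each contained talkspurt as a within-speaker overlap.
4. **Typology and descriptives** — the five perceptual categories
   (smooth/|FTO| < 100 ms; gap and overlap up to 700 ms; long gap and long
   overlap at 700 ms or beyond), per-group and per-context FTO summaries,
   and the speaker-balance score.
5. **Inference** — Bayesian multilevel ex-Gaussian regressions of FTO with
   group-by-context fixed effects and dyad-level random structure, posterior
   contrasts, a robustness criterion and posterior predictive checks.
6. **Simulation** — a generative model of two-channel conversation timelines
   with full ground truth, used throughout the test suite.

## The floor-transfer rule

The only genuinely open design point in turn extraction is what counts as a
floor transfer when talkspurts interleave in unusual ways. `turnfto` uses a
deterministic, local rule: a talkspurt `T` by the non-floor-holder is a
within-speaker overlap **iff a single talkspurt of the floor holder starts
strictly before `T` and ends strictly after it**. Otherwise the floor
transfers, and

```
FTO = onset(T) - max{ end(s) : s a floor-holder talkspurt with onset <= onset(T) }
```

Consequences worth knowing:

* A listener talkspurt that bridges a pause of the floor holder transfers
  the floor (it is not contained in a *single* talkspurt).
* `FTO = 0` exactly is classified as a gap; the one-sided model subsets
  (gaps-only uses FTO > 0, overlaps-only FTO < 0) both exclude it.
* Two degenerate identical talkspurts (same boundaries on both tiers)
  transfer the floor with FTO = −duration: neither contains the other.
* When both speakers start the recording simultaneously, the initial floor
  goes to the speaker whose talkspurt ends later, with a lexicographic
  tie-break on speaker id. This is the single label-dependent point of the
  algorithm; the symmetry test excludes exactly this configuration.
* Consecutive talkspurts of one speaker are within-speaker pauses and emit
  nothing.

The test suite pins this rule to an independently written brute-force
reference over thousands of enumerated and randomised two-speaker timelines.

## The ex-Gaussian model

FTO distributions are leptokurtic with a peak near 0 ms and a long right
tail, and the field's standard model is the **ex-Gaussian**: the sum of a
Gaussian (location `mu`, scale `sigma`) and an exponential (mean `tau`), with
distribution mean `mu + tau` and variance `sigma^2 + tau^2`. The log-density

\[
\log f(x) = -\log\tau + \frac{\sigma^2}{2\tau^2} - \frac{x-\mu}{\tau}
  + \log\Phi\!\Big(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\Big)
\]

cancels catastrophically in the near-Gaussian regime, so `dexgauss()`
evaluates it through the scaled complementary error function on one branch
and the log-CDF form on the other; the unit tests verify normalisation to
`1e-6` and agreement with exponential and Gaussian limits. The CDF uses the
identity `F(x) = pnorm(z) - tau * f(x)`.

### Hierarchical model

`fit_hierarchical()` fits, on the millisecond scale,

```
fto ~ Group * Context + (1 + Context | Dyad),  ex-Gaussian likelihood
```

with treatment coding (reference levels: group ASD, context Introduction).
Only the location `mu` carries the regression; `sigma` and `tau` are global
per model. This mirrors the default behaviour of mainstream distributional
regression software and has a consequence that users must keep in mind when
interpreting contrasts: **`delta` is a contrast of Gaussian locations, not
of distribution means**. If two groups differ mainly in tail weight
(`tau`), their raw mean FTOs can differ by hundreds of milliseconds while
`delta` — which tracks the location of the distribution's left edge — is
much smaller. The package's reference simulation shows exactly this
pattern.

Priors are weakly informative and centred at zero: Normal(0, 1000 ms) for
the intercept and all fixed effects (FTOs live within roughly ±3000 ms, so
this is flat over the feasible range while regularising), half-Normal(0,
500 ms) for `sigma`, `tau` and the random-effect SDs. Random intercepts and
random context slopes are **independent** zero-mean normals; the package
does not model their correlation — one parameter fewer, with negligible
influence at 9–14 dyads per group, and the reduction keeps the Gibbs
sampler's conditional structure simple.

### Computation

The ex-Gaussian likelihood is handled by exact data augmentation: each
observation carries a latent exponential component `e_i ~ Exp(1/tau)` with
`y_i ~ Normal(mu_i + e_i, sigma)`. Sampling runs in JAGS with two choices
that matter for mixing:

* **hierarchical centring** — dyad-by-context cell means are drawn around
  the fixed-effect cell means rather than around zero; and
* the JAGS **glm module**, which block-updates the normal linear
  substructure.

Default sampler settings are 4 chains × 4000 iterations with 2000 warmup
(8000 retained draws). A documented *desk-scale* mode (2 chains ×
1000/500) exists for pipelines and continuous integration; it is not
intended for publication-grade inference. Convergence is summarised by
split R-hat and effective sample size per parameter, with a warning above
R-hat 1.01. Derived contrasts are summarised with their own R-hat/ESS: the
overall group contrast typically mixes far better than individual
interaction coefficients, whose chain-to-chain differences cancel in the
difference.

### Contrasts and robustness

`summarise_contrast()` reports the posterior mean difference `delta`, the
equal-tailed 95% credible interval and `P(delta > 0)`. `"group"` averages
the group difference over the contexts in the model; `"group@Tangram"` and
`"Tangram-Introduction@non-ASD"` give cell-level contrasts. For
overlaps-only fits the magnitudes are modelled (|FTO|, so the right-skewed
ex-Gaussian applies) and signs are flipped back on report.

`is_robust()` encodes the decision rule: the 95% CI excludes zero — or
includes it by at most 2% of its width — *and* the directional posterior
probability `max(P(delta>0), 1-P(delta>0))` is at least 0.89. The 2% margin
quantifies "only narrowly includes zero", which the decision rule's source
leaves unquantified; at a typical CI width of ~270 ms it allows an
intrusion of ~5 ms.

Posterior predictive checks replicate datasets from the fitted model over
the observed design and compare mean, SD, median and the smooth/long
category shares; tail areas near 0 or 1 flag the statistic the model cannot
reproduce (a handful of extreme outliers, for instance, reliably trips the
SD check).

## The synthetic-conversation generator

`simulate_corpus()` builds two-channel talkspurt timelines dyad by dyad:
turn durations are log-normal (default `meanlog = log(2.2)`, `sdlog = 0.6`,
i.e. a median turn of 2.2 s); each transition event draws a type from the
cell's within/between/gap mixture; floor transfers draw an FTO from the
dyad's ex-Gaussian conditioned on the sign matching the drawn type; within
overlaps place a 200–800 ms listener talkspurt strictly inside the current
turn with 200 ms clearance on every side. All boundaries land on the
millisecond grid, which is why the extraction pipeline recovers injected
FTOs *exactly* — the round-trip identity is the module's core guarantee and
is asserted label-for-label in the tests. Dyad-level variation enters as a
Normal(0, 120 ms) shift of `mu` shared across contexts and a Normal(0, 0.3)
logit shift of the within-overlap weight.

### The reference ("paper-scale") configuration

`paper_preset()` describes a corpus of 9 autistic-autistic and 14
non-autistic dyads, three 10-minute contexts (Introduction, Tangram,
Discussion), with per-cell ex-Gaussian parameters and type mixtures chosen
as the package's reference study conditions. Per cell, `(mu, sigma, tau)`
solve three requirements in priority order:

1. `mu + tau` equals the target cell mean exactly;
2. `P(X >= 0)` equals the cell's gap share among floor transfers exactly —
   this makes the sign-conditional FTO sampling *self-consistent*, so the
   realised FTO distribution is the untruncated ex-Gaussian and empirical
   cell means converge to `mu + tau`;
3. the implied median sits as close as possible to the target cell median.

Requirements 1 and 2 pin down two of the three parameters; the remainder is
spent on 3. The implied cell SDs then fall below the target dispersions
(e.g. 644 ms where the target lists 933 ms): matching mean, SD *and* sign
share simultaneously is mathematically infeasible for an ex-Gaussian (with
mean and SD fixed, the attainable `P(X >= 0)` tops out around 0.68 against
a required 0.76). Self-consistency was kept and dispersion sacrificed,
because the package's distributional-fidelity guarantee — empirical means
converge to `mu + tau` — is what the recovery tests lean on.

Two realised-versus-nominal effects are worth knowing. First, a drawn
within-overlap is skipped when the current turn cannot host one with full
clearance (short or crowded turns), so the realised within share runs
1–2 percentage points below the nominal mixture weight. Second, dyad-level
`mu` shifts perturb each dyad's sign split slightly away from its mixture,
adding dyad-level (not transition-level) noise to realised cell means.
Recovery tests therefore judge means and mixtures against standard errors
that include the dyad-level component.

What the generator deliberately does **not** emulate: turn content,
backchannel placement preferences, speaker asymmetries (both simulated
speakers are statistically exchangeable, so speaker-balance scores
concentrate near zero rather than at empirically observed levels),
annotation errors, or any time-course dynamics within a conversation.
Passing recovery tests on this generator therefore validates the
*measurement and inference machinery*, not the behavioural realism of any
particular dataset.

## Numerical and scale choices

* Times are seconds internally (the TextGrid native unit); FTOs are
  reported in milliseconds. Intervals are half-open `[start, end)`;
  adjacency means exact boundary equality, which avoids double counting.
* Boundary classification: smooth is `|FTO| < 100`; gap `[100, 700)`; long
  gap `>= 700`; overlap `(-700, -100]`; long overlap `<= -700`.
* Medians of even-sized samples are midpoints of the central pair; the
  sample SD uses `n - 1`.
* The speaker-balance denominator is the dyad's combined speech time (not
  the wall clock), making scores comparable across contexts that differ in
  silence; the score is reported as an absolute difference in percentage
  points.
* Problem sizes in the test suite are scaled to run on one CPU: recovery
  fits use 150 s contexts at the full 9 + 14 dyad design, null-calibration
  corpora use 4 + 4 dyads in a single context, and desk-scale sampler
  settings are used throughout the suite; the study-scale corpus (three
  full 10-minute contexts, ~17,000 transitions) is exercised once in the
  acceptance workflow.

## Known limitations

* Regression structure on `mu` only: group effects expressed in `sigma` or
  `tau` are visible in posterior predictive checks but not in `delta`.
  Extending the model distributionally would require placing predictors on
  all three parameters.
* No random-effect correlations (see above).
* The extraction algorithm assumes each tier's intervals are internally
  consistent; it does not attempt to repair overlapping intervals within a
  single speaker's tier (they are rejected at validation).
* The robustness rule's 0.89 threshold and the 2% CI margin are
  conventions, not discoveries; both are parameters of `is_robust()`.
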