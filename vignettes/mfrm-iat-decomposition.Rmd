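---
title: "Decomposing IAT effects with many-facet Rasch measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing IAT effects with many-facet Rasch measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iatfacets)
```

## The measurement problem

The Implicit Association Test infers implicit attitudes from the speed of a
two-key categorization task under two associative mappings. A single summary
score (the D score) cannot say *which* associations carry an observed
preference: whether heterosexual respondents' pro-heterosexual IAT effect
reflects attributing positive words to heterosexuals, negative words to
homosexuals, or both. `iatfacets` addresses this by treating the task as a
measurement problem with several crossed facets — respondents, respondent
groups (sexual orientation), attribute stimuli, and associative conditions —
and fitting a many-facet rating-scale Rasch model to ordinal response-speed
categories.

## From latencies to ordinal categories

Raw trials pass through a fixed pipeline (`preprocess_trials()`):

1. **Respondent exclusions** (on unfiltered trials, since one criterion
   counts sub-300 ms responses): missing critical blocks, more than 10% of
   critical latencies under 300 ms, or a critical error rate above 30%.
   These emulate the usual data-reduction rules for internet-collected IAT
   sessions; all thresholds are configurable and any criterion can be
   disabled (`exclusion_criteria()`).
2. **Latency filter**: trials under 300 ms or over 10,000 ms are dropped.
   The bounds are kept — "smaller than 300" and "greater than 10,000" are
   read strictly.
3. **Aggregation**: critical-block attribute trials are averaged into one
   cell per respondent × condition × stimulus (arithmetic mean — the
   minimal-assumption aggregate; cells with no trials are recorded as
   missing, never as zeros). Error trials keep their recorded latencies and
   enter the means by default (`include_error_trials = TRUE`): the task's
   error feedback forces a correcting response within the same trial, and no
   latency penalty is applied at this stage. The flag exists because this
   convention is genuinely open.
4. **Tertile discretization**: the pooled non-missing cell means define
   global 1/3 and 2/3 cuts (linear-interpolation quantiles, type 7 — the
   convention must be pinned down for reproducibility, and this is the one
   most software defaults to). Cells at or below the lower cut are fast
   (category 3), above the upper cut slow (category 1). A mean lying exactly
   on a cut goes to the faster category; the tie-break is arbitrary but must
   be deterministic.

Order matters: filtering precedes aggregation, so a cell's mean is taken
over its surviving trials only.

## The model and its estimation

For a cell with step score $k \in \{0, 1, 2\}$ (category minus one),

$$P(k) \propto \exp\!\Big(k\,\eta - \sum_{h \le k} \tau_h\Big), \qquad
\eta = \alpha_n + \beta_g + \gamma_s + \varepsilon_c ,$$

a rating-scale model: one shared threshold vector $\tau$ for all cells,
because there is a single 3-category dependent variable. (A partial-credit
variant with per-stimulus thresholds would add parameters the discretized
data cannot support and is deliberately out of scope.)

**Identification.** The sum $\alpha_n + \beta_g$ is not separately
identified, so the engine estimates a combined respondent parameter
$\theta_n$ (free, absorbing the grand level) and decomposes it afterwards:
$\beta_g$ is the group mean of $\theta$ minus the unweighted mean of the
three group means, re-centered to mean zero, and
$\alpha_n = \theta_n - \beta_{g(n)}$. Stimuli, conditions and thresholds are
re-centered to mean zero every iteration. This makes results deterministic
and matches the reporting convention in which group, stimulus and condition
measures average to zero.

**Algorithm.** Joint maximum likelihood via alternating Newton updates of
the score equations (observed minus expected raw score per element), with
steps clipped at 1 logit for stability. Convergence requires the largest
absolute score residual to fall below 0.01 score points *and* the largest
parameter change below 0.001 logits, within 200 iterations by default
(`mfrm_control()`); non-convergence is a hard error with diagnostics, never
a silent result. Iteration order is fixed (sorted element ids), so repeated
runs are bit-identical.

**Extreme scores.** A respondent answering in the minimum or maximum
category everywhere has no finite maximum-likelihood measure. Such
respondents are removed from estimation, reported, and given an imputed
measure: the value whose expected score lies 0.3 step points inside the
extreme (configurable), with the SE flagged as extrapolated. Extreme
stimuli or conditions abort the fit — they would indicate a degenerate
design rather than an outlying individual. Estimation proceeds as long as
every category occurs somewhere in the pooled data; otherwise the fit stops
with advice to collapse categories.

**Uncertainty and diagnostics.** Standard errors come from the Rasch
information, $SE = 1/\sqrt{\sum W}$ with $W$ the model variance of the
cell's step score. Per element, outfit is the unweighted mean square of
standardized residuals and infit the information-weighted one; both have
expectation 1 under fit. Per facet, the separation reliability
$R = \max(0, 1 - \overline{SE^2}/\mathrm{var}(\text{measures}))$ (sample
variance, $n-1$) and the fixed all-same chi-square
$\chi^2 = \sum w m^2 - (\sum w m)^2/\sum w$, $w = 1/SE^2$, $df = L-1$.
These formulas are documented and oracle-tested here; they are not claimed
bit-identical to every convention in legacy facet-analysis software, whose
small variance-weighting choices are not published in full.

## Interaction (bias) analysis

The contrast layer is deliberately **two-pass**: the main fit is frozen and
each interaction cell (condition × group, or stimulus × condition × group)
receives a single offset $\delta$ solved by Newton iteration from its own
score equation, $\delta \leftarrow \delta + \sum(x - E)/\sum W$, to a
$10^{-4}$ score-residual tolerance, with $SE = 1/\sqrt{\sum W}$. A joint
refit would redistribute the main effects and change their interpretation;
the two-pass design keeps "measure" and "bias" separable, at a price worth
stating: part of a true localized interaction is absorbed by the main
effects (in the validation simulations, roughly 0.1 of an injected 0.5-logit
stimulus bias), so bias estimates are mildly conservative. Cells whose
observations are all-minimum or all-maximum get no finite $\delta$ and are
flagged out of the t tests.

Downstream reports:

* **IAT effect**: $\Delta = \varepsilon_1 - \varepsilon_2$ (condition 1 =
  `HEG_HOB`, so positive means heterosexuals-with-good was easier),
  $SE = \sqrt{SE_1^2 + SE_2^2}$, normal z test (matching the usual z
  reporting for these contrasts). Group effects shift $\Delta$ by the
  condition × group biases. Two effects are compared by a normal z on the
  difference, optionally of absolute values — the right scale when two
  groups prefer opposite targets and only the strength is at issue.
* **DSF table**: per stimulus and group, condition-specific measures
  $M_c = \gamma_s + \delta_{(s,c,g)}$, $t = (M_1 - M_2)/\sqrt{SE_1^2+SE_2^2}$,
  $df = n_1 + n_2 - 2$ (the convention consistent with complete-cell row
  maxima), Cohen's $d = 2|t|/\sqrt{df}$ reported unsigned, two-sided t-
  distribution markers at 0.05 / 0.01, rows sorted by t within group. No
  multiplicity correction is applied across the 45 tests, mirroring standard
  practice for this descriptive table.

## The D₂ cross-check

`dscore()` implements the conventional D₂ variant: latencies above 10,000 ms
deleted; error trials kept with their recorded latencies (no penalty);
sub-300 ms latencies retained in scoring but a respondent whose critical
trials are more than 10% anticipatory is flagged; within each block pair the
condition mean difference is divided by the combined two-block SD ($n-1$),
and D is the mean of the two pair values. Blocks pair by rank within
condition, so counterbalanced orders are handled by condition labels, not
block indices. An optional switch deletes trials under 400 ms (off by
default — descriptions of this sub-variant differ, so it is exposed rather
than hard-coded). D is scale-free in latency units, which is the property
the tests assert.

## The synthetic-data generator

`sim_config()` emulates the study design the package targets: a 7-block
online Sexuality-IAT session — three practice blocks, four critical blocks
(two per mapping, order alternating with respondent index), 7 positive and
8 negative attribute words (the task's actual word lists), target-image
trials included in critical blocks and discarded by preprocessing. Defaults
mirror the emulated study: 689/47/53 respondents and group IAT effects of
1.08 / −0.20 / 0.29 logits for heterosexual/gay/bisexual groups;
`trials_per_cell = 4` (the task yields a handful of trials per stimulus and
mapping); `sd_alpha = 1` and `sd_gamma = 0.2` logits, chosen so the
simulated respondent and stimulus measure ranges match those typically seen
in such analyses (respondents spanning roughly ±3 logits, stimuli ±0.4);
thresholds $\tau = (-0.5, 0.5)$.

Latencies follow a lognormal response model,
$\log L = \mu_0 - c\,\eta + \mathcal N(0, \sigma^2)$ per trial, with
$\mu_0 = \log 700$ ms and $\sigma = 0.35$ — a realistic IAT latency scale
and trial-level noise. The base process is truncated to the task's valid
300–10,000 ms range; out-of-range latencies (and error flags) are injected
only through the configurable contamination fractions (defaults 1% fast,
0.5% slow, 5% errors). The slope is **calibrated**: $c = 0.142$ log-ms per
logit makes the full pipeline (latencies → filtering → tertiles → JMLE)
recover one latent logit as approximately one estimated logit under the
default acquisition noise, so that true effect sizes are directly
comparable with recovered ones. The calibration is part of the generator's
design, performed once on its own seed batches.

What the generator does **not** emulate: practice effects and block-order
drift, sequential trial dependencies, respondent-specific effect
heterogeneity beyond the group structure, slower error latencies, and the
self-selection of online samples. Passing recovery tests therefore show
that the estimation machinery is correct under the stated response model —
not that real IAT data satisfy that model.

## Validation experiments and problem sizes

The test suite validates the pipeline at sizes chosen to be informative yet
routine on a single CPU:

* **Oracle agreement**: on a 4-respondent × 2-condition × 3-stimulus
  instance, JMLE matches a brute-force BFGS maximization of the same joint
  likelihood within 0.01 logits on every parameter.
* **Recovery**: 20 seeded end-to-end replications at 200 respondents per
  group, 15 stimuli, 4 trials per cell, true group effects 1.0 / −0.2 /
  0.3; at least 95% of the 60 group-level estimates land within 3 estimated
  SEs of truth, and the heterosexual-vs-bisexual contrast is detected in
  ≥95% of runs.
* **Calibration**: under model-true categorical data the mean element infit
  and outfit lie in [0.9, 1.1]; under a null latency process ($c = 0$,
  30 respondents per group) the overall Δ z test rejects at the nominal 5%
  level within binomial tolerance over 100 replications.
* **Bias recovery**: a +0.5-logit stimulus × group × condition injection is
  recovered within 3 SE at 100 respondents per group, in a design with
  equal group effects so the interaction cells carry no differential
  condition functioning besides the injection.
* **Cross-method agreement**: D₂ group means carry the same signs as the
  model-based group effects.

## Known limitations

* JMLE carries the usual finite-length bias (slight outward stretch of
  measures); no correction is applied, matching standard facet-analysis
  practice. The generator calibration absorbs it for the emulated design.
* Bias estimates are mildly conservative under the two-pass scheme (see
  above).
* The rating-scale form, the mean aggregation per cell, and the inclusion
  of error-trial latencies are documented conventions, not empirical
  findings; all three have configuration switches or clearly marked
  extension points.
* With very small groups, group measures and their chi-squares rest on few
  respondents; `group_iat_effects()` refuses groups of fewer than two.
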