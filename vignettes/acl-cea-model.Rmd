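---
title: "Model and methods: ACL reconstruction versus conservative treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: ACL reconstruction versus conservative treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aclcea)
```

## The decision problem

Rupture of the anterior cruciate ligament can be treated by surgical
reconstruction or conservatively (immobilization and physiotherapy). This
package implements a cohort decision-tree model comparing the two
strategies from a third-party-payer perspective over a 90-month horizon.
Outcome is measured on the Gottlob activity scale — ordinal classes from I
(symptomatic activities of daily living) to V (unrestricted high-demand
sport) — mapped to health-state utilities on [0,1] and reported, following
the convention of the source analysis this model re-implements, as QALYs
without time-weighting or discounting: the "effect" of a strategy is its
expected utility at the horizon.

## Model structure and assumptions

Each strategy is a chance tree rolled back to an expected (cost, effect)
pair (`build_strategy_tree()`, `rollback()`).

**Reconstruction.** Base cost is the surgical profile total (9,926 USD)
plus a residual constant (below). With probability 0.035 the
reconstruction fails and is redone once (one extra surgical cost; the
patient's activity distribution shifts one class down, class I acting as an
absorbing floor). With probability 0.34 a late sequela occurs: 86%
osteoarthritis (knee prosthesis, 14,826 USD inpatient + 2,535 USD
perioperative = 17,361 USD) and 14% meniscal lesion (3,847 + 2,535 = 6,382
USD); sequelae patients are assigned activity class II regardless of their
prior class. Failure and sequelae are treated as *independent* events —
the original publication does not state the nesting, and independence is
the minimal structural assumption; whatever finer structure the original
software model contained is absorbed by the residual constants.

**Conservative.** Base cost 2,535 USD plus its residual. With probability
0.16 the patient crosses over to surgery; only the cost treatment of
crossover is published (one average surgical cost is added), so crossover
patients *keep the conservative activity distribution* for effect — an
open modelling choice we resolve conservatively (pun intended): granting
crossover patients the operative distribution would only strengthen the
case for early reconstruction. Sequelae occur with probability 0.77, split
74/26 between osteoarthritis and meniscus.

**Evidence pooling.** Arm-specific activity distributions come from
pooling study-level class counts: proportions are summed counts over
summed sample sizes (`pool_activity()`), a fixed-effect pooling with no
heterogeneity modelling. Fractional counts (half-patients in published
tables) are accepted as-is. Summary age and follow-up use sample-size
weighting (`weighted_mean()`); note that the published pooled age (28/27
years) and follow-up (89/90 months) of the four-study table are *not*
reproducible as sample-size-weighted means of the printed row values
(operative follow-up computes to 104.6 months, age to 29.1 years); we
implement the stated weighting and leave the discrepancy visible rather
than reverse-engineer an unknown rule.

## Calibration: the two openly-parameterized gaps

Two published quantities cannot be derived from published inputs alone;
both gaps are closed by explicit constants stored in the shipped config
(`inst/extdata/baseline_config.json`) with notes, and both can be switched
off.

**Residual costs.** A literal rollback of the tree above gives expected
costs of 15,653.55 (reconstruction) and 15,293.13 USD (conservative); the
published analysis reports 16,038 and 15,466. The ~2% per-arm gap reflects
micro-structure of the original proprietary tree that was never published.
We add per-arm constants — 384.4504 and 172.8658 USD, the exact
differences — so the baseline reproduces the published costs, and the test
suite asserts *both* behaviours (calibrated and literal). Setting
`residual_cost_*` to 0 recovers the literal model.

**Utility key.** The per-class utilities come from an expert survey
published separately and are not printed. `fit_utilities()` calibrates
monotone, bounded per-class means so that the model's arm-level expected
effects hit the published targets (arm cost divided by arm
cost-effectiveness ratio: 16,038/20,612 = 0.77809 and 15,466/23,391 =
0.66119). With 2 targets and 5 unknowns the problem is underdetermined; a
softmax-increment parameterization guarantees monotonicity and bounds
exactly, and a small penalty (weight 1e-6) pulls the class increments
toward equal spacing to select a unique representative. Exactly equal
spacing is infeasible: it would require a class-V utility of 1.03. The
achieved squared target deviation is ~4e-13. The resulting key (0.321,
0.626, 0.807, 0.929, 0.972) is honest plumbing — a key consistent with
the published aggregates — not a claim of recovering the survey's values.

```{r key}
attr(fit_utilities(effect_targets(16038/20612, 15466/23391),
                   config_model_params(baseline_config())), "fit")
```

## Probabilistic sensitivity analysis

Only utilities are sampled (the published analysis varied utility values
only): per iteration, each class utility is drawn from an independent
normal with the key's mean and SD, truncated to [0,1] by resampling
(rejection capped at 1,000 tries). Draws are shared between strategies
within an iteration (both arms use the same transformation key) and are
reproducible from `(seed, iteration)` alone. Because rollback is linear in
the class utilities, the production path evaluates draws through per-class
effect weights extracted from the trees themselves; a test proves this
identical to rebuilding and rolling back the tree for individual draws.
Default: 10,000 iterations; WTP grid 0–100,000 USD/QALY in 1,000-USD
steps; ties broken toward the cheaper strategy.

**Per-class SDs** are not publicly available and are package defaults, not
elicited values: sd = 0.10, capped at (1 − mean)/3.5 so that the [0,1]
ceiling stays at least 3.5σ away from every class mean (giving 0.10, 0.10,
0.055, 0.020, 0.008 for I–V). The cap is what makes the "normal
distribution truncated to [0,1]" specification internally consistent: with
a ceiling closer than ~1σ, truncation would shift sampled means
materially and the PSA mean would no longer estimate the deterministic
effect. An earlier draft default (sd 0.03 for class V, ceiling at 0.95σ)
failed exactly that internal-consistency check and was replaced by the
rule above. Consequently the published PSA dispersions (±0.07/±0.13
utility) are *not* reproduced or asserted — they require the unpublished
survey SDs.

## Synthetic data: what it emulates and what it does not

`generate_studies()` emulates multi-study evidence tables: per study and
arm, a uniform sample size, multinomial class counts, uniform age and
follow-up, and (with probability 0.2) a half-patient split between
adjacent classes to exercise the fractional-count path.
`generate_utility_survey()` emulates an expert elicitation (default 25
experts) with truncated-normal draws; `generate_cost_items()` produces
line items summing exactly to requested totals by uniform stick-breaking.
These generators share the real data's *statistical shape* (multinomial
sampling noise, truncation, exact additivity) but none of its biology: no
correlation between age/follow-up and outcomes, no study heterogeneity
beyond multinomial noise, no selection bias between arms. A green
parameter-recovery test therefore establishes that the pipeline is
self-consistent — pooling, tree evaluation and incremental analysis invert
the generator — not that the published evidence base is unbiased.

The end-to-end recovery test uses a deliberately well-separated synthetic
world (operative mass concentrated on class V, conservative on class I,
small sequelae probabilities) so the incremental effect is large (~0.5)
and the multinomial sampling error of the ICER at 10,000 pooled patients
is ~0.4%, inside the 1% acceptance band by design rather than seed luck.

## Numerical choices

- Costs are carried as doubles in USD and rounded to whole USD only in
  formatted reports; proportions and ICERs are never rounded internally
  (the published ICER of 4,890 is itself only obtainable from unrounded
  internals — the rounded table entries would give 572/0.12 = 4,767).
- Chance-node probabilities must sum to 1 within 1e-9; distribution
  invariants use the same tolerance; validation returns a structured
  report listing every violating node rather than failing fast.
- Children are evaluated in declaration order, and all Monte Carlo streams
  derive from explicit `(seed, iteration)` mixing below 2^31, so every
  result is bit-reproducible.
- Dominance handling: strategies costlier and no more effective than
  another are flagged `dominated`; extended dominance prunes frontier
  members that break ICER monotonicity along the chain. Zero incremental
  effect yields an `NA` ICER (undefined), never an error.
- CHF→USD conversion divides by the stated factor 1.15. (One published
  CHF/USD pair, 8,673 CHF as 7,536 USD, is inconsistent with that factor —
  7,541.74 — and is treated as report context, not a model input.)

## Known limitations

- Single-period tree: no Markov cycling, no discounting, no
  patient-level simulation; effects are horizon-average utilities.
- The calibrated utility key and residual costs are identifiable only up
  to the published aggregates; scenario results that depend on the full
  utility vector (e.g. the exact worst-case ICER) are reported, not
  asserted — the test suite asserts the published ≥10-fold inflation
  property, and the shipped configuration yields ~16.8-fold.
- Costs are Swiss tariffs converted at a fixed 2010 exchange rate;
  indirect and societal costs are out of scope by design.
- PSA covers utility uncertainty only; probabilities and costs are fixed,
  so the acceptability curve understates total decision uncertainty.
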