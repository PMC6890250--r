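---
title: "Combined self-report and RULA health-risk assessment for MSDs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined self-report and RULA health-risk assessment for MSDs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdrisk)
```

## The screening problem

Work-related musculoskeletal disorders (MSDs) in repetitive industrial work
are usually screened with one of two instrument families: subjective
self-report questionnaires (how often and how badly does it hurt?), or
objective observational posture scores such as the Rapid Upper Limb
Assessment (RULA). The two disagree systematically — workers in highly
repetitive jobs often under-report symptoms relative to their observed
postural exposure — so a screening programme that relies on either one
alone will either miss exposed-but-asymptomatic workers or flag symptomatic
workers whose exposure is already controlled.

`msdrisk` implements a combined health-risk assessment (HRA): a 5 × 4
likelihood-by-severity risk matrix whose rows are the worker's self-reported
discomfort level for one body region and whose columns are the worker's
whole-body RULA ergonomics-risk level. Cohorts are summarised as per-level
count/percentage prevalence tables for each of four body regions (neck,
upper limbs, trunk, lower limbs).

## The three scoring stages

### 1. Self-report discomfort

For each body region the questionnaire yields a pain **frequency rank**
`f ∈ {1, 2, 3, 4}` (1–2 times/week, 3–4 times/week, once daily, several
times daily) and a pain **severity rank** `s ∈ {0, 1, 2, 3, 4}` (no pain,
mild, moderate, severe, very severe). The discomfort score is the product

$$D = f \times s \in \{0\} \cup \{1, \dots, 16\},$$

binned into five levels: 0 (no discomfort, score 0), 1 (mild, 1–2),
2 (moderate, 3–4), 3 (severe, 5–8), 4 (very severe, 9–16). Two modelling
choices deserve a note:

* **Product, not sum.** A sum of the two ranks tops out at 8 and cannot
  fill the instrument's 0–16 score range; the multiplicative form is the
  standard likelihood × severity construction and is the one the score
  range implies. `score_discomfort()` implements the product.
* **Severity 0 dominates.** When a worker reports no pain, the frequency
  item is typically left blank; the score is forced to 0 and a blank
  frequency is accepted (`NA`), so "no pain" rows parse cleanly.

### 2. RULA

`assess_rula()` runs the standard RULA worksheet: Table A maps the four
arm/wrist posture codes (upper arm 1–6, lower arm 1–3, wrist 1–4, wrist
twist 1–2) to posture score A; Table B maps neck (1–6), trunk (1–6) and
legs (1–2) to posture score B; each group's muscle-use (0/1, static or
repetitive) and force/load (0–3) increments are added to give scores C and
D; and Table C combines them into the grand score 1–7 (inputs of 8 or more
capped at 8). The three tables ship as long-format CSV fixtures transcribed
cell-by-cell from the published worksheet, so the transcription is
auditable; tests pin their dimensions, value ranges, axis monotonicity and
per-table checksums. Posture-code adjustments (shoulder raised, arm
abducted, wrist deviated…) are the observer's responsibility and are
assumed already folded into the codes, since screening datasets record only
final codes or levels.

Two level-binning schemes are exposed via `bin_rula()`:

* `"action_levels"` (default): the standard RULA action levels — grand
  score 1–2 → level 1, 3–4 → 2, 5–6 → 3, 7 → 4. This is the only mapping
  under which level 4 ("correct immediately") is reachable, and therefore
  the only one consistent with field reports of large very-high-risk
  shares in repetitive work.
* `"survey_bins"`: some survey instruments print the discomfort-score
  bands (1–2, 3–4, 5–8, 9–16) for the RULA column as well. Under these
  bands grand scores 5–7 are all level 3 and level 4 is unreachable; the
  scheme is provided verbatim for fidelity to instruments typeset that
  way, not as a recommended analysis choice.

Because screening studies often report only the final RULA outcome,
cohorts may supply the 11 posture-code columns, a precomputed grand score
(`rula_grand`), or a precomputed level (`rula_level`); resolution is per
worker in that order of precedence.

### 3. The combined risk matrix

With discomfort level $d \in 0..4$ and RULA level $r \in 1..4$, the matrix
score is the product $M = d \times r$, binned by `bin_hra()` into
acceptable (0), low (1–2), moderate (3–4), high (5–8) and very high (9–16)
risk:

```{r}
hra_matrix()
```

The zero-discomfort row carries a footnoted **override**: a worker who
reports no discomfort but whose posture is rated high (RULA 3) or very
high (RULA 4) is placed at low rather than acceptable risk (scores 1 and
2), so that high observed exposure is never entirely masked by the absence
of symptoms. The override is on by default and can be disabled
(`override = FALSE`), because screening reports exist whose acceptable-risk
column exactly equals the no-discomfort column — arithmetic only possible
with the override off. The choice is deliberately immaterial above the
screening threshold: the override only moves workers between the
acceptable and low bands, so every moderate-or-above quantity is identical
under both settings (this invariance is property-tested).

Two numerical edge cases are handled for API totality and documented here:
a matrix score of 5 cannot arise as a product of the level ranges but is
accepted and binned to level 3 (the band of its neighbours), and the
survey-style RULA bins above 7 are unreachable.

## Cohort summarisation

`classify_cohort()` applies the three stages to every worker, pairing the
worker's single whole-body RULA level with each of the four regional
discomfort levels (screening instruments of this design record one RULA
outcome per worker, not one per region; a per-region RULA is out of
scope). `summarize_cohort()` produces the three standard report tables —
RULA levels, discomfort levels per region, HRA levels per region — as
counts with percentages computed as $100\,c/n$ and rounded **half-up** to
two decimals, the rounding used in the survey-report tables this package
reproduces (base R's `round()` rounds half to even, which disagrees on
boundary values). `moderate_or_above()` returns the conventional screening
headline, the share of workers at level 2 or above. Optional descriptives
(mean/SD, median, min–max of age and tenure) are included when the columns
are present, and summaries can be stratified with `by = "department"`.

## The synthetic cohort generator

Real per-worker screening data of this kind are rarely published; what is
published are the categorical marginals. `generate_cohort()` therefore
draws cohorts from a specified set of marginals, and
`default_cohort_spec()` encodes the reference workforce the package
emulates — a 107-worker potato-chip processing cohort:

* departments: cool room 17, process 11, packing 71, warehouse 8 (of 107);
* RULA levels 1–4 with probabilities (0, 3, 21, 83)/107;
* per-region severity marginals, e.g. trunk (59, 36, 9, 2, 1)/107 from
  no-pain through very severe;
* frequency ranks uniform on 1–4 — frequency conditional on pain is not
  published for the reference workforce, and severity dominates the level
  binning (severity 0 forces level 0, and at low frequencies the product
  stays in the severity's own band);
* association 0 (independence) between discomfort and RULA level.

The construction is a one-factor Gaussian copula: one latent standard
normal per worker drives the RULA level through the inverse CDF of its
marginal, and each region's severity uses a latent normal correlated with
it at the `association` parameter. This keeps every marginal exact in
distribution for any association, makes `association = 0` exact
independence, and preserves the sign of the rank correlation — which is
all that can be said, since the true discomfort–RULA joint distribution is
unpublished. The `association` knob exists precisely to study how the
combined table depends on that unknown; fitting it to reproduce any
particular published joint table is deliberately not attempted
(under-determined). A single integer seed fully determines the cohort and
the caller's RNG state is never touched.

Demographics (76% female, age uniform on 21–43 years, tenure 6 months plus
a gamma with shape 2 and overall mean 20.6 months) mimic the reference
workforce's descriptives and feed only the descriptive-statistics block.

**What passing tests do and do not show.** The generator reproduces
categorical marginals and a rank-coupling; it does not emulate
department-specific posture profiles, within-worker correlation across
body regions (regions are conditionally independent given the latent
factor), measurement error in posture coding, or non-response. Tests that
pass on synthetic cohorts therefore validate the scoring arithmetic and
the summarisation, not any claim about real-world joint structure. One
consequence worth stating: with uniform frequency ranks, nonzero-severity
workers spread across discomfort levels 1–3 rather than landing in their
severity's own band, so generated *discomfort-level* marginals match the
reference tables exactly only in the no-discomfort column; recovery tests
compare empirical marginals against the *generating* parameters
(`recover_marginals()`), which is the well-posed check.

## Numerical and testing choices

* Half-up rounding uses a `1e-9` offset before `floor()` to neutralise
  binary representation of decimal boundary values.
* Chi-square goodness-of-fit checks of the generator run at n = 10,000
  across 20 seeds at α = 0.01, dropping zero-probability categories; with
  100 tests the expected chance rejection count is one, so the suite
  asserts at most five rejections rather than zero.
* The large-sample convergence check uses n = 50,000, where the binomial
  3σ band around a 77.57% share is ±0.56 points.
* These problem sizes keep the full suite under a few seconds while
  leaving the stochastic assertions with comfortable power.

## Known limitations

* Single whole-body RULA level per worker; no per-region posture scoring,
  no REBA/OCRA/Strain-Index engines, no multi-task time-weighted exposure
  aggregation.
* The questionnaire model assumes the past-month recall framing and
  performs no psychometric validation.
* Interior acceptable/low cells of a combined table cannot be recovered
  from published marginals alone (they depend on the unpublished joint and
  on the override convention); only override-invariant moderate-or-above
  quantities are treated as reproducible reference values.
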