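---
title: "Methods: normalized ciliation, control-derived thresholds, and the two-round automaton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalized ciliation, control-derived thresholds, and the two-round automaton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliascreen)
```

## The assay and its model

An arrayed RNAi ciliation screen measures, per experiment and per reagent,
two integers: the number of cells bearing an acetylated-tubulin-positive
primary cilium and the number of DAPI-positive cells examined (protocol
target: at least 150 cells per condition, at least 5 independent
experiments). The statistical model behind every stage of this package is
correspondingly simple:

* within an experiment, cells are independent, so a condition's ciliated
  count is Binomial(total cells, p);
* the baseline ciliation probability drifts between experiments (culture
  age, confluence, staining batch) around roughly 55% with a few percent of
  spread — which is why every condition is normalized to the *same-experiment*
  scrambled control before anything is averaged;
* knocking down a gene multiplies the ciliation probability by an effect
  factor (1 = no effect, 0.25 = strong loss, >1 = gain), and the realized
  effect tracks how much transcript the duplex actually removed.

Normalization takes the per-experiment ratio first and then the unweighted
mean across experiments. Unweighted (rather than cell-count-weighted)
averaging treats experiments, not cells, as the unit of replication, which
matches how the counting protocol is replicated and makes the reported SEM
an honest between-experiment quantity. Experiments missing either the
condition or the control observation are excluded and logged; a control at
exactly zero ciliation is excluded the same way (the ratio is undefined and
a zero control indicates a failed experiment, not an infinite effect).

When more than one scrambled duplex is present, the per-experiment control
reference is the mean over the scrambled observations of that experiment,
and each scrambled duplex's own ratios (scattered tightly around 1) supply
the negative-control dispersion. At least two scrambled duplexes are
therefore required for calibration: a single scrambled normalized against
itself is identically 1 with zero variance, which the calibrator rejects as
degenerate rather than silently producing a zero-width threshold band.

## Thresholds

The loss threshold is *anchored*, not estimated: the normalized ciliation of
a positive-control reagent with a known moderate effect (PCM1-level
depletion, about 0.65x control) becomes the cutoff, but only after passing a
conservatism check — it must lie at least `k_sd = 4` pooled standard
deviations below the negative-control mean. If the anchor fails that check
the calibrator falls back to `neg_mean − k_sd · neg_sd` and says so in the
QC log; analyses never proceed on an unvalidated anchor silently.

Two choices here were genuinely open and are worth recording:

* **Which values feed the SD.** We pool the per-experiment normalized values
  of all scrambled duplexes, rather than per-duplex means. Pooling uses all
  the information the controls carry about experiment-to-experiment noise;
  the per-duplex-mean alternative can be obtained by calling
  `calibrate_thresholds()` with those means directly.
* **The gain side.** The screen design requires only "a significant
  increase" for the gain arm without fixing a rule; we mirror the
  control-derived rule symmetrically (`neg_mean + k_sd · neg_sd`). It is a
  configurable default, not a claim about the original analysis.

The threshold applies to the cross-experiment mean, and a mean exactly *at*
a threshold counts as crossing it — the tie rule that makes the anchor
duplex score positive against its own threshold.

## Knockdown concordance and the automaton

A duplex is *effective* only if its phenotype crosses a threshold **and**
its knockdown is confirmed. Knockdown comes in three dialects:

* `CT`: textbook single-reference 2^(−ΔΔCt) with the linked scrambled
  control's mean ΔCt as calibrator (per-replicate relative quantities are
  summarized). The original instrument software's normalization is not
  documented beyond "standardized and normalized", so the textbook method is
  implemented because it is oracle-checkable; a pass-through mode exists
  precisely so that precomputed "% RNA remaining" values reproduce published
  endpoints regardless of dialect.
* `PERCENT_REMAINING`: precomputed percent-remaining replicates, percent
  scale in files, fractions internally.
* `ACTIVITY`: a binary flag for miRNA mimics, which raise rather than lower
  their target, so "fraction remaining" is meaningless for them.

The knockdown cutoff (≤ 60% of transcript remaining) is explicitly a
tunable: no published value defines "knocked down", and the default is
chosen so that clearly effective duplexes (20–50% remaining) pass with
margin while clearly inactive ones (80–110%) fail.

Gene-level decisions are a small automaton, exhaustively tested against a
hand-written 36-row truth table: both round-1 duplexes effective in the same
direction is a hit; exactly one effective *and* the silent duplex also
failing to knock down is a "split" carried to round 2 (the phenotype's
absence is explained by the reagent's failure, so the gene deserves a
retest); everything else — including a silent duplex that *did* knock down,
opposite-direction effective duplexes, and any phenotype-positive duplex
with unmeasured knockdown — is negative, with the firing rule recorded in a
rationale string. Round 2 requires both fresh duplexes effective in the
pending direction. Genes probed by more than two round-1 duplexes use a
documented generalization (≥ 2 effective, one direction, no discordant
silent-but-knocked-down duplex) with no split rescue.

## Cilium length

Gain-arm reagents are compared to the scrambled control with the classic
pooled-variance unpaired two-tailed Student's t-test (n₁ + n₂ − 2 degrees of
freedom), each measured cilium one observation — matching how published
sample sizes (e.g. 45 control vs 43 condition cilia) are printed. Welch's
form is available behind a flag. Degenerate inputs are defined exactly:
zero pooled variance with equal means is t = 0, p = 1; with unequal means it
is an error. The implementation is hand-rolled and verified against
`stats::t.test` to 1e-10 on random fixtures, so the two routes stay
independent.

## The synthetic-data generator

`simulation_config()` states the world the pipeline assumes: 5 experiments,
160 cells per condition, baseline ciliation Normal(0.55, 0.05) truncated to
(0, 1) between experiments, binomial counting within experiments, active
duplexes leaving Uniform(0.2, 0.5) of transcript and silent ones
Uniform(0.8, 1.1), and a linear dose–response that reaches the full effect
once ≤ 40% of transcript remains (step and Hill links are options). qPCR
replicates get multiplicative log-normal noise (sd 0.1). Positive controls
realize their nominal factors (0.25 strong, 0.65 anchor) directly — they
model pre-validated reagents whose role is calibration, not discovery.
Control cilium lengths are Gamma with mean 2.4 µm and SD 0.35 µm; the
gain-arm default shifts the mean by +1.4 µm (four pooled SDs), the stated
default world for the power property at the printed sample sizes. A single
seeded generator with documented draw order makes equal seeds produce
byte-identical files.

What the generator does **not** emulate: transfection-efficiency
heterogeneity, field-level clustering of cells, plate-position effects,
off-target (seed-sequence) phenotypes, and any between-experiment variance
component specific to non-control reagents beyond what the shared baseline
induces. A green operating-characteristics test therefore establishes that
the *decision logic* has the claimed error rates under the stated sampling
model — not that a real screen, with its unmodeled artifacts, achieves them.

`evaluate_design()` runs simulate → pipeline repeatedly and reports
per-class hit rates with binomial standard errors, plus bias/RMSE of the
normalized-effect estimator against the *realized* per-duplex effect (the
nominal factor pushed through the sampled knockdown's dose–response — the
quantity the ratio estimator is actually consistent for; both values are in
`ground_truth.csv`).

## The packaged fixture

No raw per-condition counts were ever published for the screen this package
reconstructs; only gene-level hit lists, split annotations and figure-level
qualitative outcomes are printed. `inst/extdata/paper_outcomes.csv` encodes
one qualitative pattern per gene (41 candidates across three categories) and
`screen_from_outcomes()` expands each pattern into deterministic, noise-free
counts — loss duplexes at 0.30x control, gains at 1.30x, silent at 1.00x,
failed round-2 duplexes at 0.85x (above the anchor threshold) — so that the
full numeric pipeline, not a shortcut, reproduces the published decisions.
Three reconstruction choices are documented rather than resolved:

* the published gene arithmetic (5 + 18 + 19 candidates) exceeds the
  published total of 41, and the printed tables name fewer rare-variant
  genes than the text counts; the fixture carries 41 candidates
  (5 + 16 + 20) reproducing every named hit and all printed totals;
* the text names one rare-variant hit (CHD4) whose table row reads CHD3;
  the fixture follows the text and keeps CHD3 as a tested negative;
* the text says two rare-variant hits were decided in round 2 without naming
  them; the fixture assigns CHD7 and TBX1 arbitrarily (gene-level outcomes
  are unaffected).

## Numerical and interface choices

* Percentages are fractions in [0, 1] internally, percent in files and
  reports.
* Gene symbols match case-insensitively and display case-preservingly
  (published tables are inconsistent about case).
* The gene `category` column accepts the four canonical labels plus
  simulator class labels; keeping it open lets operating-characteristics
  tallies stratify by simulated class without a parallel column.
* The minimum-cells rule (150) is a QC warning, not an error: it is a
  protocol target, and discarding an otherwise valid count would be a
  silent data drop.
* Results serialize to JSON at full printed precision; the decision set
  round-trips exactly, numeric effects to ~15 significant digits.

## Known limitations

No plate-effect correction (B-score/median polish) — the modeled design is
single-vessel. No multiple-testing correction across genes: the design's
error control is threshold-plus-replication, and its realized false-positive
rate is what `evaluate_design()` measures. No image analysis: counts and
lengths enter as numbers. The fixture is a constrained reconstruction, and
per-duplex published bar heights are figure-only; nothing in the test suite
asserts them.
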