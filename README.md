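# ciliascreen

Hit calling for arrayed RNAi screens that score formation of the **primary
cilium** — the solitary microtubule-based sensory organelle projecting from
most vertebrate cell types. In this assay design, candidate genes (for
example, broadly expressed neuropsychiatric risk genes) are silenced in
cultured fibroblasts with independent siRNA duplexes, cilia are counted by
acetylated-tubulin immunofluorescence over DAPI-stained nuclei, and a gene is
scored as a hit only when its ciliation phenotype is reproduced by multiple
duplexes *and* tracks the degree of knockdown measured by qRT-PCR.

The package is for screen analysts who have count-level data (ciliated
cells / total cells per condition per experiment) and want reproducible,
auditable gene-level calls — plus a simulator to study the design's operating
characteristics before committing to it.

## The statistic and the decision rule

For condition *c* in experiment *e*, percent ciliation is
`p(c,e) = ciliated(c,e) / total(c,e)`. Each condition is normalized to the
same-experiment scrambled (non-silencing) control,

```
r(c,e) = p(c,e) / p(scrambled, e),
```

and the unweighted mean of `r(c,e)` across experiments (n = 5 by default) is
the duplex's **normalized percent ciliation** (1.0 = control level).

Thresholds are control-derived: with `m` and `s` the mean and SD of the
pooled per-experiment normalized values of all scrambled duplexes, the loss
cutoff is anchored at the normalized ciliation of a positive control of known
moderate effect (PCM1-level depletion, ~0.65x control), accepted only if it
lies below `m − 4s`; the gain cutoff mirrors it at `m + 4s`. A duplex is
*effective* when it crosses a cutoff **and** knocks down its target
(mean fraction of transcript remaining ≤ 0.60 by default, or an activity
flag for miRNA mimics).

Gene calls follow a two-round automaton:

* both round-1 duplexes effective in the same direction → **hit**;
* exactly one effective and the silent duplex also failed to knock down
  ("split") → retest with two fresh duplexes in round 2; both must confirm;
* every other outcome → **negative**.

Gain-arm hits are additionally tested for increased cilium length with a
pooled-variance two-tailed Student's t-test (each measured cilium one
observation).

## Worked example

The package ships a 41-gene fixture reconstructing the qualitative
per-duplex outcomes of a published two-round ciliation screen
(`inst/extdata/paper_outcomes.csv`; see the vignette for its provenance and
limits). Expanding it to a full numeric screen and running the pipeline:

```r
library(ciliascreen)
screen <- screen_from_outcomes(paper_outcomes())
res <- call_screen(screen)
res
#> <screen_calls> 41 genes: 20 HIT_LOSS, 3 HIT_GAIN, 0 pending, 18 negative
#> <threshold_set> loss <= 0.6523, gain >= 1.0802 (k = 4 SD)
#>   negative controls: mean 1.0000, sd 0.0200 (n = 10 per-experiment values)
#>   anchor 0.6523, validated against the 4-SD bound
```

20 genes reduce ciliation and 3 increase it; the loss threshold sits at the
anchor's normalized ciliation (0.6523), which clears the 4-SD
negative-control bound (1 − 4·0.020 ≈ 0.92), so the anchor is accepted. The
round-2 logic is visible per gene:

```r
res$decisions[res$decisions$gene %in% c("SYNE1", "CEP170"),
              c("gene", "status", "decided_in_round")]
#>      gene   status decided_in_round
#>    CEP170 NEGATIVE                2
#>     SYNE1 HIT_LOSS                2
```

Both genes split in round 1; SYNE1's fresh duplexes confirmed the loss,
CEP170's did not. Length testing of the gain arm:

```r
lengths_report(screen)[1, c("reagent_id", "n_condition", "n_control",
                            "mean_condition", "mean_control", "p_value")]
#>   reagent_id n_condition n_control mean_condition mean_control     p_value
#> 1 siCCDC18-1          43        45            3.2          2.4 5.22758e-17
```

Simulating screens and measuring the design's error rates:

```r
cfg <- simulation_config(n_genes = c(NULL_EFFECT = 4L, STRONG_LOSS = 4L),
                         simulate_lengths = FALSE, seed = 11)
evaluate_design(cfg, n_replicate_screens = 50)$by_class
```

reports per-class hit rates with binomial standard errors (null genes are
essentially never called; strong-loss genes are called at ~100%).

A command-line wrapper lives at `inst/cli/ciliascreen.R`
(`call` / `simulate` / `evaluate` / `lengths` subcommands, YAML config).

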