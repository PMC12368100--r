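# trnacharge

Simulation, classification and differential analysis of **tRNA
aminoacylation ("charging") from nanopore direct RNA sequencing signal**.

Chemical ligation can trap the amino acid of a charged tRNA between the
tRNA body and a 3' adapter, so a single nanopore read carries the molecule's
sequence *and* its charging state: the embedded amino acid depresses ionic
current at the charge site (scaling with side-chain volume) and inflates
dwell time nine positions downstream where it contacts the motor protein
(scaling with hydrophobicity). This package is for computational biologists
who want to develop, calibrate or stress-test analysis pipelines for such
data without a flow cell:

* **references**: extended constructs 5'adapter + body + CCA (+T) +
  3'adapter with anchored charge-site coordinates (0-based; effects indexed
  by signed offset from the anchor);
* **simulate**: event-level squiggle generation — per-position dwell
  (log-normal around `multiplier/130 nt s⁻¹`) and current samples
  (Normal(level(9-mer) + shift, σ)), aberrant truncation ("unblocking",
  41.0%/27.6% for Asn/Cys with the legacy all-RNA 5' adapter), elevated
  basecall error around the amino acid, and translocation-time sampling
  bias under per-channel time budgets;
* **signal features**: median/MAD normalization, per-position dwell and
  trimmed-mean current at reference-anchored positions, anchor-centered
  training chunks, dwell-bias diagnostics, amino-acid property
  correlations;
* **classify**: per-read charging probabilities mapped to integer 0–255
  modification-likelihood (ML) scores — score ≥ 200 calls a read charged —
  plus all 380 ordered pairwise amino-acid models and an alignment-based
  baseline; F1 = 2TP/(2TP + FP + FN);
* **quantify**: per-isodecoder charging/abundance tables, pooled
  two-proportion Z-tests `z = (p̂₁−p̂₂)/√(p̂(1−p̂)(1/n₁+1/n₂))` with
  Benjamini–Hochberg correction per family, and concordance against
  orthogonal (northern-style) charging measurements.

See `vignettes/charging-signal-model.Rmd` for the signal model, the
`bio-default` and `flexizyme-panel` calibration presets, and what a green
test on synthetic data does and does not establish.

## Worked example

```r
library(trnacharge)

## 1. charging classifier on simulated ground-truth libraries
##    (400 charged + 400 deacylated reads, 80/20 split, ML > 199 calls)
ce <- charging_experiment(n_per_class = 400, seed = 1)
unclass(ce$eval)[c("TP", "FP", "FN", "TN", "precision", "recall", "F1")]
#> $TP        [1] 80
#> $FP        [1] 0
#> $FN        [1] 0
#> $TN        [1] 80
#> $precision [1] 1
#> $recall    [1] 1
#> $F1        [1] 1
sprintf("deacylated reads with ML >= 200: %.2f%%", ce$fp_rate_pct)
#> [1] "deacylated reads with ML >= 200: 0.00%"

## 2. dwell-bias diagnostic: charged reads translocate ~1.2x slower
spec <- library_spec(charged_fraction = 0.5, n_reads = 2000, seed = 2)
lib  <- simulate_library(spec, signal = "none")
dwell_bias_diagnostic(lib$truth$duration, lib$truth$charged)$ratio
#> [1] 1.200815

## 3. differential charging (leucine-starvation style: one isodecoder's
##    charged fraction drops 0.8 -> 0.2, others stay at 0.7)
iso <- synthetic_isodecoders()[c("G", "L", "K", "V")]
run <- function(cf, seed, cond) {
  spec <- library_spec(isodecoders = iso, charged_fraction = cf,
                       n_reads = 8000, seed = seed, condition = cond)
  l <- simulate_library(spec, signal = "none", unblocking = FALSE)
  tabulate_isodecoders(
    data.frame(read_id = l$truth$read_id, charged = l$truth$charged),
    data.frame(read_id = l$truth$read_id, isodecoder = l$truth$isodecoder),
    sample = cond)
}
d <- differential(run(c(.7, .8, .7, .7), 3, "rich"),
                  run(c(.7, .2, .7, .7), 4, "starved"))
d[, c("isodecoder", "frac_charged_a", "frac_charged_b",
      "log2fc_charging", "q_charging")]
#>   isodecoder frac_charged_a frac_charged_b log2fc_charging q_charging
#> 1    Gly-GCC          0.703          0.695        -0.01497   8.22e-01
#> 2    Leu-CAA          0.787          0.196        -2.00505  1.66e-301
#> 3    Lys-CUU          0.697          0.696        -0.00218   9.42e-01
#> 4    Val-AAC          0.701          0.688        -0.02745   7.27e-01
```

Reading the output: the classifier separates the held-out charged and
deacylated reads perfectly at the fixed ML ≥ 200 cutoff (simulated effect
sizes are calibrated, so this is a pipeline check, not a real-data claim);
the mixed library recovers the configured 1.2× charged/uncharged
translocation-time ratio; and the differential layer flags exactly the
perturbed leucyl isodecoder (log2FC ≈ −2, q ≪ 0.05) while the unperturbed
isodecoders stay null.

## Command line

A thin CLI over the simulator and statistics lives in `inst/cli/trnacharge`
(`simulate`, `diagnose`, `differential` subcommands); see
`Rscript inst/cli/trnacharge --help` after installation.
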