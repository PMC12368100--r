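---
title: "Signal model, calibration and statistics for tRNA charging by nanopore sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal model, calibration and statistics for tRNA charging by nanopore sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Aminoacylated ("charged") tRNAs can be captured by chemically ligating a 3'
adapter through the amino acid itself, so that direct RNA nanopore sequencing
reads the construct 5' adapter + tRNA body + CCA + (amino acid) + 3' adapter
in the 3'-to-5' direction. The embedded amino acid distorts the ionic-current
signal in two characteristic ways:

* **current depression at the charge site** — bulky side chains occlude ionic
  flow as they pass the pore's reader head, maximally at the bond position
  between the CCA's final A and the first 3'-adapter base (the *anchor*);
* **dwell inflation nine positions downstream (3'-ward) of the charge site**
  — the amino acid contacts the motor protein while the adapter transits the
  pore, slowing translocation; hydrophobic residues bind longest.

`trnacharge` simulates this phenomenology at event level, classifies
charging state and amino-acid identity from reference-anchored signal
windows, and performs per-isodecoder differential tests of charging and
abundance between conditions.

# Coordinates and references

Coordinates are 0-based, half-open. The anchor is the index of the first
base 3' of the CCA (the first 3'-adapter base in standard mode; an inserted
`T` in pairwise mode). Per-position effects are indexed by signed offset
from the anchor, which generalizes the fixed positions of any single
construct (e.g. "position 77" = offset 0, "position 86" = offset +9 on a
73-nt body with our default adapters) to variable-length tRNAs.

Both 3' adapters begin with `GGC`, so the six-nucleotide classifier window
`CCAGGC` spanning offsets −3..+2 is identical across isodecoders and across
the charged/uncharged adapters; a model trained on that window transfers to
any tRNA. The shipped adapter sequences are synthetic placeholders that obey
this constraint — they are **not** the oligonucleotides of any published
protocol, whose sequences are not in the public text.

# The simulator

Per reference position, a read gets:

* dwell ~ LogNormal with mean `dwell_multiplier(offset) / mean_speed`
  (defaults: 130 nt/s, log-SD 0.35 — right-skewed, as real dwell
  distributions are);
* `round(dwell × sample_rate)` current samples (min 1; 4 kHz default)
  ~ Normal(`level(9-mer) + current_shift(offset)`, `noise_sd` = 2.5 pA).

The k-mer level function is a seeded hash of the 9-mer mapped into 60–120
pA. It makes no attempt to mimic a real pore table (which is proprietary);
only *relative* distortions matter downstream, and every operation that
compares classes does so within one level-model seed.

**Effect profiles.** For amino acid *a* with side-chain volume $V_a$ (Å³,
Zamyatnin 1972 residue volumes) and pH-7 hydrophobicity index $H_a$ (Monera
et al. 1995; Phe = 100, Gly = 0):

* current shift at offset 0 is $-(2 + 0.04\,V_a)$ pA, decaying geometrically
  (factor 0.5/position) over offsets −3..+6. The 2 pA floor plus
  0.04 pA/Å³ slope puts glycine at ≈ −4.4 pA and tryptophan at ≈ −11 pA,
  the few-pA scale seen in charged-vs-uncharged traces;
* dwell multipliers depend on the preset (below);
* an `unblock_prob` gives the chance of aberrant truncation.

Ties would break strict monotonicity (Ile/Leu share a volume; Leu/Trp a
hydrophobicity value), so a vanishing secondary term (10⁻⁴·H for current,
10⁻³·V for dwell) makes both calibrations strictly monotone in the
lexicographic order. This matters only for property-ordering invariants,
never for effect sizes.

**Two dwell presets** (the two regimes are numerically incompatible in one
profile, so they are separate):

* `"bio-default"` — moderate inflation spread over offsets 0..+12 (peaked
  at +9) calibrated so that the charged/uncharged total-translocation-time
  ratio is exactly 1.2 for the construct length it is built against, with a
  gentle ±15% hydrophobicity modulation whose mean over the 20 amino acids
  is 1 (so the panel-average ratio stays 1.2);
* `"flexizyme-panel"` — heavy per-amino-acid inflation at +9 only: the mean
  dwell there is $0.05 + 2.5/(1+e^{-(H_a-27)/10})$ seconds, a logistic in
  hydrophobicity calibrated so that **exactly the nine most hydrophobic
  amino acids** (F, I, W, L, V, M, Y, C, A) exceed 1 s while threonine and
  below stay under it, saturating near 2.5 s;
* `"zero"` — all effects off (negative control).

**Unblocking.** With the legacy all-RNA 5' adapter, Asn-charged reads
truncate with probability 0.410 and Cys-charged with 0.276; the DNA/RNA
hybrid 5' adapter reduces every amino acid to the 2% baseline. The stall
position is uniform over the 5'-adapter region (the interaction is between
the amino acid and the 5' adapter; the exact stall point is not known), so
truncated reads still cover the anchor window and are excluded from
quantification by their flag rather than by missing data.

**Basecalls** are emulated parametrically: per covered position, an error
(substitution/insertion/deletion at 0.6/0.2/0.2) occurs with probability
`error_rate` (default 0.08), multiplied by `charged_error_boost` (default 5)
within `window` positions of the anchor for charged reads only. The default
window is local (±3). For experiments that compare against the
alignment-based baseline we pass `window = 24` (the full 3' adapter):
physically the amino acid distorts signal throughout the adapter's transit,
and with only local corruption a minimum-edit-distance assigner can rescue
every read from the clean distal adapter — which would make the baseline
artificially strong, not weak.

**Randomness.** Everything flows from one integer master seed through a
splittable derivation (`derive_seed(seed, index)`); each read owns a
substream keyed by its index, so read *i* is bit-identical no matter how
many other reads are drawn.

# What the generator emulates — and what it does not

It reproduces: amino-acid-specific current and dwell distortions with the
documented property scalings; charged/uncharged duration asymmetry;
Asn/Cys pore blocking; elevated basecall error around the embedded amino
acid; time-budget sampling bias (below); compositional library structure.

It does **not** reproduce: real pore tables or rescaling pipelines; pore
state drift, stalls unrelated to amino acids, or adapter detection; tRNA
modifications (m⁵C, m⁷G, ac⁴C, ...) and their signal signatures; basecaller
behaviour beyond the parametric error model; ligation-efficiency biases.
A green test therefore establishes that the *pipeline logic* recovers what
the generator put in at realistic effect sizes — not that the classifier
would reach the same numbers on real flow-cell data. That is why the
held-out F1 and median pairwise F1 on simulated data sit at or near 1.0,
above the real-data values they are compared against as lower bounds.

# Signal features

* **Normalization**: `normalize_signal()` maps a vector to median 0 and
  scaled MAD 1 (affine-invariant, idempotent; constant input is an error).
  Applied per read, the center and scale come from the **per-event mean
  currents**, one value per covered position. Normalizing over the raw
  sample stream instead would let long-dwell events dominate the scale —
  under the flexizyme preset most samples of a read can come from the one
  +9 event, which demonstrably flipped the current-vs-volume correlation
  before this choice was made.
* **Per-position metrics**: dwell in ms and the 0.1-per-tail trimmed mean
  of normalized current at each covered position (trim fraction is
  configurable; "trimmed mean" alone does not pin a fraction, and 0.1
  balances robustness against data loss). Uncovered positions are absent,
  not zero, and per-read dwells sum exactly to the total duration.
* **Chunks**: one per read covering the anchor-centered feature window —
  trimmed-mean current at offsets −3..+6 and log dwell at offsets −3..+10
  (the +9 dwell probe included), plus (when raw samples are retained) a
  fixed-length normalized sample vector, 200 samples each side of the
  anchor event's center. Reads not covering the window are skipped and
  counted by reason.

Memory modes: `signal = "samples"` keeps raw per-position samples;
`"summary"` (default) keeps only per-position normalized trimmed means
computed before discarding samples; `"none"` skips currents for dwell-only
studies. The classifier's window features work in the first two modes.

# Classifier

The contract is the probability interface: a model maps a chunk to
P(charged). The default architecture is a ridge-penalized logistic model
(glmnet, α = 0, fixed λ = 0.01) on the window features, with
class-balancing weights; a `"chunk_bins"` variant fits binned raw-sample
vectors. A conv+recurrent network would mirror the reference tooling more
closely, but no neural-network backend exists in the supported dependency
set, and the feature-based model is the documented fast fallback; at the
calibrated effect sizes it saturates the synthetic task. Training is
deterministic given the seed, which governs only the read-level 80/20
stratified split.

Probabilities map to integer modification-likelihood scores,
`round(255 × p)`; with the fixed default cutoff of 199, score ≥ 200 calls a
read charged, ≤ 199 uncharged (the 0.78-probability boundary). Charged is
the positive class; F1 = 2TP/(2TP + FP + FN). Model-level evaluation
(pairwise F1s, chance-level null checks) thresholds probability at 0.5;
the 199 cutoff is the *calling* convention on the 0–255 scale.

**Pairwise models**: one per ordered amino-acid pair (380 for 20), trained
on inserted-T (`CCAT`) references with amino acid *i* as positive class;
the unordered matrix reports the mean of the two ordered F1s. Panels share
a single synthetic tRNA body — with per-amino-acid bodies the models learn
the reference sequence, not the amino acid (every pair including Ile/Leu
scored F1 = 1.0 in that configuration; with a shared body the hydrophobic
cluster Ile/Leu/Met collapses to ~0.5–0.6 while distant pairs stay at 1.0,
the qualitatively expected confusion structure).

**Alignment baseline**: each read's 3'-terminal basecall region is compared
with the two unique 3' adapters by edit distance; ties are unassigned and
count as misclassifications of the true class (a conservative convention:
an unassigned truly-charged read is a false negative, an unassigned
truly-uncharged read a false positive).

# Quantification and statistics

Per-read calls aggregate to per-isodecoder counts (reads not covering the
anchor are excluded and counted separately). "Abundance" is the fraction of
classified reads per sample — compositional, tested as isodecoder-vs-rest
pooled counts. Differential analysis between conditions uses pooled
two-proportion Z-tests, $z = (\hat p_1-\hat p_2)/\sqrt{\hat p(1-\hat p)(1/n_1+1/n_2)}$
with two-sided normal p-values, and Benjamini–Hochberg correction applied
separately to the abundance and charging families (they are presented as
separate analyses). Replicates are pooled for the statistic; per-replicate
log2 fold changes are summarized as mean ± SD. A 0.5 pseudocount enters
zero cells for fold changes only, never for tests. Whether the original
analysis pooled replicates or meta-analyzed them is not documented; pooling
is this package's declared, configurable choice.

# Time-budget sampling bias

Charged reads translocate ~1.2× slower, so a fixed sequencing time budget
yields disproportionately many uncharged reads and sequencing
*underestimates* charging. Mechanically this is subtler than it sounds:
with reads drawn i.i.d. sequentially and every completed read kept, the
composition of completed reads equals the pool composition (a renewal
argument — the number of completed reads adjusts, their mix does not). The
bias comes from the molecule in progress when the budget expires, which is
length-biased toward charged reads and lost. `simulate_library()` therefore
discards the budget-crossing read of each channel.

Because simulated total durations are narrow (CV ≈ 3.5%), the bias only
materializes when the budget boundary discriminates between channel
compositions: at 2.2 s (~2.1 mean durations) two uncharged reads fit a
channel but two charged reads do not, giving a measured charged fraction of
~0.44 against a 0.5 input, uniformly across isodecoders; at 2.5 s every
channel completes exactly two reads and the bias vanishes. Real runs have
broad duration spreads and thousands of reads per pore, producing a
smoother, percent-scale version of the same effect; the simulator
reproduces the direction and mechanism, not the field magnitude.

# Numerical conventions and degenerate inputs

* Dwell is reported in ms (durations internally in seconds); currents are
  dimensionless after normalization.
* `two_proportion_ztest` defines z = 0 (p = 1) when both proportions are
  jointly 0 or jointly 1; zero trials are an error.
* `f1_score` is `NA` when 2TP + FP + FN = 0.
* Constant signal (zero MAD) is an explicit error, not a silent NaN.
* FASTA headers carry `anchor=`/`mode=` fields so references round-trip
  with coordinates; duplicate names are rejected; an empty file yields an
  empty set with a warning.
* The binary signal container stores current samples as float32; round
  trips are exact from the second pass onward (and to 10⁻⁶ relative on the
  first).

# Known limitations

* The classifier is linear in window features; fine-grained amino-acid
  pairs that differ only through non-linear signal structure would need the
  richer architecture the reference tooling uses.
* Absolute charging quantitation is out of scope: the simulator reproduces
  the underestimation bias, and `charging_concordance()` exposes it via
  identity-line residuals, but no correction factor is fitted or applied.
* The synthetic tRNA bodies are random-sequence stand-ins without
  cloverleaf structure; only the invariant CCA/adapter context carries
  classifier-relevant signal, which is the design point of the shared
  window, but body-dependent effects in real data are not modeled.
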