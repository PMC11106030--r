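---
title: "Comparing nanopore current events at candidate modification sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing nanopore current events at candidate modification sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigglescope)
```

## The problem

Base modifications (m6A on RNA, 5mC on DNA, and many others) perturb the
ionic current measured while a molecule traverses a nanopore. A common
validation strategy compares a **native** sample against a **negative
control** carrying little or no modification — in vitro transcribed (IVT)
RNA, or whole-genome-amplified (WGA) DNA — at a handful of candidate sites.
Two classes of evidence are used:

* **alignment features**: modified bases elevate basecalling error, so the
  per-position mismatch profile differs between native and control reads;
* **current-event features**: after "resquiggling" (assigning contiguous
  runs of raw samples — *events* — to individual bases), the per-base mean,
  median, standard deviation and dwell time shift at and around the
  modified position.

squigglescope ingests the file outputs of the standard preprocessing tools
(f5c resquiggle, eventalign, basecaller move tables, Tombo-style exports,
ASCII SLOW5 raw signal, minimap2 BAMs), harmonizes them, and provides the
visualization plus a per-position statistical test.

## The model and procedure

### Per-read signal normalization

Raw currents differ between pores and reads. For the mapped section of each
read the signal is rescaled as

$$\mathrm{NormSignal} = \frac{\mathrm{RawSignal} - \mathrm{Shift}}{\mathrm{Scale}}$$

with Shift the median and Scale the median absolute deviation (plain MAD,
no 1.4826 consistency factor — the robust scale is used as-is). Normalized
values beyond a threshold (default ±5) are replaced by the threshold, so
noise spikes cannot dominate event statistics. Features are computed on the
clipped values; the clip is applied before, not after, feature computation.
A zero MAD (constant signal) is reported as a degenerate-signal error
rather than silently producing infinities.

### Event features and reference projection

Each event contributes four features: mean, median, standard deviation
(population form, divisor $n$, so one-sample events give 0 rather than
NaN), and dwell time. Dwell is reported in raw samples; divide by the
sampling rate for milliseconds.

f5c resquiggle and move tables index the *basecalled read*; those events
are projected onto the reference by walking the alignment CIGAR: aligned
columns map one-to-one, events on inserted or soft-clipped bases are
dropped, deleted reference positions simply receive no event (they are
omitted, never zero-filled). For reverse-strand alignments the BAM stores
the reverse complement, so basecall position $i$ corresponds to query index
$q_\mathrm{len} - 1 - i$ before the walk. eventalign and Tombo-style tables
already carry reference positions and skip projection; rows sharing a
position are merged into one event (earliest start, summed length).

Direct-RNA reads are sequenced 3'→5' and the signal is stored in that
orientation; basecall-space events and samples are reversed
(`reverse_rna_events()`, an involution) before projection. For
reference-space dialects this package adopts the convention that exported
indices refer to the 5'→3'-oriented signal, so only the stored samples are
flipped. Display mode `rna = TRUE` renders U for T everywhere; counts are
stored as T internally.

Preprocessors also disagree about *which* base of the pore's k-mer an event
is attributed to (for the RNA002 5-mer CUAAG, f5c uses the first base C
where Tombo uses the second, U). The `base_shift` option ("auto" by
default) resolves this from an editable table keyed by (dialect, molecule,
pore) shipped in `extdata/base_shift_table.tsv`; unknown combinations fail
loudly rather than guessing. Events shifted outside the read are dropped.

### k-mer PCA and MANOVA

A modification perturbs neighbouring bases too, so each position is tested
with a window of $k$ consecutive positions (default $k = 3$, giving
$3 \times 4 = 12$ features per read; `kmer_size` is tunable). Reads missing
any window position are excluded, so rows are complete. Dwell is
log10-transformed before use — dwell distributions are heavy-tailed and the
transform stabilizes the decomposition (switchable via
`assemble_kmer_matrix(log10_dwell = FALSE)`).

Columns are standardized (zero-variance columns dropped) and projected onto
the first two principal components; group separation is then tested with a
MANOVA using **Pillai's trace** and the standard F approximation. Running
the test in PC-score space matches what the scatter plot shows; the raw
4k-feature alternative is available via `use_pca = FALSE`. Pillai's trace
was chosen as the most robust of the classical MANOVA statistics. If the
within-group covariance is singular the p-value falls back to a
label-permutation test of the same statistic (seeded, flagged in the
output). With a single retained response the test reduces exactly to
one-way ANOVA.

Positions with $-\log_{10} p > 3$ (i.e. $p < 10^{-3}$) are flagged. No
multiple-testing correction is applied to the flagging rule — the raw
profile with a fixed cutoff is the interface — but a Bonferroni column is
emitted for transparency. Because k-mer features smear evidence across
neighbours, flagged positions form a cluster; the truly modified base is
expected near the middle of that cluster, and the package deliberately does
not auto-call a single site. P-values are floored at 1e-300 before the log
transform.

## The synthetic-data generator

`simulation_config()` / `simulate_sample_pair()` emit a complete,
internally consistent fixture set (FASTA reference, ASCII SLOW5 signals,
f5c-resquiggle and Tombo-style event TSVs, BAM alignments) for a native and
a control group. The generative model:

* per-base current levels A = 85, C = 95, T = 100, G = 110 pA — the pA
  scale and level spread of an R9.4.1-class pore, deliberately coarse
  (single-base levels rather than a k-mer model);
* Gaussian measurement noise, sd 2.5 pA;
* dwell per base $1 + \mathrm{Geometric}(p)$ with $p = 1/9$ (mean 9
  samples/base at 4 kHz, matching ~450 bases/s DNA translocation); the
  1-offset guarantees every event has at least one sample and the
  geometric tail qualitatively matches real dwell distributions;
* the native group's level at the modified site is shifted by
  `effect_delta`, expressed in normalized-current units and converted to pA
  by the MAD of the per-position level track (the same robust scale the
  normalization divides by); the immediate flanks get `neighbor_deltas`
  (default 0.75 each), emulating the observed spill-over of modification
  effects onto adjacent bases;
* the native group's emitted base at the modified site is substituted with
  probability `basecall_error_rate` (default 0.15), emulating
  modification-induced miscalls;
* RNA mode stores signal and basecall-space event starts 3'→5'.

Defaults (50 reads/group, `effect_delta = 1.5`, reference length 60,
modified site in the middle) are the standing study conditions used by the
test suite and the acceptance script. With `effect_delta = 0` the two
groups are exchangeable by construction, which anchors the null
calibration checks.

What the generator does **not** emulate: sequence-context (k-mer) current
models, homopolymer noise, indel errors (substitutions only; alignments are
perfect-match CIGARs), coverage variation along the reference, pore decay,
or multi-contig references. Passing tests therefore demonstrate the
pipeline's statistical behaviour under a clean, well-specified signal
model — not performance on real flowcell data, where context effects and
alignment artefacts add variance the generator omits.

## A worked run

```{r example, eval = FALSE}
fixture_dir <- tempfile()
sim <- simulation_config(seed = 7)
run_simulate(sim, fixture_dir)

cfg <- fixture_run_config(fixture_dir, sim, file.path(fixture_dir, "out"),
                          flank = 10)
res <- run_current_events_magnifier(cfg)
res$profile$results[, c("position", "statistic", "p_value", "neg_log10_p",
                        "flagged")]
res$profile$flagged  # cluster of 0-based positions around the injected site
```

The output directory contains `current_features.tsv` (per read × position ×
feature), `position_tests.tsv` (per-position Pillai statistic, p-value,
flag), `center_pc_scores.tsv` (per-read PC1/PC2 at the candidate site),
`kmer_feature_matrix.tsv` (the ML-ready k×4 table for the candidate site),
figures, and `run_metadata.json` recording the full configuration and seed,
sufficient to reproduce the run exactly.

## Numerical choices and degenerate inputs

* Quartiles in the box panels use linear interpolation (R type 7); whiskers
  extend to the most extreme observation within 1.5 × IQR.
* Event intervals are 0-based half-open; CLI positions are 1-based
  inclusive and converted at the boundary.
* The feature region is extended by $\lfloor k/2 \rfloor$ positions on each
  side of the requested region so every requested position has a complete
  window.
* Zero-coverage positions yield missing mismatch fractions, never 0.
* Tested sites require a configurable minimum of complete reads per group
  (default 10); under-covered sites are skipped with an explicit error when
  nothing is testable.
* Figures default to SVG, which renders byte-identically for a given
  bundle; PDF output embeds a creation timestamp and is therefore not the
  determinism-checked default.
* Problem sizes in the shipped checks (60-base references, 50 reads/group,
  20 replicate seeds, 1000-replicate null calibration) were chosen as the
  smallest sizes at which the statistical properties of interest are
  stable.

## Known limitations

* BLOW5/pod5/fast5 binary containers are not parsed; convert to ASCII
  SLOW5 (slow5tools) or export per-read TSV indices first.
* The base-shift table ships with a small set of seeded defaults; values
  for unlisted (dialect, molecule, pore) combinations must be added by the
  user — "auto" refuses to guess.
* MANOVA on two PC scores discards variance beyond PC2; for signals that
  separate groups only in higher components, use `use_pca = FALSE`.
* No classifier training is included; `kmer_feature_matrix.tsv` is the
  intended hand-off to external machine-learning tooling.
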