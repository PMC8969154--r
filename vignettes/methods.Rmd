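---
title: "Models, statistics, and design choices in acylomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics, and design choices in acylomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`acylomics` re-implements, as one tested pipeline, the desk-side computations
that surround a study of lysine glutarylation on a mitochondrial
dehydrogenase (GCDH) and its removal by the sirtuin deacylase SIRT5: a
hepatic gene-coexpression screen, label-free acyl-site quantification,
two-state thermal-unfolding fits, enzyme/radiolabel/qPCR arithmetic, and
metabolite differential statistics. Every stage has a synthetic-data
generator with known ground truth, so recovery can be tested without any
external download. This vignette explains the models, the tunable
parameters, and the choices made where the design was genuinely open.

## Coexpression screen

The screen takes a genes x samples log-scale expression matrix with a
per-sample tumor flag, keeps only non-tumor samples, and computes the
all-vs-all Pearson correlation matrix (Spearman available; Pearson is the
microarray convention on log-scale values and no alternative is named in the
source analyses). Zero-variance genes cannot be correlated and are dropped
with a warning rather than an error, since real matrices contain flat
probes.

Significance for a query gene's correlates is empirical: `resample_null()`
draws `B = 1000` "virtual gene lists" of `list_size = 20` coefficients from
the off-diagonal upper triangle (without replacement within a list, with
replacement across lists), pools the `B * list_size` draws, and gates each
query correlation at `mean ± k·sd` with `k = 2`. Open choices resolved here:

* **Signed r, not r².** The source text describes resampling r² values, but
  a two-sided ±2 SD gate is only meaningful on a signed quantity (r² has no
  lower tail). The default statistic is therefore signed `r`; `stat = "r2"`
  preserves the literal reading for one-tailed use.
* **Virtual-list size** is unstated in the source; it defaults to the
  query-list size (20). Because the mean and SD are computed over the pooled
  draws, the list size barely affects the bounds — only the total number of
  pooled draws does.
* The threshold is applied to each gene's correlation with the query, not to
  list membership; the upper triangle excludes the diagonal so trivially
  perfect self-correlations never enter the null.

With 200 independent-noise samples the sample correlation of unrelated genes
is approximately normal with SD `1/sqrt(n-1)`, so the fraction of
coefficients beyond the ±2 SD bounds should approach the normal-tail value
`P(|z| > 2) = 4.55%`; the acceptance suite verifies this calibration on a
2000 x 200 matrix.

Over-representation of the beyond-threshold correlates uses the upper-tail
hypergeometric test per gene set (the concrete enrichment tool behind the
original analysis is unnamed; over-representation of an unranked hit list is
the minimal defensible reading) with Benjamini–Hochberg adjustment across
sets.

## Synthetic expression data

`gen_expression()` uses a single-latent-factor construction: the query gene
carries the factor itself (scaled to the noise SD), and each planted-module
gene is `beta·f + noise` with `beta = sd·r/sqrt(1-r²)`, which makes the
population correlation of each planted gene with the query exactly
`planted_r = beta/sqrt(beta² + sd²)` — a closed-form target that the
Monte-Carlo tests check. Tumor samples get a global `+0.5 SD` mean shift on
every gene, so an unfiltered analysis shows inflated correlations and the
non-tumor filter has a visible effect. Values are emitted on an
already-normalized log2 scale (per-gene baselines near 8); the generator
does not emulate probe-level normalization, batch effects, or heavy-tailed
arrays, so a green recovery test establishes correctness of the screen's
logic, not robustness to raw-array artifacts.

## Acyl-site quantification

The quant table is long-format replicate MS1 intensities for one protein's
peptides. The stages mirror label-free practice:

1. **Protein abundance** per (condition, replicate) sample is an aggregate of
   unmodified-peptide intensities only. The source states no aggregation;
   the default is the mean (robust to peptide-count differences between
   samples; `median` and `sum` are available).
2. **Normalization** divides every intensity by its sample's protein
   abundance. This is exactly invariant to per-sample global scaling — the
   property that makes the step cancel loading and instrument drift.
3. **Low-abundance imputation** fills each missing cell with a uniform draw
   from the observed intensities at or below the 5th percentile of its own
   sample, seeded and deterministic. The exact resampling distribution
   behind "low abundance resampling" is unspecified upstream; a uniform draw
   from the low tail is the simplest model consistent with the name, and the
   tests assert the ceiling property rather than a distributional shape.
4. **Per-site statistics**: log2 fold change as the difference of mean log2
   normalized intensities, and a pooled-variance two-sample Student's t
   (df = 2n-2) — pooled, not Welch, to match the named test. A glutarylation
   call requires jointly `log2FC > 1.8` and `p <= 0.05`; a deglutarylation
   call (modified + deacylase over modified) uses the p-gate alone, since no
   fold-change gate is stated for that contrast. When several peptides cover
   a site, their normalized intensities are averaged per sample before
   statistics (upstream is silent; averaging keeps replicate counts equal
   across sites).

Residue coordinates are mapped from construct to full-length numbering by
pure 1-based arithmetic with a configurable presequence offset — the offset
is a property of the construct, not a constant of the method, so no default
is asserted. Modification masses are sums of standard monoisotopic atomic
masses; glutarylation (C5H6O3) gives 114.0316941 Da.

The generator plants per-site log2 effects on top of log-normal peptide
intensities, applies a per-sample log-normal loading factor (so
normalization is necessary, not optional), and places missing values with a
logistic weight in log2 intensity (missingness in MS1 data is
abundance-dependent — the reason low-abundance imputation exists). Replicate
noise defaults to SD 0.3 on the log2 scale (~20–25% CV, typical of
label-free MS1 quantification).

## Thermal unfolding

Melting curves follow the two-state van't Hoff model with linear baselines:

    signal(T) = [(yN + mN·T) + (yU + mU·T)·K(T)] / (1 + K(T))
    K(T) = exp[-(dH/R)(1/T - 1/Tm)],  T in kelvin, R = 8.314 J/mol/K

Only "a two-state model" is named upstream; linear pre- and post-transition
baselines are the standard CD practice. Fitting is nonlinear least squares
on the **raw signal** (the instrument measures raw ellipticity, and fitting
the raw trace keeps the noise model homoscedastic); fraction-unfolded
normalization is offered as an output transform only. Initialization is
heuristic — Tm at the steepest smoothed signal change, baselines from linear
fits to the end segments, dH = 300 kJ/mol — with `nls` (port, Tm bounded
inside the scanned range) and an L-BFGS-B fallback. A fit is reported
unconverged (never an exception) when the optimizer fails, when Tm pins to
the range boundary, or when a straight line explains the curve essentially
as well (the two-state fit must at least halve the linear-model residual) —
the latter is what flags transition-free curves. The default synthetic ramp
is 20–85 °C in 1 °C steps (a 1 °C/min ramp read once per minute), and the
2%-of-amplitude noise level used in the recovery tests corresponds to
SD 0.3 signal units on the default ~15-unit transition.

## Assay arithmetic

All four readout operations are pure arithmetic. Specific activity converts
the initial-rate slope of A600 versus time via Beer–Lambert:
`rate (nmol/min) = |slope per min|/(eps·l) · volume_mL · 1000`, with DCPIP
`eps600 = 21 mM^-1 cm^-1` as the configurable default (a literature value;
none is stated upstream) and the fit window defaulting to the first 20% of
the trace, the initial-rate region. A statistically significant *increase*
in A600 raises an assay-direction error. Radiolabel release is
background-subtracted DPM over total label added, clamped at zero with a
message. Relative qPCR expression is `2^-ddCt` against an endogenous control
and calibrator sample. Percent-of-control is `100·value/control`.

## Metabolite differential statistics

Peak areas are log2-transformed; the fold change is the difference of group
means on that scale (a ratio of geometric means — chosen over the mean of
per-replicate ratios, which is ill-defined for unpaired designs); the test
is a two-tailed unpaired Student's t (pooled variance, mirroring the
acyl-site choice; Welch available); BH adjustment runs across all features;
hits require `q < 0.015` and `|log2FC| > 1`. Features with under two
replicates or zero variance in both groups are reported not-testable (`NA`)
rather than given a fabricated p-value.

The generator's replicate noise defaults to SD 0.2 on the log2 scale (~15%
CV), the commonly reported technical precision of LC-MS peak areas from
cultured-cell extracts. This choice matters: with n = 3 and a q < 0.015
gate, planted 4-fold effects are reliably recovered at ~15% CV but not at
~30% — the stricter regime is also the one in which the stated recovery
behaviour of the pipeline's own validation suite is coherent.

## Reproducibility and numerical conventions

A single global seed is fanned out to per-stage child seeds by a stage-name
hash (`derive_seed`), so each stage is independently reproducible from
(seed, parameters) alone; every generator and every stochastic stage
(resampling null, imputation) is bit-reproducible under a fixed seed. All
file formats are plain text (TSV/CSV/GMT/JSON); numeric writers use 17
significant digits so write/read round-trips are lossless. Ties in |r| are
broken lexicographically by gene id; hypergeometric p-values include the
observed overlap in the upper tail (zero overlap gives p = 1); BH is the
textbook step-up with a cumulative minimum and cap at 1.

## Limitations

The package starts from tables — expression matrices, peptide intensities,
melting traces — and deliberately excludes everything upstream of them:
spectral search, PSM-level FDR, site-localization scoring, peak extraction,
probe summarization, and scan-rate or irreversibility corrections in the
thermal model. Synthetic data are Gaussian/log-normal with independent
replicates; they do not emulate correlated noise, batch structure, or
instrument drift, so recovery tests validate the implementations, not the
field-robustness of the methods themselves.
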