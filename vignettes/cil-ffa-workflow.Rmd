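---
title: "Profiling free fatty acids by chemical isotope labeling LC-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling free fatty acids by chemical isotope labeling LC-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilffa)
```

## The measurement model

Chemical isotope labeling (CIL) LC-MS derivatizes carboxylic acids with a
pair of amine reagents before analysis: 2-dimethylaminoethylamine (DMED,
the *light* tag) and its four-deuterium analogue d4-DMED (the *heavy*
tag). Amidation adds C4H12N2 and eliminates water, so the neutral mass of
a light derivative is the acid mass + 70.0895 Da; the heavy derivative
additionally carries four deuterium-for-protium substitutions,

$$\Delta m = 4\,(m_{^2\mathrm H} - m_{^1\mathrm H}) = 4.0251\ \mathrm{Da}.$$

All ions are singly protonated ([M+H]+). For caprylic acid (C8H16O2) the
light and heavy ions sit at m/z 215.2118 and 219.2369:

```{r}
derivative_mz("C8H16O2", "light")
derivative_mz("C8H16O2", "heavy")
```

In a 1:1 light/heavy labeled mixture, every acid therefore appears as a
*peak pair*: two features separated by exactly 4.0251 Da, co-eluting, with
near-equal intensities. The pair is the unit of evidence for one
potential free fatty acid (FFA); isolated features (chemical noise,
non-acids) have no partner and are discarded. The package always matches
against the exact delta 4.0251068 Da, not the 3-decimal 4.025 commonly
printed.

### Retention indexing

Retention times drift between runs, so all retention coordinates are
converted to retention indices (RI) against a spiked homologous ladder of
straight-chain alkanoic acids C5:0–C24:0 labeled with the heavy tag. We
adopt the Kovats-style convention RI(Cn:0) = 100·n, which makes carbon
number legible directly in RI units. The RT→RI map is piecewise linear
through the detected ladder anchors, with end-segment linear
extrapolation: it is exact at anchors, strictly increasing, and — the
property that matters — *invariant* under any affine time warp applied to
a whole run, since anchors and analytes warp together. Nonlinear
(spline/LOESS) calibration is deliberately out of scope: the linear map
makes no assumption between anchors, and anchor density (one per CH2
unit) keeps interpolation error small.

Ladder detection takes, for every expected heavy-ladder m/z, the most
intense peak within the m/z tolerance (standards are spiked high, so
intensity is the robust discriminant); a peak claimed by two expected
masses is assigned to the closer one. A ladder whose anchors are not
strictly increasing in RT is rejected as physically invalid.

## Pair extraction and cross-sample merging

A pair (light `l`, heavy `h`) is emitted iff

* |(h.mz − l.mz) − 4.0251| ≤ `mass_delta_tolerance` (default 5.0 mDa,
  the only instrument tolerance the protocol states, reused everywhere);
* |h.RI − l.RI| ≤ `ri_tolerance` (default 5 RI units ≈ 1/20 of a CH2
  unit; the derivatives co-elute);
* intensity fold difference ≤ `max_intensity_fold` (default 5; 1:1
  mixing implies a near-unity ratio, and the generous bound tolerates
  deuterium ionization effects).

Each peak joins at most one pair. Assignment is greedy in ascending
|mass error| (ties: ascending RI gap, then light m/z) rather than a
global optimal matching: it is deterministic, conflicts are rare at
LC-MS feature densities, and the result is independent of input row
order because candidates are sorted internally. Chimeric/overlapping
pair deconvolution is a documented non-goal.

Pairs from different runs are merged into consensus *potential FFAs* by
clustering light (m/z, RI): observations are first chained by single
linkage in m/z (a gap larger than the dedup tolerance separates
features — detections of one compound form a dense cloud), then each
chain is split along RI wherever an observation falls more than the RI
tolerance from the running mean of its cluster. Consensus m/z and RI are
intensity-weighted means. This two-stage rule was chosen over nearest-
centroid assignment because centroids seeded on noise outliers split
true features; the gap rule is also order-independent.

Region presence/absence algebra then gives per-region counts, the
symmetric common-FFA count matrix, and the asymmetric ratio matrix
R[a, b] = common(a, b)/|a| — the *row* region is the denominator, so
R[a, b]·|a| = R[b, a]·|b| holds exactly.

## Annotation

Identification is two-tier. First, library matching by light m/z
(±5 mDa) and RI (±10): among qualifying entries the closest m/z wins,
ties resolved by closest RI. Second, unmatched FFAs get de novo CHNO
formula generation from the neutral labeled mass (light m/z − proton):
candidate derivative formulas within tolerance are back-transformed
(−DMED + H2O, i.e. C−4, H−10, N−2, O+1) to neutral acids. Candidates
must have non-negative counts; an empty candidate list is a legitimate
outcome (unassignable pair).

Formula generation enumerates hydrogen counts directly from the mass
window for every C/N/O combination inside the bounds (defaults C ≤ 50,
H ≤ 100, N ≤ 6, O ≤ 10 — wide enough for very-long-chain FFA derivatives
carrying the two label nitrogens in a m/z 180–650 scan). Candidates are
filtered to integral, non-negative ring-plus-double-bond equivalents
(RDBE = C − H/2 + N/2 + 1, deuterium counting as hydrogen) — the
standard even-electron plausibility filter, switchable off — and ranked
by |mass error|, ties by fewer heteroatoms then fewer atoms, so output
order is deterministic. Isotope-pattern scoring and adducts beyond
[M+H]+ are non-goals.

Saturation classes derive from RDBE: one equivalent is the carboxyl C=O,
so C=C double bonds = RDBE − 1 (0 saturated, 1 monounsaturated, >1
polyunsaturated); chain-length classes are short (2–5 C), medium (6–12),
long (13–22), very long (>22). Bile acids are not derivable from a
formula at this level and ride as library metadata.

The packaged library (`inst/extdata/ffa_library_synthetic.csv`) is a
synthetic stand-in — the original in-house standards collection is a
hosted service without a public dump. Its 58 entries cover the full
C5:0–C24:0 ladder (RI = 100·n), 7 monounsaturated and 10 polyunsaturated
acids with the heuristic RI = 100·C − 45·(C=C), 4 bile acids, and
branched/hydroxy/oxo acids; treat its RIs as fixture values, not
measurements.

## Quantitation and sample QC

Quantitative runs label samples with the light tag only and spike the
heavy ladder as internal standards. A sample in which any of the 20
standards is undetected is excluded (`required_fraction = 1`,
configurable) — partial standard detection signals an unreliable run.
Each analyte is normalized by the intensity of the ladder standard with
the nearest RI (ties to the lower carbon number): one-point internal-
standard normalization cancels per-run global intensity scale exactly,
and the nearest standard best shares the analyte's elution-dependent
ionization conditions. A bracketing two-standard interpolation was
considered and rejected for the default: it halves robustness to a
single aberrant standard without evidence of better accuracy at this
noise level. Undetected analytes are explicit `NA`s, never zeros;
half-minimum imputation exists only behind an explicit flag of the
modelling preparation step.

## Feature selection

Per FFA, a transform gate tries none → sqrt → log10 and accepts the
first under which every group passes Shapiro–Wilk normality and the
groups pass Levene's test (both α = 0.05); if none passes, log10 is used
with a warning flag. In automatic gating a transform undefined for the
data (negatives under sqrt, non-positives under log10) is skipped and
recorded; explicitly *requesting* such a transform is an error. One-way
ANOVA then uses the classical between/within decomposition with p from
F(k−1, N−k); zero within-group variance with unequal means is flagged
degenerate and reported at the smallest representable p.

PCA (unit-variance scaled, SIMCA's default; centering always) reports
cumulative R2X and a cross-validated Q2 in which held-out matrix
elements are reconstructed from the remaining elements of their row via
training-set loadings — an honest prediction, not a refit.

OPLS-DA uses NIPALS with min(k−1, rank) predictive components plus
orthogonal components (count chosen by maximizing stratified 7-fold Q2,
up to 5). A single predictive component — the textbook two-class OPLS
layout — cannot carry group contrasts orthogonal to the first Y-latent
direction when k > 2, so a four-region design would structurally miss
effects confined to later contrasts; multiple predictive components are
SIMCA's own multiclass behaviour, and for two classes the model reduces
exactly to one predictive component. VIP is computed over predictive
components, weighted by the Y variance each explains, and satisfies
Σ VIP² = p to machine precision (a unit test asserts 1e-9); it agrees
with the independent `mixOmics` PLS-DA VIP implementation on identical
inputs.

Selection is the joint rule VIP > 1.0 ∧ p < 0.05 with *no*
multiple-testing correction — faithful to the source protocol. The
statistical cost is predictable: with m truly null features the rule
admits on the order of α·m chance selections, because features that
reach p < 0.05 by chance also tend to carry elevated VIP (both reflect
between-group variance). On the default 58-FFA panel that is about two
chance features per study. Benjamini–Hochberg FDR is available behind
the `fdr` flag and essentially eliminates them, at the price of
departing from the original rule.

## The synthetic-data generator

The generator emulates the two study designs at feature level:

* **qualitative** — one pooled run per region (13 regions by default),
  each present FFA emitting a light/heavy pair (common log-normal base
  intensity split with ratio noise around 1), plus ladder and decoys;
* **quantitative** — 4 regions × 12 samples by default, light analytes
  with per-FFA log-normal base levels, per-region fold effects,
  multiplicative noise, a per-sample global scale factor, and the heavy
  ladder with optional planted dropout to exercise QC.

Defaults are the emulated study conditions: m/z noise σ = 1 mDa
(matching the 5 mDa tolerance at 5σ), RI jitter σ = 1, intensity CV
20 %, log-normal base intensities (µ = log 1e6, σ = 0.6 — typical
LC-MS area spread), region presence probability 0.55 (per-region counts
at roughly half the union, as observed in regional profiling), ladder at
5e6 with 5 % CV, and per-run affine RT drift (intercept σ 0.1 min,
slope σ 0.02). Decoys are sampled uniformly over m/z 180–650 but
rejection-sampled to stay ≥10 mDa away from every existing peak *and*
from every existing peak shifted by ±4.0251 Da, so decoys can never form
accidental pairs with anything — this keeps false-pair tests sharp, and
means planted-pair recall/false-positive results say nothing about
chimeric interference, which real data can contain. Heavy derivatives
get no systematic RT offset (co-elution is assumed; a stress option
exists in the drift field). Everything is driven by one seed; identical
configurations are byte-identical, and the caller's RNG state is
restored.

What the generator does **not** emulate: chromatographic peak shapes,
isotope envelopes, profile spectra, adduct multiplicity, co-eluting
isomers, or intensity-dependent m/z error. Passing tests therefore
demonstrate the algebra and statistics of the pipeline, not robustness
to raw-data pathologies upstream of feature detection.

## Numerical and scale choices

Atomic masses are standard monoisotopic values at ≥10 significant
digits (1H 1.00782503207, 2H 2.01410177785, 12C exact, 14N 14.0030740048,
16O 15.9949146196, proton 1.007276466879); they reproduce the printed
derivative m/z values to 4 decimals. Test problem sizes were chosen to
finish a full suite run in well under a minute of compute while keeping
statistical checks meaningful: 1000 planted pairs with 2000 decoys for
pair recovery, 2000 simulated features for ANOVA null calibration,
100 random masses for exhaustive formula-generation equivalence, and a
48-sample, 58-FFA study for end-to-end selection.

## Known limitations

* Greedy 1-to-1 pairing can mis-assign in dense chimeric clusters.
* Consensus merging windows cannot separate compounds closer than the
  dedup tolerances in both m/z and RI (e.g. stereoisomers).
* The uncorrected joint selection rule admits ≈ α·m chance features, as
  discussed above.
* Bile-acid identity rests entirely on library metadata.
* The packaged library's RIs are synthetic; matching results on real
  data require a user-supplied measured library.
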