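---
title: "Predicting bitterness from mass spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bitterness from mass spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bitterspec` classifies compounds as bitter or nonbitter directly from
experimental mass spectra. This vignette is the package's account of the
statistical model, the parameters that matter, the synthetic data it is
validated on, and the design decisions taken where more than one
reasonable choice existed.

## The model

A mass spectrum is a peak list: pairs of m/z (Th) and relative
intensity. After min–max normalization of intensities to `[0, 100]`,
each spectrum becomes a fixed-length descriptor vector with two parts.

**Instrument descriptors.** MS type and ion mode are categorical and
coded as natural numbers starting at 1, in a vocabulary fixed at
training time (`buildInstrumentVocab()`); the collision energy enters
in eV, with 0 encoding "unknown". The code 0 is reserved for
categories unseen in training, consistent with 0 already meaning
unknown for the energy. These three descriptors let the ensemble
condition its fragment-pattern rules on how the spectrum was acquired —
EI and collision-induced fragmentation produce systematically different
patterns.

**Binned peak descriptors.** The m/z axis between the minimum and
maximum training m/z is tiled with half-open bins `[lo, lo + w)` of
width `w` (default 0.1 Th). Three strategies populate the bins:

- *intensity* (default): total intensity of the peaks in the bin; if
  any bin exceeds 100 the spectrum's bin vector is min–max rescaled
  back into `[0, 100]`;
- *binary*: 1 if at least one peak falls in the bin;
- *count*: the number of peaks in the bin.

Bins with no training peak are pruned (`pruneEmptyBins()`) and the
schema is then frozen: prediction-time featurization reuses it
unchanged, and peaks outside the trained m/z range are dropped (their
count is reported as an attribute). A spectrum with *no* peak in range
is refused at prediction time rather than classified from instrument
metadata alone.

The classifier is a tree ensemble — a `ranger` probability forest by
default, or `xgboost` gradient boosting — trained on spectra, with the
compound label inherited by each of its spectra. Hyperparameters are
grid-searched under five-fold cross-validation optimizing balanced
accuracy; the compound label, not plain accuracy, because the datasets
this method targets are imbalanced both in compounds and (more
severely) in spectra.

**Aggregation.** At prediction time each spectrum gets
`p(bitter)`; it is labeled bitter iff `p >= 0.5`; a compound's label is
the majority vote over its spectra, with an exact tie resolved by a
fair coin on its own seeded stream. The threshold 0.5 is the default
decision rule of the underlying classifiers; the tie coin is seeded
separately from training so the two randomness sources are
independent.

**The naive baseline.** `naiveFit()` records the training prevalence
of bitter spectra; `naivePredict()` then predicts bitter with that
probability independently of the spectrum. Because prediction is
independent of truth, its expected balanced accuracy is 0.5 for any
prevalence, while its precision converges to the evaluation set's
bitter fraction and its recall to the fitted probability. On a set that
is about two-thirds bitter this lands precision and recall near 0.66 —
a useful anchor: any genuine spectrum-to-taste signal must clear it.

## Why splits are drawn by compound

A compound commonly has several spectra (different instruments,
collision energies, repositories), and some of them are near-identical.
A train/test split drawn over spectra can place near-duplicates on both
sides, which inflates every test metric. All partitions here —
the outer repeated splits and the inner CV folds — are therefore drawn
over *compounds*, stratified within class (test share rounded to
nearest, minimum 1 compound, so both classes always appear in the test
set). The leakage hazard is not hypothetical:
`compareSplitLevels()` runs the same data through both split styles,
and on the `"imbalanced"` synthetic preset (weak class signal, strong
compound fingerprints) spectrum-level splitting inflates balanced
accuracy by roughly 0.1–0.2 — entirely spurious, since the honest
compound-level estimate sits near chance.

Model selection over the repeated splits follows "best test balanced
accuracy, ties broken by F1". The repeated-split metric table
(mean ± sd) is the honest performance summary; the best model is what
one would deploy.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `binWidth` | 0.1 | Th | fine enough to separate nominal-mass fragments while keeping the pruned matrix tractable; bin labels print as `[146.0 to 146.1]` |
| `strategy` | `"intensity"` | — | retains abundance information; binary/count are provided for comparison |
| `testFraction` | 0.2 | — | 80/20 compound split per class |
| `repeats` | 20 | — | enough repeats to report mean ± sd and curve bands |
| `folds` | 5 | — | inner CV for the grid search |
| ensemble grid | trees {100, 300, 500}; depth {∞, 10, 30}; mtry {√p, 0.1·p}; min leaf {1, 3}; class weights {none, balanced} | — | standard forest ranges; balanced weighting is always a candidate because the spectrum classes are imbalanced |
| `threshold` | 0.5 | probability | default decision rule of the classifiers |

Every random stage (splits, fold assignment, fits, the naive draws, the
tie coin, the bootstrap) traces to one master seed through a
deterministic seed-derivation stream, so a whole pipeline run is
reproducible from a single integer; the run report records the seeds, a
hash of the configuration and package versions.

## Evaluation machinery

`confusionCounts()` treats bitter as the positive class and derives
precision, recall, specificity, accuracy, balanced accuracy and F1.
Zero-denominator ratios are reported as `NaN`, never silently as 0.

`averageCurves()` averages ROC or precision–recall curves over the
repeated splits: each repeat's curve is interpolated onto a common grid
(linear interpolation for ROC; the step-wise interpolated-precision
envelope for PR, which avoids the optimistic bias of linear PR
interpolation), and a 95% percentile bootstrap band for the *mean*
curve is computed by resampling repeats — the uncertainty quantified is
across splits, not within one test set. Per-repeat areas are
trapezoidal AUC (ROC) and average precision (PR).

`inferConfusionMatrix()` inverts rounded printed metrics: given class
sizes it enumerates all integer confusion matrices and keeps those
whose half-up-rounded metrics match every supplied value. Half-up
rounding (0.675 → 0.68) matches how published tables round, where base
R's `round()` rounds half to even. The enumeration is exact and cheap
(class sizes are at most hundreds), and when the solution is unique the
printed table determines the underlying counts exactly.

`binPopularity()` counts peaks (not spectra) per class in selected
bins, the companion view to feature importance: an important bin is
interpretable only together with which class populates it.

## The synthetic generator

`generateSynthetic()` emulates the structure of a curated spectral
dataset without emulating fragmentation physics:

- compounds carry a class label; bitter compounds draw more spectra per
  compound than nonbitter ones (the skew a combined EI + tandem
  collection exhibits, where tandem repositories contribute many
  spectra per compound), so spectra are bitter-dominated even when
  compounds are not;
- each spectrum mixes *shared* fragments (present in both classes),
  *class-specific* fragments included with probability `classSignal`,
  *compound-fingerprint* fragments (the reason spectra of one compound
  resemble each other — and the mechanism that makes spectrum-level
  splits leak), and Poisson-distributed uniform noise peaks;
- m/z values are jittered (Gaussian, sd 0.01 Th); intensities are
  log-normal (heavy-tailed, like real relative abundances) and then
  min–max normalized like ingested spectra; tandem spectra get positive
  mode and a collision energy, EI spectra mode-unknown and energy 0.

Defaults are fixed at a desk scale that mirrors the shape of a combined
collection — 60 bitter / 88 nonbitter compounds and a skewed
spectra-per-compound law giving roughly 450–500 bitter and 200–250
nonbitter spectra. Three presets bound the behavior: `"separable"`
(`classSignal = 1`; a correct pipeline approaches perfect held-out
metrics), `"null"` (`classSignal = 0` and identical per-class spectrum
counts; any honest estimate must hover at balanced accuracy 0.5), and
`"imbalanced"` (`classSignal = 0.05`, strong fingerprints; the leakage
demonstration). `permuteLabels()` provides the matching permutation
null on any dataset.

What passing on synthetic data does **not** show: real fragment
chemistry is not simulated (no isotope clusters, no neutral losses, no
correlated fragment series), m/z error is not instrument-calibrated,
and class-specific fragments in reality overlap heavily between classes
rather than being drawn disjointly. Synthetic results validate the
*pipeline* — leakage-freedom, featurization algebra, seed discipline,
recovery of plantable signal — not the achievable accuracy on real
spectra.

## Numerical choices and edge cases

- **Half-open bins, upper ownership.** A peak exactly on an edge
  belongs to the upper bin. Bin indices are computed as
  `floor((mz - origin)/w + 1e-9)`, the tolerance absorbing float error
  for values that are exact edges in exact arithmetic.
- **Degenerate normalization.** A spectrum whose peaks all share one
  intensity (including single-peak spectra) normalizes to all-100
  rather than all-0: the information "a peak is present" is preserved.
- **Strategy-1 rescaling is per spectrum**, using the bin vector's own
  min and max — it is that spectrum's descriptor vector that must live
  in `[0, 100]`.
- **m/z sort ties** break by descending intensity, for determinism.
- **Collision-energy text** ("35 eV", "5 to 70 eV") is coerced to its
  first numeric value — deterministic and recoverable; absent energies
  become 0.
- **EI-MS and the ion-mode filter.** EI records rarely state an ion
  mode; `filterSpectra()` exempts EI-MS from the positive-mode
  predicate so single-stage EI spectra are retained.
- **Label conflicts** between sources drop the compound with a warning:
  a taste label cannot be adjudicated automatically.
- **Grid-search ties** prefer the smaller ensemble, then the shallower
  tree — the less complex model at equal CV performance.
- **Naive-baseline metrics are computed over spectra** (the unit the
  baseline predicts); compound-level external evaluation goes through
  the majority vote.

## Problem sizes used in the test suite

The suite validates on generated data at deliberately small sizes:
featurization and voting properties on handfuls of spectra; classifier
properties on 24 + 24 compounds with 1–2 spectra each; the leakage and
null simulations on the full default generator (~150 compounds, ~700
spectra, 3–10 repeats). These sizes are chosen so each property is
decided by the construction, not by sampling luck, and the whole suite
runs in well under a minute.

## Known limitations

- Mass spectrometry is blind to chirality; enantiomers share spectra
  and cannot be distinguished, whatever the classifier.
- A frozen bin schema discards prediction-time peaks outside the
  trained m/z range; a model trained on a narrow range degrades on
  wider-scan instruments.
- The binning is uncalibrated: systematic m/z error larger than the bin
  width moves peaks into neighboring bins.
- Probability outputs are not calibrated; the 0.5 threshold and the
  majority vote are decision rules, not posterior statements.
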