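# bitterspec

Predicting whether a compound tastes bitter **directly from its
experimental mass spectrum**, without first assigning a chemical
structure.

## The problem

Bitterness is sensed through the TAS2R receptor family and matters for
food science, natural-product discovery and pharmacology. Machine-learning
bitterness predictors exist, but they start from a chemical structure —
and in metabolomics most detected features are never assigned a structure
(the "dark metabolome"): library search typically identifies only 5–10%
of spectra. `bitterspec` implements the alternative route: classify the
spectrum itself. It supports single-stage electron-ionization spectra
(EI-MS) and positive-mode electrospray tandem spectra (ESI-MS/MS).

## The method

For each spectrum, a descriptor vector is built in two parts:

1. **Instrument descriptors** — MS type and ion mode coded as natural
   numbers, plus the collision energy in eV (0 when unknown).
2. **Binned peak descriptors** — the m/z axis between the minimum and
   maximum training m/z is tiled by half-open fixed-width bins
   `[lo, lo + w)` (default `w = 0.1` Th). Three per-bin strategies are
   available: summed intensity (min–max rescaled back into `[0, 100]`
   when a bin total exceeds 100), binary presence, or peak count. Bins
   that contain no training peak are pruned and the schema is frozen
   into the model.

A tree ensemble (random forest via `ranger`, or gradient boosting via
`xgboost`) is trained on these vectors, with grid-searched
hyperparameters selected by five-fold cross-validation optimizing
**balanced accuracy** `BA = (recall + specificity) / 2` — the datasets
are class-imbalanced, so plain accuracy is misleading.

Two design rules carry most of the statistical weight:

- **Compound-level splitting.** A compound can contribute many similar
  spectra; a random spectrum-level train/test split leaks
  near-duplicates into the test set and inflates performance. All
  splits (and the inner CV folds) are therefore drawn by compound,
  stratified within class, repeated (default 20×) with per-repeat
  seeds. `compareSplitLevels()` demonstrates the inflation
  quantitatively on synthetic data.
- **Majority-vote aggregation.** At prediction time every spectrum of a
  compound is classified (bitter iff `p ≥ 0.5`) and the compound label
  is the majority vote, with exact ties resolved by a seeded fair coin.

A **naive baseline** that predicts bitter with probability equal to the
training prevalence (independent of the spectrum) anchors the metrics:
its expected balanced accuracy is 0.5, while its precision and recall
track the bitter fraction of the evaluation set.

Everything is testable offline through a synthetic generator of
class-conditional fragment spectra (shared, class-specific and
compound-fingerprint fragments, log-normal intensities, m/z jitter)
with controllable class signal.

## Worked example

```r
library(bitterspec)

d <- generateSynthetic(syntheticPreset("separable", seed = 42))
report <- runPipeline(d$labeled, repeats = 5, seed = 42,
                      params = list(num_trees = 300L))
print(report)
```

```
Pipeline report (5 splits, seed 42, config 6d2483a3)

Dataset composition:
      label n_compounds n_spectra
1 nonbitter          88       245
2    bitter          60       461

Test metrics (mean +/- sd over splits):
             metric mean sd
1         precision    1  0
2            recall    1  0
3       specificity    1  0
4          accuracy    1  0
5 balanced_accuracy    1  0
6                f1    1  0

Naive baseline on the same test splits:
             metric  mean    sd
1         precision 0.654 0.066
2            recall 0.639 0.067
3       specificity 0.368 0.047
4          accuracy 0.543 0.046
5 balanced_accuracy 0.504 0.043
6                f1 0.643 0.046

Mean ROC AUC 1.000; mean PR average precision 1.000
```

The synthetic "separable" preset plants disjoint class-specific
fragments in every spectrum, so a correct pipeline should approach
perfect held-out metrics — and the naive baseline, which ignores the
spectrum, stays at balanced accuracy ≈ 0.5 on the same splits. The
report also carries averaged ROC / precision–recall curves with 95%
bootstrap bands over the repeated splits, the best split's model and
its top-20 feature importances (percentages summing to 100, bins
labeled by their m/z interval).

Real data enter through `readMassBank()` / `readMsp()` →
`filterSpectra()` → `normalizeIntensities()` →
`attachSpectra(labels, spectra)`, or through the bundled command-line
front end:

```sh
inst/scripts/bitterspec ingest --format massbank --in records.txt --out spectra.tsv
inst/scripts/bitterspec run --spectra spectra.tsv --labels labels.tsv --seed 1 --out report/
inst/scripts/bitterspec predict --model report/model.rds --spectra new.tsv --out pred.tsv
```

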