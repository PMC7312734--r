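---
title: "ppiwave: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ppiwave: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiwave)
```

## The problem and the model

`ppiwave` predicts whether two proteins interact from their primary
sequences alone. The model has three stages, each with its own
assumptions:

1. **Physicochemical digitization.** Interaction propensity is assumed
   to be carried by the along-chain profiles of eight residue
   properties (H1, H2, V, P1, P2, SASA, NCI and the composite
   P = PI + u·pKa, u = ΣPI/ΣpKa). The 20×8 table ships with the
   package (`aa_property_table()`); each column is standardized to mean
   0, sd 1 *over the 20 amino acids*, using the population standard
   deviation (denominator 20) because the table is the complete
   population of standard residues, not a sample. The P column ships as
   tabulated; `compute_p_property()` lets users rebuild it from their
   own PI/pKa sources, since published PI/pKa tables differ.

2. **Wavelet summarisation.** Each of the eight signals is reduced to a
   fixed-length summary so proteins of different lengths become
   comparable: a 4-level dyadic DWT with the 62-tap discrete Meyer
   filter bank (details D1–D4 plus approximation A4 — the unique
   reading of "iterate the low-pass four times" that yields exactly
   five subsequences), each subsequence summarised by mean, sd, and the
   four largest-|value| coefficients with relative positions; plus the
   25 singular values of the L×25 Mexican-hat CWT matrix. The
   assumption is that multiscale energy placement along the chain —
   not residue identity per se — discriminates interacting pairs.

3. **Order-invariant pair classification.** The two 600-vectors are
   concatenated, each half consumed as a 75-step × 8-channel sequence
   by a bidirectional LSTM stack whose parameters are one shared
   storage for both branches. Concatenation order is an artefact, so it
   is neutralised twice: during training by forward/backward
   augmentation (every training pair also presented swapped; the split
   is exactly doubled, duplicates kept, test folds untouched — the
   package refuses to augment a test split), and at inference by
   averaging the scores of both orders, which makes deployed
   predictions exactly symmetric.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `rnn_units` | 512 | recurrent units per bidirectional layer, both directions combined (256 per direction), so the default audits to 512·2·2 = 2048 total units |
| `rnn_layers` | 2 | bidirectional layers per branch |
| `buffer_units` | 256 | width of the buffer layer joining the branches |
| `dense_units` | 32, 8, 2 | dense head; the final 2 units are the one-hot softmax output |
| `batch_size`, `learning_rate`, `epochs` | 128, 0.05, 200 | the reference training protocol |
| `momentum` | 0 | plain SGD by default; see "desk-scale protocol" below |
| `min_len`, `max_len` | 64, 1200 | closed-interval length filter; below 64 residues the 4-level dmey DWT (62-tap filter) is dominated by boundary padding, and the same bounds are the conventional benchmark filters |
| `noise_rate` (generator) | 0 | independent label-flip probability |

## Numerical choices

* **Boundary handling.** DWT and CWT are silent choices in most
  descriptions; here the DWT uses half-point symmetric extension
  (reflection including the edge sample), the common default that
  avoids edge spikes. Single-level output length is
  ⌊(L + 61)/2⌋.
* **CWT convention.** Integer scales 1..25; the Ricker wavelet at scale
  *a* is sampled on a centred integer grid of min(10a, L) points,
  L²-normalised, and applied by "same"-mode convolution — the
  convention popularised by `scipy.signal.cwt`. Rows are positions,
  columns scales; singular values are orientation-invariant anyway.
* **Subsequence statistics.** The sd is the population form (a
  length-1 subsequence has sd 0). Top-4 coefficients are stored
  *signed*, sorted by descending absolute value; ties resolve to the
  earlier index (stable). Subsequences shorter than 4 pad value/location
  slots with (0, 0) so the descriptor length stays fixed at 600.
* **Feature layout.** Per property: D1, D2, D3, D4, A4 blocks of
  (mean, sd, v1–v4, loc1–loc4), then sv01–sv25; properties in the order
  H1, H2, V, P1, P2, SASA, NCI, P. The ordering is a documented
  convention (`feature_layout()`); the recurrent consumer is agnostic
  to it but it is fixed for reproducibility.
* **Degenerate metrics.** Recall/specificity/precision with a zero
  denominator return 0 with a warning; MCC returns 0 whenever a factor
  under the radical is zero. Raw confusion counts are always carried in
  the report so any other convention can be recomputed. `sensitivity`
  is an alias of `recall` — they are one formula.
* **Classification threshold.** Class = argmax of the softmax
  (score > 0.5); an exact 0.5 tie resolves to non-interacting.
* **Gradients.** Backpropagation through time is implemented
  analytically and verified against central finite differences (cell
  level in the test suite; full network during development).

## Open design points and how they were resolved

* **How a 600-vector becomes a "sequence".** Nothing in the
  architecture description fixes this, so it is isolated behind
  `reshape_for_rnn()`: step *t* carries the *t*-th feature of each of
  the eight property blocks (75 steps × 8 channels), chosen because
  each property contributes exactly 75 features and the channels then
  have a consistent physical meaning. The inverse reshaping is exact.
* **Buffer realisation.** Per-branch shared affine+ReLU to 128 units
  each, concatenated to 256 (preserves branch symmetry); a single joint
  map is available via `buffer_mode = "joint"`.
* **"512 neurons" per bidirectional layer** is read as both directions
  combined (256 per direction), which is what makes the printed product
  512·2·2 = 2048 come out.
* **Optimizer.** The reference protocol names only batch size, learning
  rate and rounds; the package defaults to plain SGD at those values and
  exposes momentum. *Desk-scale protocol:* at the small problem sizes
  used by the tests and the acceptance script, plain SGD at lr 0.05
  moves too slowly to fit anything within 50 epochs, so those runs use a
  small architecture (16 recurrent units, 1 layer, 32 buffer units),
  batch 32, momentum 0.9, and early stopping at perfect training
  accuracy. These are training-protocol settings, not changes to the
  model.
* **Initialization.** Glorot-uniform everywhere, forget-gate biases at
  1 (standard recipe for trainable LSTMs); all randomness — init, batch
  shuffling, fold splits, simulation — flows from explicit integer
  seeds, so every fit and report is bit-reproducible.

## What the synthetic generator does and does not show

`simulate_ppi_data()` draws proteins from two residue-composition
archetypes (hydrophobic-rich vs charged-rich, own-group residues 3×
more likely) with lengths uniform on [64, 1200], and plants a symmetric
rule: same-archetype pairs interact. Labels can be flipped at a
configurable noise rate. Because the rule lives in sequence composition,
an end-to-end test exercises digitization, both wavelet stages, pair
construction and the classifier — not a shortcut feature.

The generator emulates *learnable compositional signal with a symmetric
pair rule*; it does **not** emulate real interactome topology (hubs,
degree distributions), homology between proteins, domain–domain binding
or the class imbalance of real screens. Passing its tests shows the
pipeline is implemented coherently and can learn a planted signal; it
says nothing about accuracy on HPRD/DIP-scale benchmarks, which require
the external datasets and the full 512-unit, 200-epoch protocol.

## Problem sizes used by the tests and the acceptance script

The study set is 60 proteins and 400 noise-free pairs (positive
fraction 0.5, seed-controlled); fivefold cross-validation with the
desk-scale protocol above completes in about a minute and, the planted
rule being noise-free and well separated, reaches perfect fold accuracy.
Unit tests use a 16-protein, 40-pair set. The acceptance script
additionally scores 100 freshly drawn hold-out pairs with the best CV
model. All quantities it reports are computed at run time from these
inputs.

## Known limitations

* Pure-R training: fine at desk scale, not intended for the 512-unit ×
  200-epoch × 10⁴-pair regime (use a GPU framework to reproduce
  benchmark-scale runs; the feature files written by `featurize` are
  framework-agnostic TSV).
* The dmey DWT is exact but the 62-tap filter makes subsequence lengths
  only weakly dyadic for short inputs; below 64 residues the features
  are padding-dominated, hence the hard lower length bound.
* Non-standard residues (B, J, O, U, X, Z) are rejected by default
  (`policy = "strict"`); lenient mode drops them with a warning. No
  imputation is offered on purpose.
* `generate_labels()` enumerates all protein pairs to sample without
  replacement; for very large `n_proteins` (≫ 5000) this is memory-heavy.
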