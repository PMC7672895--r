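---
title: "Fragment-based fold recognition: models, features, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based fold recognition: models, features, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Protein fold recognition asks which known structural fold (in the sense of
the SCOP hierarchy) a query amino-acid sequence will adopt. This package
implements a two-stage, fragment-based approach. The premise is linguistic:
if a protein sequence is a document, recurring backbone fragments of 4–20
residues are its words, and a fold is characterized by its vocabulary usage.

**Stage 1** classifies every sliding-window fragment of the query into one
of `n` structural fragment classes (100 in the default configuration). Each
window is represented by three feature groups — sequence composition (77
values), physicochemical properties (82), and evolutionary information from
the position-specific scoring matrix (1,600) — for 1,759 features in all. A
separate deep-belief-network stack is pretrained generatively on each group
(stacked restricted Boltzmann machines, contrastive divergence), their top
representations are concatenated and fused by a joint RBM, and a
fully-connected head (two layers of width 1,000) ends in a softmax over the
fragment classes. The whole network is then fine-tuned discriminatively.

**Stage 2** averages the per-window class distributions into a single
fragment vector per sequence — a fixed-length usage profile over the
fragment vocabulary — and classifies it with a small convolutional network:
a 1-D convolution (10 filters, kernel 10), overlapping max-pooling (width
10, stride 1), a stacking layer that arranges the 10 channel outputs as a
2-D map, a second convolution (100 filters of size 10×10 spanning the full
stack height), max-pooling of width 5 at stride 5, and two fully-connected
layers of width 100 before the fold softmax. For a 100-long fragment vector
the shapes run 100 → 91×10 → 82×10 → 10×82 → 1×73×100 → 1×14×100 → 1,400
flattened inputs to the head.

## Feature blocks

All blocks operate on a fragment (4–20 residues) and, for the evolutionary
group, on its PSSM rows. Fixed layout, 1,759 columns:

| block | dim | definition |
|---|---|---|
| group frequencies | 10 | fraction of residues in each of ten side-chain chemistry groups |
| information entropy | 2 | Shannon entropy (bits) of residue and overlapping-dipeptide distributions |
| residue distribution | 20 | mean relative position i/L of each residue type (0 if absent) |
| group transitions | 45 | frequency of adjacent residue pairs per unordered group pair |
| PseAAC | 40 | type-1 pseudo amino-acid composition, 20 composition + 20 correlation slots |
| wavelet statistics | 42 | 3-level Haar analysis of 3 property profiles, 14 statistics each |
| P-PSSM | 400 | mean sigmoid-transformed profile column per query residue type |
| PSSM-DC | 400 | averaged products of transformed scores at adjacent positions |
| bigram PSSM | 400 | products of softmax-normalized profile rows at adjacent positions |
| ED-PSSM | 400 | mean squared differences of transformed scores at lag d (default 1) |

Choices the printed dimensions force or leave open, and how they were
resolved:

* **Ten functional groups.** The partition {G}, {A,V,L,I}, {S,T}, {C},
  {M}, {P}, {F,W,Y}, {N,Q}, {D,E}, {K,R,H} — standard side-chain chemistry
  classes. Exactly ten groups is forced by the dimension 10 and by
  C(10,2) = 45 transition pairs. The partition ships as a text fixture
  (`inst/extdata/functional_groups.tsv`) and is swappable.
* **Relative positions** use 1-based i/L, so the final residue maps to 1
  and single-residue sequences are well defined.
* **PseAAC** uses the classic type-1 formulation with weight w = 0.05 and
  correlation factors over standardized Kyte–Doolittle hydrophobicity,
  Hopp–Woods hydrophilicity and monoisotopic side-chain mass
  (standardized to zero mean, unit population variance over the 20
  residues). The 40-wide layout reserves 20 correlation slots; because a
  fragment of at most 20 residues supports lags k ≤ 19, the default lag
  cap is 19 and unused slots are zero-padded, keeping the layout fixed
  across window lengths.
* **Wavelet block.** Profiles of hydrophobicity, flexibility
  (Bhaskaran–Ponnuswamy) and mean accessible surface area (Rose) are
  linearly resampled to 32 points — windows vary from 4 to 20 residues,
  and a fixed length makes the block length-invariant — then analysed with
  an orthonormal 3-level Haar transform. Per profile: mean, standard
  deviation and maximum of A3/D3/D2/D1, total energy, and the entropy of
  the normalized squared coefficients (3 × 14 = 42). Orthonormality makes
  the block testable: the coefficient energy must equal the resampled
  signal energy (Parseval), which the suite checks on random fragments.
* **Evolutionary blocks.** Scores pass through a logistic transform
  1/(1+e^−s) rather than per-profile min–max scaling, which would depend
  on a 4-residue window's own extremes and break comparability across
  fragments. PSSM-DC and bigram-PSSM are deliberately distinguished by
  their input normalization (sigmoid + length averaging vs softmax row
  distributions without averaging) so the two 400-blocks are not
  duplicates; the bigram block consequently sums exactly to L−1 and is
  invariant to adding a constant to all scores, while the sigmoid blocks
  are not — both directions are property-tested.

## Training protocol and numerical choices

* Optimizer Adam, package-default learning rate 1e-4, batches of 500
  (clipped to the data size), dropout 0.5 after every hidden layer, early
  stopping on a stratified validation split (patience 10 epochs, minimum
  improvement 1e-4), best-validation parameters returned.
* RBM pretraining uses logistic units — contrastive divergence requires a
  probabilistic unit — with Gaussian visible units for the standardized
  first layer and Bernoulli units above; the leaky-ReLU activation
  (slope 0.01, one package-wide constant) applies to the fine-tuned
  network and the CNN.
* Convolutions use no padding; the pooling height of MP2 is clipped to
  the map height (1) left after the full-height second convolution. The
  printed kernel widths make ~32 the shortest fragment vector the default
  stack accepts; the constructor reports the full shape pipeline when an
  input is too short.
* Feature columns are standardized with training-set statistics stored in
  the checkpoint; columns with zero variance pass through unscaled.
* Ties in the fold argmax break toward the lowest fold index.
* All randomness flows from one integer seed per run; training is
  bit-reproducible given (seed, config, data order), and inference is
  deterministic (dropout only in training mode).

## Synthetic data: what it emulates and what it does not

`make_fragment_library()` draws, per class, a random consensus sequence of
4–20 residues; each sample copies the consensus residue with probability
`motif_strength` (default 0.9 in the recovery experiments) and otherwise
draws uniformly from the other 19 letters. `synth_pssm()` forms profile
rows as BLOSUM62 log-odds of the sequence plus rounded Gaussian noise
(sd 1 by default) — plausible in scale and integer-valued like the ASCII
dialect. `make_fold_dataset()` concatenates fragments drawn from a
per-fold mixture over classes until a target length is reached, truncating
the last fragment.

This emulates exactly the structural premises of the method — fragment
classes with a sequence signal, folds as fragment-usage mixtures — and
nothing else. Real data differ in ways the generator does not model:
fragment classes are defined by backbone geometry and are not in
one-to-one correspondence with sequence motifs; real PSSMs carry
position-dependent conservation structure from database searches, not
i.i.d. noise around a substitution matrix; real folds share fragments and
have highly unequal usage. Passing the recovery experiments therefore
demonstrates that the pipeline's machinery (features, training,
aggregation, classification) can extract class structure that is present;
it says nothing about accuracy on real fold benchmarks, which additionally
requires the real fragment library and database-derived profiles.

## Desk-scale experiment design

The reference experiments in `R/benchmarks.R` are sized for a single CPU:

* Stage-1 recovery: 10 classes × 100 samples, motif strength 0.9,
  stratified 80/20 split; reduced widths (sequence 77→64→32, physchem
  82→64→32, evolutionary 1600→128→64, fusion 64, head 64).
* End-to-end: a 40-class × 50-sample library (40 classes keep the
  fragment vector long enough for the full convolutional stack), four
  folds with disjoint block mixtures, 25 sequences of 25–40 residues per
  fold, stratified 75/25 split.
* These runs use Adam's canonical step size 1e-3 with 150–300 epochs: a
  desk run takes on the order of a thousand optimizer steps, where the
  full-scale protocol's 1e-4 step is appropriate for millions. The
  package-wide default remains 1e-4.
* The label-shuffled negative control re-trains stage 1 on permuted
  labels and must score at the class prior on held-out data, guarding
  against leakage through the pipeline.

The vignette states no measured numbers; the recovery accuracies are
computed, from scratch, by the test suite and by
`scripts/acceptance.R`.

## Known limitations

* The exact functional-group partition, wavelet statistic set and
  property tables behind the published feature dimensions are not
  recoverable from their printed dimensions alone; the implementations
  match every printed dimension but not necessarily the original values.
* The four evolutionary blocks' normalization constants are similarly
  under-determined; the definitions here are fixed, documented and
  oracle-tested.
* CD-based pretraining of wide layers is slow in pure R; the default
  widths (1,000×1,000 head) are practical for inference and contract
  checking, while training experiments use the reduced widths above.
* The stage-2 network sees only fragment usage: interactions between
  distant fragments are represented only insofar as pooling windows
  overlap, a structural limit of the architecture.
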