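---
title: "Detecting ligand-binding regions and drug-target interactions from sequence"
author: "hots package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ligand-binding regions and drug-target interactions from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hots)
```

## The problem

Most sequence-based drug-target interaction (DTI) predictors treat the
protein as a bag of motifs and give no account of *where* a compound acts.
This package implements a model that couples the two questions: it
predicts **binding regions (BRs)** - contiguous stretches of protein
sequence containing the residues that contact a ligand - as a
one-dimensional object-detection problem, and reads the drug-target
interaction probability off the same network. Training the detector first
and then fine-tuning for interaction prediction lets the DTI head
concentrate on the sequence regions that actually bind, and the
transformer attention over those regions is itself an interpretable
output.

## From binding information to binding regions

Residue-level binding annotations (BI) derived from 3D complexes are
sparse and often discontiguous. Each binding residue is therefore expanded
to a window of `expansion_length = 9` residues centred on it, windows are
clipped at the sequence boundaries, and overlapping or touching windows
are merged ([expand_and_merge()]). The result is a set of disjoint,
sorted intervals - the detection ground truth. We store intervals 0-based
half-open (BED-like) internally and convert 1-based inclusive residue
indices at every file boundary.

During training each ground-truth region is replaced by a random jitter
with intersection-over-union of at least 0.7 ([jitter_br()]): the shift is
uniform within half the region width and the width is rescaled by a
uniform factor in [2/3, 3/2], rejection-sampled against the IoU floor.
This augmentation teaches the detector that region boundaries are fuzzy.

## The network

A protein of length $L$ is embedded per residue and passed through 1D
convolutions with several window sizes (motif detectors of different
spans). The sequence is then split into grids of `grid_size = 25`
residues and each filter's maximum within each grid is pooled, giving
$\lceil L / \texttt{grid\_size} \rceil$ grid encodings after a dense
projection to $H$ dimensions. The compound is a 2048-bit circular
(Morgan, radius 2) fingerprint mapped through a dense layer to an
$H$-dimensional *compound token*. The token is prepended to the grid
encodings, sinusoidal positional encodings are added, and the sequence of
$1 + \lceil L / \texttt{grid\_size}\rceil$ vectors passes through
post-norm transformer blocks, so every grid can condition on the compound
and on every other grid.

Detection follows the anchor-based single-shot recipe: for each grid $g$
and each anchor width $r_i$ (defaults 9, 15, 21), dense layers emit
sigmoid outputs $(c_g, w_g, p_g)$, reconstructed as

$$\mathrm{Center}_g = s_g + \mathrm{size}_{grid} \cdot c_g,
\qquad \mathrm{Width}_{ig} = r_i e^{w_g},$$

where $s_g$ is the grid start. Because all three outputs pass through a
sigmoid, an anchor can only decode widths in $[r_i, r_i e)$; the anchor
set must therefore tile the useful width range with consecutive ratios
below $e$ (checked at configuration time). Ground truth is assigned
YOLO-style: a region is the responsibility of the grid containing its
centre, with the anchor whose clipped log-ratio target decodes to the
width of maximal IoU with the truth; ties go to the least-stretched
anchor. A second region with a centre in the same grid takes its next-best
free anchor, and is dropped with a warning only when every anchor of the
grid is taken.

The detection loss is

$$L(c, w, p) = \lambda_{reg}\left(|c_{true} - c_{pred}|_1 +
|w_{true} - w_{pred}|_1\right) + \lambda_{conf}\,\mathrm{FL}(p_t),
\qquad \mathrm{FL}(p_t) = -(1 - p_t)^\gamma \log p_t,$$

with the L1 terms averaged over responsible cells and the focal term over
all valid grid-anchor cells. Binding regions cover a small fraction of a
protein, so almost all cells are negatives; the focal factor
($\gamma = 2$ by default) down-weights the easy negatives that would
otherwise dominate the confidence gradient.

For DTI prediction the full token+grids sequence continues through
additional transformer blocks and the compound-token position is read out
through dense layers and a sigmoid into $P_{DTI} \in (0,1)$. The
displayed readout equation feeds only the compound token forward; since
self-attention still needs keys and values, the DTI blocks attend over
the full sequence by default and only the token position is read out
(`dti_mode = "full"`); a pure token-only readout stack is available as
`dti_mode = "token"`.

Everything - embedding, convolutions, pooling, transformer blocks with
multi-head attention and layer norm, both heads, the focal and L1 loss
gradients, and the Adam optimizer with global-norm clipping - is
implemented in plain R matrix code in this package. The backward pass is
checked against central finite differences for every parameter tensor in
the test suite, which is the strongest correctness evidence a hand-rolled
network can give. One implementation note: because convolution inputs are
embedding rows selected by residue code, each window's convolution is
evaluated through per-shift lookup tables ($E_t = \mathrm{emb}\,W_t$,
rebuilt once per optimizer step), which turns the convolution into row
gathers and its backward pass into per-code pooled sums; this is exact,
not an approximation.

## Training scheme

Training is staged, mirroring the two datasets' roles:

1. **BR pre-training** ([pretrain_br()]): encoder, BR blocks and
   detection head are trained on (protein, compound, BR) records with
   jitter augmentation; validation AP is tracked each epoch and the
   best-AP weights kept.
2. **Alternating fine-tuning** ([finetune_alternating()]): cycles of 3 BR
   epochs followed by 1 DTI epoch (the BR dataset being the smaller of
   the two). DTI epochs minimize binary cross-entropy on $P_{DTI}$
   through *all* weights - the BR stages are deliberately not frozen,
   which is why BR validation AP can dip after the first DTI epoch before
   both metrics converge together. BR epochs never touch the DTI blocks
   or head; the trainer snapshots those weights around every BR epoch so
   the invariant is auditable (`weight_log`).

DTI labels are binary, so the DTI loss is cross-entropy; negatives are
random non-interacting pairs at a 2:1 negative:positive ratio. Adam is
used throughout (learning rate 1e-3, global-norm gradient clip 5). Three
optimization choices matter at desk scale and were settled empirically:

* **Small batches.** Batch 8 for detection and batch 4 for DTI epochs -
  many optimizer steps per epoch - roughly doubled learning per epoch
  relative to batch 32 at slight extra cost.
* **Discriminative rates in DTI epochs.** A DTI epoch updates the DTI
  blocks/head and the compound-token projection at the full rate, and
  everything else (embedding, convolutions, BR blocks) at a tenth
  (`shared_lr_factor = 0.1`). Every weight is still fine-tuned - the BR
  stage is deliberately not frozen - but without the scaling the two
  alternating objectives destructively interfere: each DTI epoch wrecks
  detection AP and each BR phase erases the DTI progress. With it,
  detection is maintained while interaction learning accumulates in the
  blocks the BR phases never touch.
* **Validation-selected checkpoint.** Detection AP characteristically
  dips right after a DTI epoch and recovers over the following BR
  epochs, so `finetune_alternating()` scores the validation AP and AUROC
  both after each cycle's BR phase and after its DTI epoch and returns
  the best state (`keep_best`), rather than whatever state the last DTI
  epoch left behind.

Early stopping in pre-training uses patience 10 on validation AP.

## Evaluation

* **Average precision** ([average_precision()]): predictions from all
  complexes are pooled and sorted by confidence; a prediction is a true
  positive when its IoU with a still-unmatched truth region of its
  complex reaches 0.5. Precision is interpolated with
  $p_{interp}(r) = \max_{\tilde r \ge r} p(\tilde r)$ and AP is the area
  under the interpolated curve (an interpolated AUPR). We pool across
  complexes rather than averaging per-complex APs, matching the
  collect-then-sort definition.
* **Top-n success** ([topn_success()]): per complex, the $n$ (+2)
  highest-confidence predictions are taken, $n$ being the complex's
  number of interacting-ligand records; a truth region is hit when a
  selected prediction covers at least half of it - a coverage criterion,
  deliberately distinct from the IoU used for AP. The per-complex score
  is the fraction of its truth regions hit (an any-hit variant is
  available), averaged over complexes.
* **DTI metrics** ([dti_metrics()]): AUROC, AUPR, and threshold-0.5
  accuracy/precision/recall/specificity/F1.
* **Similarity audit** ([sw_norm()], [similarity_report()]): normalized
  Smith-Waterman similarity
  $\mathrm{SW}(p,p')/\sqrt{\mathrm{SW}(p,p)\,\mathrm{SW}(p',p')}$
  (BLOSUM62, gap open 10, extend 0.5) quantifies train/test relatedness;
  for a sequence-only method this is the main confound to report.
  Alignment itself is delegated to Biostrings; the test suite checks it
  against an independent affine-gap dynamic program.

Decoded predictions are real-valued intervals, so IoU and coverage are
computed on continuous spans - predictions are never rounded to integer
residues. Greedy non-maximum suppression (IoU 0.5, configurable) removes
near-duplicate detections from adjacent grids before top-n selection;
without it one binding site would fill several top-n slots.

## Attention analysis

To ask where the compound token looks, the per-head attention matrices of
a chosen block (default: the first BR block) are extracted for each
complex; the token's query row over grid keys is reduced by the maximum
over heads, and the maximum over BR-labelled grids and over non-BR grids
are collected per complex ([collect_max_attention()]). A grid is
BR-labelled when it overlaps any truth region. One caveat learned from the
desk-scale model: which block carries the "token concentrates on its
binding regions" signal depends on the depth budget. With a single BR
block and a single DTI block, the aggregation role lives in the DTI block
- its token row shows a far higher attention Gumbel location on BR grids
than on non-BR grids (the acceptance script recomputes both fits and the
KS contrast) - while the lone BR block's token row serves the grid-side
conditioning and can even show the opposite polarity. The block is
therefore an explicit argument of every analysis function, and the
package's end-to-end analyses read the aggregation (DTI) block. Per-complex maxima are
extreme values, so Gumbel distributions are fitted to both samples by the
method of moments ($\beta = s\sqrt{6}/\pi$,
$\mu = \bar x - \gamma_E \beta$) - closed-form, and directly testable by
parameter recovery ([fit_gumbel()]). The BR/non-BR contrast is assessed
with a two-sample Kolmogorov-Smirnov test on the raw samples (a KS test
between two *fitted* curves has no sampling distribution, so we test the
samples). [export_circos()] serializes one head's attention as a
Circos-style edge list, keeping weights down to the 10% quantile cutoff
("upper 90%", ties retained) with sectors classed compound / BR / non-BR.

## The synthetic corpus

All tests and the acceptance script run on corpora from
[generate_corpus()], built so that binding has a known, planted cause:

* background residues are uniform over the 20 amino acids;
* each of `n_motifs = 8` motifs has a consensus of length 10-14 (drawn
  within the 6-15 range the motif model allows; the narrower default
  keeps a 70%-identity scan unambiguous, see below) and pairwise
  consensus identity below 50%;
* each protein carries `motifs_per_protein = 2` distinct motifs, each as
  1-3 copies mutated at per-position rate 0.05 but capped at 30% of the
  motif length, so every planted copy retains at least 70% identity;
* each motif is linked to one compound whose fingerprint sets a dedicated
  32-bit block (blocks disjoint across compounds) plus 2% Bernoulli noise
  bits outside all blocks;
* ground-truth BI are the planted copy positions; BRs are their
  expand-and-merge; positive DTIs are the planted (compound, protein)
  pairs and negatives are sampled 2:1 from pairs whose protein shows no
  70%-identity window for the compound's motif.

The conservation floor and the negative screen make motif presence and
the DTI label *exactly* equivalent, so an independent scan oracle must
agree with every label - a property the test suite asserts. What the
corpus does not emulate: real secondary-structure context,
position-specific conservation, homology between proteins, real
chemistry behind fingerprints, and label noise. Passing the end-to-end
tests therefore shows the machinery can recover a planted sequence-level
binding rule at desk scale, not that it reaches the published performance
of the full-scale model on curated complex databases - those require the
original training corpora and days of training.

## Numerical choices and degenerate inputs

* Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside logs; width
  targets are clipped to `[0, 1 - 1e-3)`.
* Even expansion windows place the residue left of centre (offset
  `floor((e-1)/2)`), defined although the default window (9) is odd.
* Expansion windows are clipped at sequence boundaries (not shifted), so
  boundary regions may be narrower than the window.
* Attention ties and equal confidences are broken deterministically
  (complex id, then start) so every metric is reproducible.
* An empty truth set yields an all-negative detection tensor; a BR whose
  grid has no free anchor is dropped with a warning; jitter falls back to
  the unjittered region after 200 rejections, with a warning.
* Sequences longer than `max_len` are truncated with a warning rather
  than rejected.

## Desk-scale study conditions

The end-to-end runs in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use a corpus of 500 proteins of length 200-400
with 8 motifs (seed 7) split 9:1 by protein, and a small model:
$H = 32$, one BR block, one DTI block, residue embedding initialized to
the 21-symbol one-hot basis, 16 filters per window. The schedule is 16
pre-training epochs followed by 5 alternating cycles. The 5-seed
pre-training ablation in the test suite replicates the
with/without-BR-pre-training contrast on a 120-protein corpus with a
shortened schedule, matching DTI epoch counts between arms (the
acceptance script runs the full-size single-seed ablation). These sizes
were chosen so the whole study runs in minutes on one CPU while leaving
every qualitative contrast (detection above chance, pre-training helping
DTI, attention concentrating on BRs) intact.

## Known limitations

* Fingerprints must be precomputed (TSV) or synthetic; SMILES
  featurization is not bundled.
* One box per anchor per grid; proteins with more distinct binding
  regions per grid than anchors will drop targets.
* The per-grid responsibility scheme cannot represent two regions whose
  centres fall in one grid and whose widths suit the same anchor.
* CPU-only, desk-scale training; no GPU kernels or distributed training.
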