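---
title: "Detecting intrinsic terminators with structure-aware CNNs: models and methods"
author: "termscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intrinsic terminators with structure-aware CNNs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termscan)
```

## The problem

Intrinsic (rho-independent) transcription terminators end bacterial
transcription without accessory proteins. Their hallmark is a GC-rich RNA
hairpin followed by a U-rich tract: the polymerase pauses on the U-tract,
the hairpin forms and destabilises the elongation complex. A detector
therefore has two kinds of evidence available — *sequence composition*
(A-rich upstream tract, U-rich downstream tract, GC-rich stem) and
*base-pairing structure* (the stem's complementarity). `termscan` implements
classifiers over both evidence channels, a pre-training scheme that teaches a
network structure before it ever sees a real terminator, an in-silico
mutagenesis framework that measures which evidence a trained model actually
uses, and a genome-scale scanning and evaluation pipeline.

## Input encodings

Two encodings of a fixed-length RNA window (default `L = 75` nt) feed the
two model topologies:

* **One-hot** (`one_hot_encode()`): an `L x 4` indicator matrix with column
  order A, C, G, U. This encoding exposes composition but carries no
  explicit pairing information. `N` encodes as an all-zero row so scans
  tolerate assembly gaps.
* **Pairing matrix** (`pairing_matrix_encode()`): the `L x L` matrix of
  pairwise pairing potentials, weighting G–C with 1, A–U with 0.66 and the
  G–U wobble pair with 0.33; all other combinations are 0. The matrix is
  symmetric over unordered base pairs and its diagonal is zero. A hairpin
  stem appears as a short anti-diagonal streak of high weights.

Two notes on the pairing matrix. First, positions closer than the minimum
hairpin loop are *not* masked: the model is left to learn steric
constraints. Second, reverse complementation anti-transposes the canonical
(G–C, A–U) entries but not the wobble entries, because {G,U} maps to {C,A}
under complementation; the encoding is faithful to pairing chemistry, which
is itself not closed under complementation.

## Model topologies

Both classifiers share one head (`model_config()`, `build_model()`):

* convolution with 30 filters, kernel size 10, ReLU;
* max pooling with pool size 5, dropout 0.2;
* dense 360 (ReLU) → dense 30 (sigmoid) → single sigmoid output.

The one-hot CNN convolves along the sequence with 4 input channels (1230
convolution parameters); the matrix CNN applies a 10×10 kernel and 5×5
pooling to the pairing matrix (3030 convolution parameters), all other
parameters equal, which makes the pair directly comparable: any performance
gap is attributable to the input representation.

Training (`train_model()`) minimises binary cross-entropy with Adamax
(learning rate 0.002, β₁ = 0.9, β₂ = 0.999), shuffled minibatches (default
32) and early stopping on test-set accuracy with patience 5; the best-epoch
weights are restored. Epoch caps, batch size and patience are configurable;
the loss, optimiser defaults and patience are package choices where the
method description is silent. The layers are implemented in the package
itself on single-precision BLAS kernels (im2col + GEMM); correctness is
pinned by tests comparing analytic gradients against an independent
double-precision reference implementation, and parameter counts against
closed forms. Weight initialisation follows the Glorot-uniform convention
with convolution fans counted per kernel tap and filter — with
substantially larger initial convolution weights the matrix CNN reliably
collapses to the majority class, which is worth knowing when reproducing
this class of models.

## Secondary structure: folding and inverse folding

The package's internal folder (`fold_nussinov()`) is a weighted
maximum-pairing dynamic programme: G–C scores 3, A–U 2, G–U 1, minimum
hairpin loop 3 nt, pseudoknots excluded, with a deterministic traceback
(pairing preferred over leaving the 5′ base unpaired at equal score,
leftmost partner first). It deliberately is *not* a thermodynamic model: it
is dependency-free, fast, and exactly testable against brute-force
enumeration of all nested structures for short sequences. Production users
who want nearest-neighbour energies can switch the inverse-folding backend
to ViennaRNA's `RNAinverse` (`backend = "external"`), for which an adapter
is included.

Inverse folding (`inverse_fold()`) searches for a sequence whose fold
matches a target dot-bracket structure. The internal backend is a
defect-directed stochastic local search implemented in C++:

1. start from a random pairing-compatible draw (paired positions receive a
   GC-biased complementary dinucleotide);
2. each iteration proposes either a compensatory resampling of a target
   pair, a repair of a specific defect (a spurious pair is broken by
   substituting a base that cannot pair its partner, with a bias toward A;
   a missing pair is resampled compensatorily), or a random single-base
   change;
3. a candidate is accepted if its base-pair distance to the target does not
   increase;
4. after 1500 non-improving iterations the search restarts from a fresh
   draw, alternating a diverse random draw with a deliberately tie-poor one
   (G–C-only stems over an all-A background).

The restart schedule matters: under a maximum-pairing objective, multiloop
linkers compete with genuine stems for pairing partners and single-defect
moves can be trapped on plateaus where every repair invites an equal-weight
rearrangement. Tie-poor draws avoid those plateaus at the cost of sequence
diversity, which is why they are used only for restarts. A search that does
not reach distance 0 within `max_iter` (default 20 000) returns its best
sequence with the distance reported honestly rather than raising an error.

`generate_pretraining_set()` turns a list of target structures into a
labelled pre-training dataset: positives are inverse-folded round-robin
over the targets, negatives are uniform-random sequences with a matched
length multiset, and the set is split 85 % / 15 % into a pre-training part
and a held-out part used solely to early-stop the pre-training.
`pretrain_finetune()` then seeds the main training with the pre-trained
weights. How many sequences were drawn per source structure in the original
formulation is not documented; round-robin with equal weight per structure
is this package's choice.

## Synthetic data: what it emulates and what it does not

Every module is testable without downloads through the generator family
(`make_terminator()`, `make_trna_like()`, `make_genome()`,
`make_transcripts()`). An annotated synthetic terminator has seven
contiguous sections — `left_pad`, `a_tail`, `stem5`, `loop`, `stem3`,
`u_tail`, `right_pad` — over a 75-nt window, with the dot-bracket structure
pairing stem positions in mirrored order. Defaults: A-tail 6–10 nt with
80 % A, stem 4–8 bp with 80 % G–C pairs, loop 3–6 nt, U-tail 6–10 nt with
80 % U, pads uniform random, split symmetrically with the extra base on the
3′ side. These are plausible values for the elements' biology, not fits to
any curated collection; real terminator sets differ in length and
composition distributions, so passing synthetic benchmarks demonstrates
correct mechanics and learnability, not field performance.

Candidate terminators are redrawn until the folder's maximum-pairing
structure *contains* every annotated stem pair (rejection sampling,
typically one or two draws). Containment rather than exact structure
equality is deliberate: random pads of a 75-nt window almost always admit
at least one additional spurious pair under a maximum-pairing objective, so
requiring base-pair distance 0 between the annotation and the fold would be
unsatisfiable; what matters for the classifier is that the annotated
hairpin is actually realised. The same consideration applies to tRNA-like
records, whose inverse-folded 72-nt cloverleaf core refolds exactly to the
template while the 95-nt padded record annotates its flanks as unpaired.

Synthetic genomes implant terminator cores (pads stripped, so genomic
context is the genome itself) at non-overlapping uniform positions in an
i.i.d. uniform background; the termination site of an element is the
3′-most base of its U-tail, and transcripts extend each element by random
flanks clamped at neighbouring elements, so each element lies inside
exactly one transcript. Minus-strand implantation is available behind a
flag and off by default.

## In-silico mutagenesis

The interpretability framework perturbs annotated terminators and measures
the model's response (all coordinates 0-based, half-open):

* **Section mutations** (`mutate_section()`): `floor(len/2)` positions
  (at least 1) inside one of the seven sections are each replaced by a
  different random base. The *relative activation impact* of a section is
  `1 − x̄S/x̄0`, the relative drop of the mean model output on mutated
  versus original sequences (`section_impact()`, default 15 mutants per
  sequence and section).
* **Structure mutations** (`mutate_stem_pairs()`): `k` stem pairs are
  chosen; both bases of each chosen pair are replaced, either *retaining*
  pairing (a different canonical/wobble dinucleotide with both positions
  changed — feasible for every starting pair, as enumeration over the six
  pair types shows) or *disrupting* it (a non-pairing dinucleotide, both
  positions changed). The impact of stem stability is `1 − x̄d/x̄r`
  (`structure_impact()`). Because both fates change the same number of
  bases, composition effects cancel and the contrast isolates pairing.
* **Detection impact** (`detection_impact()`): the same formulas applied to
  the *detection rate* (fraction of sequences with at least one hit) of any
  external detector exposed as a hit-count function, mirroring how binary
  terminator finders are compared against the continuous models.

The reference output `x̄0` is computed once per sequence; it needs no
mutation replicates. Analytic scorers with closed-form impacts
(`intact_stem_fraction_scorer()`: disrupt impact at `k` equals
`k/stem_length`; `section_identity_scorer()`: section impact 0.5) pin the
whole pipeline down in tests.

## Genome scan and evaluation

`scan_transcriptome()` extends each transcript by 150 nt on both ends
(clamped at contig boundaries), extracts the sense strand, slides a 75-nt
window at step 3 nt, and fuses maximal runs of windows with model output
above 0.5 at *adjacent step positions* into hits — one sub-threshold window
breaks a run, the package's reading of "neighbouring" hits. A hit carries
the maximal score of its run and the central nucleotide of the fused span.

`evaluate_scan()` compares hit centers with termination-site positions at
distance thresholds of 10, 15, 35, 50, 100, 150 and 250 nt: a hit within
the threshold of its nearest site is a true positive, otherwise a false
positive; a site with no hit within the threshold is a false negative.
Matching is not one-to-one — several hits may credit one site, and recall
counts distinct detected sites, which is the reading consistent with the
false-negative definition. The precision–recall curve sweeps a secondary
cutoff over the fused-hit scores (the 0.5 call threshold stays fixed), and
AUPRC is its average precision. `positional_profile()` averages window
scores by offset to the nearest site, which for synthetic genomes peaks
upstream of the site — where the hairpin sits relative to the 3′ end.

## Numerical choices and degenerate inputs

* Pair weights 3/2/1, minimum loop 3 nt, deterministic leftmost traceback.
* Average precision is the stepwise sum `Σ (Rᵢ − Rᵢ₋₁) Pᵢ` over distinct
  score thresholds in decreasing order; a constant scorer yields the
  positive prevalence exactly.
* `compare_models()` (two-sided Wilcoxon rank-sum) enumerates the exact
  tie-aware permutation distribution for combined samples up to 12 and
  otherwise uses the tie-corrected normal approximation without continuity
  correction; identical samples give p = 1.
* Monte Carlo splits use largest-remainder apportionment so part sizes are
  deterministic; replicate `r` derives its own sub-seed, so any single
  replicate is reproducible in isolation.
* All sources of randomness go through an explicit seed; the RNG state of
  the caller is always restored. Network training is bitwise reproducible
  on a fixed BLAS.
* Empty regions shorter than one window scan to zero windows with a
  warning; a single-class validation set, an empty site list, and a
  zero reference activation are errors rather than silent NaNs.

## Problem sizes used by the test-suite and acceptance script

The shipped checks run scaled-down analogues of the full experiments: a
synthetic classification task with 600 positives and 1800 negatives
(L = 75, threefold negatives, ten Monte Carlo replicates at 0.70/0.15/0.15);
a pre-training set of 300 inverse-folded positives over 10 synthetic stem
structures, pre-trained for one epoch (the structure task saturates its
held-out accuracy within a single epoch at this scale, and further
pre-training over-sharpens the sigmoid head, which destabilises
fine-tuning) and fine-tuned for up to 8 epochs (patience 4, batch 64); and
a 50-kb genome with 20 implanted terminators for the end-to-end scan. The
scan uses a dedicated plain matrix CNN trained on a larger matched
synthetic set (1200/3600, 85/15 train/early-stop split, up to 16 epochs):
fused hit calling applies the absolute 0.5 output threshold, so the
detector must be calibrated and specific, and models early-stopped on an
accuracy plateau rank well but score everything below 0.5.

## Known limitations

* The maximum-pairing folder ignores stacking energies and temperature;
  structures with isolated pairs or long-range pairings are handled less
  realistically than by a thermodynamic model. The external RNAinverse
  backend exists for exactly that reason (its RNG is not seedable from R,
  so external-backend runs are not bitwise reproducible).
* Synthetic negatives are uniform random; real genomic background has
  skewed composition and repeats, so false-positive rates on real genomes
  will be higher than synthetic benchmarks suggest.
* The LSTM topology discussed alongside these CNNs in the literature is out
  of scope; the model interface (`build_model()` / scorer functions) is the
  extension point.
* Scans run on the sense strand of annotated transcripts only; de novo
  minus-strand discovery requires scanning the reverse complement, which
  the region preparation supports but the default pipeline does not do.
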