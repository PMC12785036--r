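---
title: "Classifying transposable-element consensus sequences with a sparse-attention encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transposable-element consensus sequences with a sparse-attention encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

De novo repeat discovery produces libraries of consensus sequences for
candidate transposable-element (TE) families, but assigning each consensus to
a superfamily is hard: TE sequences are extremely diverse, often ancient and
decayed, and homology search fails for families with no close relative in
curated databases. `wickerformer` treats the assignment as a sixteen-class
sequence classification problem over the Wicker superfamilies (Copia,
Crypton, ERV, Gypsy, hAT, Helitron, Jockey, L1/L2, Maverick, Merlin, P, Pao,
RTE, SINE, TcMar, Transib), each rolled up to its order (LTR, LINE, SINE,
TIR, Crypton, Helitron, Maverick).

## Model

The classifier is an encoder-only transformer over k-mer tokens with a
linear classification head.

**Tokenization.** Sequences over \{A,C,G,T,N\} are cut into overlapping
k-mers (default k = 5, giving a compact vocabulary of $5^5 = 3125$ tokens
plus PAD/CLS/UNK) by a sliding window whose step dilates with input length:

$$\mathrm{step} = \mathrm{clamp}\!\left(\lceil \mathrm{len}/\mathrm{max\_embeddings} \rceil,\; 2,\; k-1\right).$$

The lower bound of two nucleotides keeps coverage dense for short inputs;
the upper bound $k-1$ guarantees consecutive tokens still overlap by at
least one nucleotide, so no position is skipped. Inputs whose token count
exceeds the embedding budget (default 2048, one slot reserved for the CLS
anchor) are processed as consecutive non-overlapping chunks, and the
sequence-level class distribution is the element-wise **median** of the
chunk distributions, renormalized to sum to one. Medians of probability
vectors need not be probability vectors, hence the renormalization; the
median (rather than the mean) makes the aggregate robust to a single
off-distribution chunk, e.g. one dominated by a nested insertion.

**Attention.** Self-attention is restricted to a sliding local window
(token $i$ attends $j$ iff $|i-j| \le w/2$), except at designated
global-attention positions, which attend to and are attended by every
token. Global positions are 0-based coordinates in the CLS-prefixed chunk,
default `c(0, 256, 512)`; position 0 is the CLS anchor, whose final
representation feeds the head. This reduces the quadratic attention cost to
near-linear for long inputs while keeping a path for long-range
dependencies — the property that matters for long LTR elements whose
terminal repeats sit thousands of nucleotides apart.

**Positional encoding.** The standard fixed sinusoidal form,
$PE_{pos,2i} = \sin(pos/10000^{2i/d})$, $PE_{pos,2i+1} = \cos(pos/10000^{2i/d})$,
added to the token embeddings. Its values lie in $[-1, 1]$ (descriptions of
this scheme as ranging "between zero and one" appear in the literature, but
the cited sin/cos form is signed; we implement the standard form).

**Loss.** Training minimizes weighted cross-entropy,
$\ell = -w_{y}\log p_{y}$, because real TE libraries are strongly
imbalanced (e.g. hundreds of Merlin models vs. $>10^5$ hAT models). Weights
are inverse-frequency, $w_c = N/(C\,N_c)$, rescaled to mean 1 so the
learning rate is invariant to the weighting scale; with balanced classes the
loss reduces exactly to unweighted cross-entropy.

## Augmentation

Ten string-level augmentations emulate the mutational processes that
diversify real TE copies: point substitutions (SNP), N-masking, random
insertion, deletion, segment duplication (Repeat), strand operations
(Reverse, Complement, Reverse-complement) and poly-A tail addition/removal.
They are applied on the fly during training only, each independently with
its configured probability, in that fixed order.

The defaults are deliberately mild so the class signal survives: 0.05 for
each mutating and tail kind, 0.25 for each strand kind. Counts of
substituted/masked sites scale as len/100 and indel/repeat segment lengths
as len/20; poly-A tails are 5–30 nt, and tail removal strips a terminal
A-run of at least 5 nt ("if present" — absent tails are a no-op). All of
these are open design choices surfaced in `augmentation_config()`: no
published values exist for them, and the involution/composition properties
(reverse and complement are involutions, their composition is the opposite
strand) are what the test suite pins down. Strand kinds are drawn
independently rather than as one mutually exclusive choice; this keeps the
pipeline a simple ordered chain of independent Bernoulli gates, and the
composition Reverse∘Complement arising when both fire is itself just the
opposite strand.

## Data handling

Labeled FASTA follows the RepeatMasker/Dfam header convention
`<id>#<class>`; the separator is configurable and the class part may
contain `/` (L1/L2). All input is sanitized: uppercased, whitespace
stripped, and every character outside \{A,C,G,T\} mapped to N — softmasked
(lowercase) bases are uppercased rather than masked.

Splits are stratified per class at 75/15/10 (train/validation/test). Within
a class of $N$ members, train gets $\lfloor 0.75N \rfloor$, validation
round-half-up$(0.15N)$, test the remainder; the convention makes every
per-class count an exact arithmetic function of the class size, so split
manifests can be audited by hand. Assignment within a
class is a seeded permutation, so a (data, seed) pair fully determines the
split. Per-epoch metrics are computed on the validation split and the final
report on the untouched test split; the best-validation-weighted-F1
checkpoint is tagged `best`.

## Training mechanics and numerical choices

- **Architecture details.** Pre-norm residual blocks (LayerNorm before each
  sub-layer, plus a final LayerNorm), GELU feed-forward, CLS pooling. Pre-norm
  keeps gradients well-behaved at small scale without long warmup schedules.
- **Optimizer.** AdamW (β = 0.9/0.999, decoupled weight decay 0.01 on weight
  matrices only), linear warmup over the first 5% of steps, default learning
  rate 1e-4. Initialization is truncated normal (σ = 0.02, ±2σ), seeded;
  identical seeds give bit-identical models.
- **Implementation.** The forward and analytic backward passes are written
  twice: a base-R reference (`model_forward()`) and a compiled
  RcppArmadillo core used by the training and inference loops. The test
  suite checks the two against each other, against a naive dense-attention
  oracle, and against central finite differences.
- **Determinism and resume.** All randomness (shuffling, augmentation,
  dropout) flows through R's RNG; checkpoints store weights, optimizer
  state, epoch and the RNG state, so resuming from epoch $e$ reproduces the
  uninterrupted run bit-for-bit.
- **Degenerate inputs.** Sequences shorter than k are flagged `too_short`
  at inference, never dropped; a deletion that would empty a sequence is a
  warned no-op; 0/0 precision or recall is reported as 0 with a warning;
  argmax ties break toward the first class in registry order; UNK tokens
  cannot occur after sanitization and their appearance is treated as a bug.
- **Thresholding.** A classification is reported only when the top
  aggregated probability reaches the threshold (default 0.7, with 0.9 as
  the strict preset); below it the record is `unclassified` but keeps its
  full probability vector. Raising the threshold can only shrink the
  classified set.

## The synthetic benchmark

Full-scale training data (Dfam/Repbase, ~880k models) is out of scope, so
the package ships a generator of labeled synthetic TE families:
a consensus drawn from a base-composition bias with planted signature
motifs, and copies perturbed by per-base substitutions and short (1–10 nt)
indels. The four-family preset imitates the field's class structure at toy
scale — an LTR-like family with direct terminal repeats (Copia label), a
long AT-rich LINE-like family with a poly-A tail (L1/L2), a short
poly-A-tailed SINE-like family (SINE), and a TIR-like family with inverted
terminal repeats (TcMar) — with distinct 12-mer signatures, lengths within
300–1500 nt, 200 copies per family and a 5% substitution rate. Mean
inter-family identity is below 60%.

What passing the recovery experiment shows: the full pipeline (augment →
tokenize → sparse-attention encoder → WCE training → median aggregation →
metrics) can learn and recover family structure from sequence alone.
What it does not show: performance on real TE libraries, whose families are
vastly more numerous, more decayed, mutually similar, and confounded by
nested insertions and fragmentary models. The negative control — one family
generated twice under two labels, byte-identical copies — checks the
opposite direction: with no signal the pipeline stays at chance instead of
hallucinating separability.

Experiment sizes used by the test suite and the acceptance script: the
four-family recovery uses a 2-layer, 2-head, 32-dimensional encoder with a
256-token embedding budget, 64-token local window, batch size 16, learning
rate 1e-3 (a tiny model trains faster and less noisily with a higher rate
than the full-scale 1e-4 default) and 30 epochs; the negative control uses
100 copies per label and 10 epochs. These sizes recover the families to
macro F1 ≈ 1.0 while keeping a desk-scale footprint.

## Known limitations

- The encoder is trained from scratch per dataset; there is no pretraining
  objective, so very small classes lean entirely on class weighting and
  augmentation.
- Chunked inference scores each chunk independently; a family whose
  signature spans a chunk boundary loses that signal (chunks do not
  overlap).
- The synthetic generator makes no attempt to mimic real consensus
  statistics (no ORFs, no phylogenetic covariance, no fragmentation), so
  absolute metrics on it do not transfer to real libraries.
- `intermediate_size` defaults to 3078 in the full-scale configuration,
  a hair off the conventional 3072 (= 4 × 768); it is configurable like
  every other width.
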