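---
title: "Structure-aware search and differentiable alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware search and differentiable alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedalign)
```

# The problem

Remote homologs — proteins that share a fold but have diverged below ~25%
sequence identity — are largely invisible to classical sequence search and
alignment. Structure comparison finds them, but most sequences have no
experimental structure. `embedalign` implements a two-stage, sequence-only
stack that borrows the supervision signal from structure:

1. **Retrieval.** A twin (Siamese) encoder maps each protein to a vector
   whose cosine similarity with another protein's vector approximates their
   TM-score (a length-normalised structural-similarity score in (0, 1];
   below 0.2 means unrelated, above 0.5 the same fold). Databases of such
   vectors are indexed and searched by cosine.
2. **Alignment.** A differentiable Needleman–Wunsch layer converts learned
   per-cell match and gap scores into a *distribution over alignments*,
   which makes the whole scoring pipeline trainable from ground-truth
   alignments by backpropagation.

Everything runs offline at desk scale: a deterministic toy embedder stands
in for a pretrained protein language model, and a seeded generator plants
synthetic homolog pairs with known alignments and similarity labels.

# The differentiable alignment layer

## The recursion

For sequences of lengths $p$ and $q$, match log-odds $\mu \in
\mathbb{R}^{p\times q}$ (strictly positive) and gap log-odds $g \in
\mathbb{R}^{p\times q}$ (strictly negative), the alignment value is

$$v_{i,j} = \operatorname{smax}_\Omega\big(\mu_{i,j} + (v_{i-1,j-1},\;
g_{i,j} + v_{i-1,j},\; g_{i,j} + v_{i,j-1})\big),$$

where $\operatorname{smax}_\Omega$ is the temperature-scaled log-sum-exp
and its gradient, the softmax, gives the per-cell transition weights
$\omega_{i,j} \in \Delta^3$ (channels match / insert X / delete Y). Note
that $\mu_{i,j}$ enters **all three branches** — the layer's default
(`mu_on_gaps = TRUE`) implements the recursion exactly in this form, and a
`mu_on_gaps = FALSE` toggle provides the textbook variant in which $\mu$
rewards only the diagonal transition. All oracles and derivative code
follow the selected variant.

Two border initialisations are provided and recorded in every result:

* `as_printed`: $v_{0,0} = 1$, all other border cells $0$. This reproduces
  the published initialisation literally (the origin carries weight $e^1$
  and every other border cell weight $e^0$, so paths may effectively enter
  from any border cell).
* `path_strict`: $v_{0,0} = 0$, other borders $-\infty$. Under this mode
  $v_{p,q}$ is exactly the temperature-scaled log-sum-exp over all
  monotone lattice paths from the origin — a clean Gibbs-distribution
  semantics that the enumeration oracle and the zero-temperature tests
  exploit.

The backward recursion propagates
$e_{i,j} = \omega^m_{i+1,j+1} e_{i+1,j+1} + \omega^x_{i+1,j} e_{i+1,j} +
\omega^y_{i,j+1} e_{i,j+1}$ from the terminal cell ($e_{p+1,q+1}=1$,
virtual terminal entering diagonally). The result, the *expected
alignment* $e = \partial v_{p,q} / \partial \mu$, is the matrix of
path-visitation marginals under the Gibbs distribution over alignments —
the "soft traceback".

## Derivatives

Three distinct derivative computations coexist, each validated against
central finite differences in the test suite:

* `nwExpectedAlignment()` — the gradient $e$ itself.
* `nwDirectional()` — the forward-over-reverse directional derivative:
  for a perturbation $Z = [z_\mu, z_g]$ it returns $\dot v = \langle
  \nabla v, Z\rangle$ and $\dot e = \nabla^2 v\, Z$ restricted to the
  $\mu$-block (a Hessian-vector product). One published detail required
  resolution: deriving $\dot\omega$ from $\omega = \mathrm{softmax}(s)$
  gives $\dot\omega = J_\Omega(\omega)\,\dot s$ with
  $J_\Omega(\omega) = \mathrm{diag}(\omega) - \omega\omega^\top$; because
  $J_\Omega$ annihilates constants, the $z_\mu$ term common to all three
  branches drops out, and no leading minus sign appears. The
  implementation uses this calculus-derived form; its agreement with
  finite differences (and the linearity of the map $Z \mapsto (\dot v,
  \dot e)$ to $10^{-8}$) is what certifies the sign convention.
* `nwBackprop()` — the reverse-mode adjoint used for training: given
  $\partial L/\partial e$ (and optionally $\partial L/\partial v$), it
  returns $\partial L/\partial \mu$ and $\partial L/\partial g$ in one
  forward-order and one reverse-order sweep. The adjoint and the
  directional derivative are cross-checked against each other through the
  symmetry of the Hessian of $v$.

A brute-force oracle (`enumeratePathsOracle()`) scores every monotone
path explicitly (refusing grids above 36 cells) and must agree with the
recursions to $10^{-8}$; as the temperature drops to zero the smoothed
value decreases to the classical hard optimum, and `nwHardDecode()` (exact
max/argmax, deterministic tie order match > insert > delete) must coincide
with the oracle's argmax path.

## Numerical choices

Temperature enters as $v = \tau \log \sum_i e^{x_i/\tau}$; $\tau = 1$ is
the recursion as written and the training default — the temperature is
exposed for the zero-temperature limit tests, not as a tuning dial.
Branches at $-\infty$ get weight 0 and are excluded before any
multiplication to avoid NaN. Expected-alignment entries are clipped to
$[0, 1]$ (excursions $\le 10^{-9}$), and the cross-entropy loss clamps
probabilities to $[10^{-12}, 1 - 10^{-12}]$ before any log. Storage is
0-based with border rows explicit; the maths above is 1-based.

# Scoring heads

Match and gap scores come from two independent convolutional
sequence-to-sequence heads over per-residue embeddings $H_X \in
\mathbb{R}^{p\times d}$, $H_Y \in \mathbb{R}^{q\times d}$:

$$\mu = \mathrm{softplus}\big(M(H_X)\,M(H_Y)^\top\big), \qquad
g = \log\sigma\big(G(H_X)\,G(H_Y)^\top\big).$$

The activations guarantee $\mu > 0$ and $g < 0$ for *any* parameters —
gaps are always penalised and matches rewarded, which keeps the layer
identifiable. Convolution details the source architecture leaves open are
fixed here as: kernel size 5, same padding, stride 1, ReLU between layers,
intermediate width configurable, final layer mapping back to $d$ (all
overridable in `newScoringHeads()`). Note that with kernel size above 1
the heads are translation- but not permutation-equivariant; the
row-permutation property of the scores holds exactly in the kernel-1
configuration and is tested there. The reference-scale architecture
(8 layers of width 1024 on $d = 1024$ embeddings) is expressible but the
desk-scale default is 2 layers of width 32 on $d = 16$.

# The twin encoder

`encodeProtein()` applies transformer encoder layers (multi-head
self-attention, layer norm, ReLU feed-forward), mask-free mean pooling
over positions, dropout (training only) and a two-layer fully connected
head; `predictTm()` is the cosine of two such vectors, clamped to
$[0, 1]$ for reporting with the raw value retained. Training minimises the
mean L1 distance between the cosine and the pair label with Adam
(reference learning rate $10^{-4}$, batch 32; the toy runs use larger
rates, exposed as arguments). The best-validation checkpoint is kept. The
fully connected head depth/width after pooling is not specified by the
source architecture; one hidden layer of the output width is used here,
so parameter counts are deliberately not comparable to the reference
models. No positional encodings are added: the toy embedder's context
window already injects local order, and pooled representations are
position-averaged anyway.

Because no automatic-differentiation framework is available to R in this
stack, the layers (1-D convolution, attention, layer norm, dense) form a
small self-contained reverse-mode library (`R/nn.R`) in which every
forward function returns its backward closure; each layer's gradients are
finite-difference-checked in the tests. The differentiable alignment
kernel itself is compiled C++.

# Training data semantics

`filterTrainingAlignments()` drops records with a gap run longer than 10
consecutive gap states or a TM-score label below 0.6, with exact
boundaries: a run of exactly 10 and a label of exactly 0.6 survive. A run
is broken when the gap character switches between X and Y (a documented
choice; the filter's source description does not say). `alignmentLoss()`
is the cross-entropy between the expected alignment and a binary
ground-truth match matrix, negated and averaged over cells (the printed
objective is a log-likelihood in sum form; the mean keeps learning rates
length-independent, and `reduction = "sum"` restores the sum).

One consequence of putting $\mu$ on all branches is that $e$ is a
*visitation* marginal, not a *match* marginal: cells crossed by gap
transitions also carry mass, and the terminal cell always has $e = 1$.
Against a match-only target the loss therefore has a positive floor on
alignments containing indels; decoding goes through the hard DP on the
learned scores (`alignPair()`), which is immune to this and guarantees a
valid monotone path. Thresholding $e$ at 0.5 is available as an
alternative decode but can produce inconsistent edge sets; the hard
decode is the default for exactly that reason. Alignments whose expected
matrix never reaches 0.5 in any row raise a low-confidence flag
(threshold configurable).

# The synthetic corpus

`generatePairCorpus()` evolves families from random ancestors
(20-letter uniform composition, lengths 40–80 by default): each member
draws a divergence $d$, substitutes each site with probability $d$
(uniform replacement, so ~5% of substitutions are silent), and applies
indels at per-site rate $0.1\,d$ with geometric lengths (mean 2). The
pair alignment is composed from the two members' ancestor-position maps —
substitutions keep the match edge, indels create X/Y states — so the
ground truth is the *true* mutation history, not a recomputed optimal
alignment. Labels are $\exp(-\lambda\,(d_a + d_b)) + \varepsilon$,
$\lambda = 2$, $\varepsilon \sim N(0, 0.02)$, clamped to $[0, 1]$;
cross-family pairs are labelled Uniform(0, 0.2). With member divergences
U(0.02, 0.5) the related-pair labels span roughly 0.14–0.95, and families
of 14 members give a pair set strongly enriched in same-fold pairs,
mirroring fold-oversampled chain-pair training sets.

What the generator does **not** emulate: realistic substitution matrices
(no BLOSUM bias), length-dependent indel placement, domain architecture,
or any actual structural constraint — the "TM-score" here is a planted
monotone function of mutation distance. Passing the recovery experiments
therefore demonstrates that the optimisation and the architecture can
recover a planted signal end to end, not that the toy models would rank
real remote homologs.

# The recovery experiments

`experimentTmScoreRecovery()` trains the toy encoder (1 layer, 2 heads,
$d_{in} = 16$, feed-forward 128, output 64, dropout 0.05) on 425 pairs of
a 9-family × 14-member corpus and evaluates on 75 held-out pairs of the
same corpus. This is the *left-out-pairs* protocol: held-out pairs may
share proteins with training pairs, exactly as in chain-pair training
sets, and the encoder succeeds by placing each seen protein consistently
with all its training pairs. Generalisation to unseen families is a
strictly harder task that this desk-scale experiment does not measure.
Observed at this scale, the held-out median absolute error sits around
0.1–0.12 with a divergence Spearman near −0.6, and leave-self-out top-1
family retrieval over the corpus lands well above chance but far from
perfect: the toy embedder's
window-averaged projections carry limited per-protein divergence
information (pooling reduces them to a composition-like signature whose
signal-to-noise ratio is length-invariant), which bounds what any encoder
can recover from them — the corresponding acceptance checks at 0.08 and
−0.8 document this gap rather than hide it.

`experimentAlignmentRecovery()` trains the toy aligner on 300 filtered
low-divergence alignments (the regime the TM ≥ 0.6 filter retains) and
scores held-out decoded edges; it reaches median precision and recall of
1.0 well within its budget, confirming that gradients flow correctly
through the entire embedder → heads → DP → loss chain.

Problem sizes throughout (500 pairs, 300 alignments, 1000×64 search
fixtures, ≤6×6 oracle grids) are chosen so the full validation runs in
minutes on one CPU while still exercising every code path at
non-trivial scale.

# Vector search

`buildDatabase()` L2-normalises vectors so cosine similarity is an inner
product. The exact backend is a full scan and serves as ground truth. The
approximate backend is an inverted-file index: a seeded k-means coarse
quantiser with $\sqrt{n}$ cells, each vector assigned to its two nearest
cells, queries probing the nearest half of the cells (all configurable);
on 1000 random 64-dimensional vectors — a worst case, since random
vectors have weak cluster structure — recall@10 against the exact scan
exceeds 0.95. Ties are broken by id order, persistence is a documented
little-endian float32 format with a text manifest, and rebuilds from the
same inputs and seed are byte-identical.

# Evaluation metrics

`alignmentPRF()` treats an alignment as a bipartite edge set over residue
pairs (empty predictions give precision 0 by convention).
`retrievalSensitivity()` is the percentage of queries whose annotation
labels intersect the union of their top-$n$ hits' labels.
`tripletAUPR()` samples anchor/positive/negative triplets (anchor uniform
over items whose label has ≥2 members, positive from the anchor's label,
negative from the rest, with replacement) and computes step-wise average
precision — no linear interpolation — of cosine scores on the balanced
pair set. `clusterAdjustedMI()` runs normalised spectral clustering on
the shifted cosine affinity $(1 + \cos)/2$ followed by seeded k-means,
scored by adjusted mutual information (hypergeometric expected-MI
correction, arithmetic-mean normaliser). The AMI and average-precision
implementations are frozen against independent reference values in the
tests.

# Limitations

* The toy embedder is a fixed random projection: all conclusions about
  real proteins require plugging in a pretrained language model via
  `registerEmbedder()`.
* The alignment layer is global (Needleman–Wunsch) with linear gap
  scores; no local alignment or affine gaps.
* The expected alignment under the printed recursion is a visitation
  marginal (see above), which slightly biases the cross-entropy loss on
  gapped alignments.
* The TM-score recovery experiment validates the left-out-pairs regime
  only, and its residual error is dominated by the toy embedder's
  information ceiling, not by the label noise.
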