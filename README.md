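# embedalign

Structure-aware protein search and differentiable sequence alignment in R.

## The problem

Remote homologs — proteins sharing a fold at < ~25% sequence identity —
are where classical sequence search and alignment break down. Structure
comparison detects them, but most sequences have no structure.
`embedalign` implements, at desk scale and fully offline, a two-stage
sequence-only stack that learns its signal from structural supervision:

1. **Retrieval** — a twin (Siamese) encoder φ maps residue embeddings
   H ∈ ℝ^{L×d} to a per-protein vector z, trained with an L1 objective so
   that cos(z_a, z_b) approximates the pair's TM-score (structural
   similarity in (0,1]; < 0.2 ≈ unrelated, > 0.5 ≈ same fold). Vector
   databases are indexed and searched by cosine (exact scan, or an
   inverted-file approximate backend).
2. **Alignment** — a differentiable Needleman–Wunsch layer. With match
   scores μ = softplus(M(H_X) M(H_Y)ᵀ) > 0 and gap scores
   g = logσ(G(H_X) G(H_Y)ᵀ) < 0 from convolutional heads M and G, the
   smoothed recursion

   v_{i,j} = smax(μ_{i,j} + (v_{i−1,j−1}, g_{i,j} + v_{i−1,j}, g_{i,j} + v_{i,j−1}))

   (smax = log-sum-exp, its gradient the softmax) yields an alignment
   value whose gradient e = ∂v_{p,q}/∂μ is the *expected alignment* — the
   matrix of path-visitation probabilities under the Gibbs distribution
   over alignments. Exact custom derivatives (expected alignment,
   Hessian-vector products, and the reverse-mode training adjoint) make
   the entire scoring pipeline trainable from ground-truth alignments
   with a cross-entropy loss.

A deterministic toy embedder (one-hot → fixed random projection → ±2
window mean) stands in for a pretrained protein language model, and a
seeded generator plants synthetic homolog families with known alignments
and TM-like labels, so every component is testable without downloads.
External embedders plug in via `registerEmbedder()`.

## Worked example

Train the toy aligner on planted homolog pairs, then align a held-out
pair (about a minute on one CPU):

```r
library(embedalign)

corp <- generatePairCorpus(generatorConfig(seed = 7, n_families = 20,
                                           members_per_family = 4,
                                           divergence_range = c(0.02, 0.12),
                                           unrelated_frac = 0))
recs <- filterTrainingAlignments(corp$alignments)$kept
fit  <- trainAligner(recs[1:100, ], corp$sequences,
                     newAligner(d = 16, seed = 1),
                     epochs = 30, lr = 1e-3, seed = 2)

hold <- recs[101, ]
res  <- alignPair(corp$sequences[[hold$id_a]], corp$sequences[[hold$id_b]],
                  fit$model)
cat(res$text)
alignmentPRF(res$path, alignmentPath(hold$states))
```

```
YNCSRYWEPKRESTLFLDWLPITEKMVMMMAANLGYVDHESSVQNGWKTT-FYYTGHII
||||||||||||||||||||||||||||||||||||||||||||||||||  |||||||
YTCSRYWEPKRESNLFLDWLPITEKDVMMMAYNLGYVDHCSSVQNGWKTTF-MPTGHII
precision    recall        f1
1.0000000 0.9827586 0.9913043
```

The three-row block is the decoded hard alignment (`|` marks matched
residues); `alignmentPRF` compares its edge set against the planted
mutation history — after ~25 seconds of training the model recovers 57
of the 58 planted match edges, mis-placing one residue around the indel.
The expected-alignment matrix `res$expected` holds the
per-cell match probabilities behind the decode, and
`res$low_confidence` flags alignments whose row maxima never reach 0.5.

Search works the same way end to end: `encodeSequences()` →
`buildDatabase()` → `queryDatabase()` (or `pipelineSearchAlign()` to
retrieve and align in one call), with `predicted_tm` = cosine similarity
reported per hit.

A command-line surface over the same functions is installed at
`system.file("scripts/embedalign", package = "embedalign")` with
subcommands `simulate`, `embed`, `train-encoder`, `train-aligner`,
`build-db`, `search`, `align`, `eval-align`, `eval-retrieval`.

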