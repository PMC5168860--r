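---
title: "Reference-free contamination screening: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free contamination screening: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scscreen` answers one question about an assembled single-cell genome: does
this set of contigs come from one organism or more? This vignette explains
the statistical machinery behind the verdict, the tunable parameters and
their defaults, what the synthetic data generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## The screening model

An assembly is treated as a bag of genomic sequence whose local
oligonucleotide composition is characteristic of its genome of origin.
The pipeline has four stages.

**Windowed canonical tetramer signatures.** A window of width
$w = \sum_i l_i / n$ (contig lengths $l_i$, target point count $n$) slides
over each contig with step $\Delta w = w/2$; contigs shorter than $w$ get one
whole-contig window, so no contig is discarded. Because of the 50% overlap an
assembly yields roughly $2n$ windows. Each window is summarised by the
frequencies of its 4-mers, with a word and its reverse complement counted as
one feature (both strands of double-stranded DNA are equivalent), which
reduces the $4^4 = 256$ raw dimensions to 136 canonical classes; with $k = 1$
the same construction would measure GC content. Counts are divided by the
number of valid (unambiguous) 4-mers in the window, so every row is a
probability vector.

**Embedding.** Barnes–Hut t-SNE reduces the signature rows to two dimensions.
t-SNE is used precisely because it exaggerates cluster structure, which is
the signal of interest; distances and densities in the embedding have no
further quantitative meaning and none is relied on beyond neighbourhood
structure.

**Two antagonistic detectors.** Deciding "one cluster vs. more" cannot be
done with ordinary cluster-validity indices (they are undefined at $k = 1$),
so two null-model tests are combined:

* *DIP*: each embedded point inspects the empirical distribution of its
  Euclidean distances to all other points. For a point inside a single
  coherent cloud this distribution is unimodal; a second cluster at some
  distance adds a second mode. Hartigan's dip statistic — the sup-norm
  distance between the empirical CDF and the nearest unimodal CDF — is
  tested against a Monte-Carlo null of uniform samples, and the assembly is
  flagged when the fraction of significant "viewers" exceeds $t_{dip}$.
  It excels at large, even strongly overlapping clusters, where component
  counting fails.
* *CC*: the mutual $k_{cc}$-nearest-neighbour graph (an edge requires both
  endpoints to list each other) is cut into connected components. Small,
  well-separated satellite clusters — invisible to the dip, which only sees a
  negligible probability mass — appear as separate components. $k_{cc}$ acts
  as the minimum number of points a separate cluster must hold.

Two repairs suppress false structure before a component counts as
contamination: all windows of a contig are reassigned to the contig's
plurality cluster (a contig belongs to one organism; chimeras are out of
scope), and clusters holding fewer than `min_cluster_bp` assembled bases are
set aside as outliers — reported, but excluded from the verdict and from
cleansing. If every cluster falls below the threshold the largest one is
retained, so the clustering is never empty.

**Bootstrap confidences.** Embedding and detection are stochastic and the
contamination signal may be marginal, so the embed-and-detect stack runs on
$B$ bootstrap folds, each a 75% subsample (without replacement) of the
signature rows with its own derived seed and a perplexity recomputed for the
fold size. The per-detector confidence is the fraction of folds that flagged
contamination. The verdict is *clean* if both confidences are strictly below
0.25, *contaminated* if either is strictly above 0.75, and *warning*
otherwise; at exactly 0.25 or 0.75 the weaker statement wins.

**Cleansing.** Once contamination is established the cluster count is no
longer one-vs-many but a standard model-selection problem: Ward's
hierarchical clustering on the full-data embedding is cut at
$k = 2,\dots,5$, each cut is post-processed as above, and the
Davies–Bouldin index
$\mathrm{DB} = \tfrac1k \sum_i \max_{j \ne i} (\sigma_i + \sigma_j) / d(c_i, c_j)$
is evaluated on the post-processed assignment (so the score describes the
clustering that would actually be exported). The minimising $k$ wins, ties
going to the smaller $k$; one FASTA per retained cluster is written, plus one
for outlier contigs, and the exported records always partition the input
exactly. When post-processing collapses every cut to one cluster the result
is declared inconclusive and the assembly is exported whole.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `n` | 1000 | points | target window count; sets $w = \sum l_i / n$ |
| `k` | 4 | bases | signature word length (136 canonical classes) |
| `theta` | 0.5 | — | Barnes–Hut speed/accuracy trade-off |
| `max_iter` | 1000 | iterations | t-SNE gradient steps |
| perplexity | $\lfloor \log(n)^2 \rfloor$ | points | effective neighbourhood size, clamped to $[2, \lfloor (n-1)/3 \rfloor]$ |
| `t_dip` | 0.001 | fraction | split-viewer fraction above which DIP fires |
| `alpha` | 0.001 | — | per-viewer dip significance level |
| `null_reps` | 1000 | samples | Monte-Carlo replicates of the dip null |
| `k_cc` | 9 | points | mutual neighbour count; minimum detectable cluster size |
| `min_cluster_bp` | 5000 | bp | smallest cluster allowed to stand alone |
| `B` | 10 | folds | bootstrap folds |
| `subsample` | 0.75 | fraction | rows per fold |
| `clean_below` / `contaminated_above` | 0.25 / 0.75 | fraction | verdict thresholds on fold fractions |
| `k_min`–`k_max` | 2–5 | clusters | cleansing search range |

Notes on the less obvious ones: the perplexity rule uses the *natural*
logarithm (1000 points give 47, a conventional t-SNE perplexity; base-10
would give an unusably small 9). `t_dip` = 0.001 means that for typical
window counts a *single* significant viewer flags a fold — detection
precision is instead controlled by `alpha` and by the conservativeness of
the uniform null (any smooth unimodal distance distribution has
stochastically smaller dip than the uniform, so per-viewer p-values are
conservative). `min_cluster_bp` is the "aggressive threshold": lowering it
makes the screen more sensitive to very small contaminants at the cost of
more false structure.

## The dip statistic

The dip is computed exactly from its definition,
$\mathrm{dip}(F_n) = \min_G \sup_x |F_n(x) - G(x)|$ over unimodal CDFs $G$
(convex left of the mode, concave right of it, with an atom permitted only at
the mode). Collapsing the sample to unique values with lower/upper ECDF
anchors, a candidate mode placement at a knot imposes one requirement per
side — half the largest gap between the lower anchors and the greatest convex
minorant of the upper anchors (mirrored on the right) — plus a joining
condition: the convex half-fit must be able to end no higher than the concave
half-fit can start. The one-sided requirements come from incremental hull
profiles; the joining condition is decided exactly by propagating the convex
region of reachable (value, slope) chain states through the anchor bands, and
the dip is the root of the resulting monotone feasibility margin (bracketed
secant iteration). The test suite verifies the implementation to 1e-12
against an independent linear-programming solution of the definitional
minimisation (`boot::simplex` for $n \le 12$; scipy/HiGHS for an $n = 200$
spot check, at that solver's ~1e-9 accuracy).

Degenerate inputs: a constant sample has dip 0 (a point mass is unimodal);
two distinct values force the maximum 0.25; non-constant samples obey
$1/(2n) \le \mathrm{dip} \le 1/4$. Monte-Carlo p-values use a null table per
sample size, cached; the per-viewer significance decision only needs the
$(k{+}1)$-th largest null dip, which is computed lazily but exactly.

## The synthetic data generator

`genome_model()` + `generate_sample()` build assemblies from nucleotide
composition models: order-0 base probabilities (or a GC shorthand spreading
GC evenly over C and G) or an order-1 Markov transition matrix, with contig
lengths drawn uniformly (or log-normally) between 5 and 50 kb — typical
single-cell draft contig sizes — until a target of 500 kb per genome is
reached. Contigs are shuffled across genomes and every contig's origin is
recorded, giving ground truth for free. The difficulty knob is the
composition distance between models: GC 0.30 vs 0.70 emulates distantly
related organisms; closer compositions emulate related ones.

What the generator does **not** emulate: real k-mer correlation structure
beyond order 1, repeats, mobile elements, amplification bias, chimeric
contigs, or assembly artefacts. Passing the synthetic suite therefore shows
that the statistical machinery behaves as designed on composition-separable
mixtures; it does not certify detection power on strain-level contamination,
whose signatures differ too little in composition for any reference-free
screen of this kind.

## Simulation scales used by the test suite

The shipped tests exercise the full stack at a reduced simulation scale so
the whole suite runs in minutes on one CPU: end-to-end detection, type-I and
cleansing checks use 150 kb (cleansing: 120 kb) per genome and a target of
250 windows — that is ~500 signature rows of ~600 bp windows, bootstrap folds
of ~375 points — with every algorithm parameter at its default, plus a single
run at the full default scale (500 kb per genome, 1000 target windows). At
both scales the windows remain an order of magnitude wider than needed for
stable tetramer estimates and the smallest cluster remains far above both
$k_{cc}$ and `min_cluster_bp`, so the reduced scale changes runtime, not the
regime being tested. Seed counts follow the validation plan (10 master seeds
per detection condition, 20 for type-I control).

## Numerical and design choices

* Ambiguous bases (N and friends) invalidate any k-mer overlapping them;
  windows with no valid k-mer are dropped and logged, and an assembly that
  loses every window is a hard error.
* The canonical representative of a k-mer class is the lexicographically
  smaller of word and reverse complement; classes are ordered by
  representative, fixing a stable feature order across runs.
* $w$ and $\Delta w$ are floored to integers and clamped to $\ge 1$; the
  trailing sub-step remainder of a contig gets no extra window (the 50%
  overlap already covers most of it).
* The embedding consumes the raw frequency rows — no PCA, centering or
  rescaling — with Euclidean distances; coordinates are bit-reproducible for
  a fixed seed and the R RNG state of the caller is never disturbed.
* "Strongly connected components" of the mutual-kNN graph reduce to plain
  connected components: mutual edges are symmetric.
* Plurality reassignment breaks ties toward the cluster with more rows
  overall, then toward the smaller label; cluster bp is the sum of full
  contig lengths (windows overlap, so window-bp would double-count).
* Bootstrap folds are subsamples without replacement (the operational
  resampling described for this screen), independent across folds via
  per-fold derived seeds; fold results are identical under serial and
  parallel execution.
* A fold whose embedding fails is recorded and warned about; if every fold
  fails the report carries a warning status and a diagnostic instead of an
  error, while fewer than half succeeding is treated as a hard error.
* Cleansing runs on a fresh full-data embedding seeded by the master seed,
  and the Davies–Bouldin score is computed after post-processing, so the
  model selection judges the partition that will be exported. Coincident
  centroids make the index undefined and are reported as an error.

## Known limitations

* Contaminants related at the strain level (average nucleotide identity in
  the high 90s) are compositionally indistinguishable and will pass as clean.
* Very unbalanced *and* overlapping mixtures can defeat both detectors — the
  dip sees too little probability mass, the graph too little separation.
* Horizontally transferred elements (phage, plasmids) carry foreign
  signatures and may legitimately split off as clusters; that is a feature of
  composition screening, not a defect, but it requires interpretation.
* The verdict is per-assembly; the screen does not attribute taxonomy. An
  annotation adapter can overlay external per-contig classifications in the
  report, but the package never runs external tools.
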