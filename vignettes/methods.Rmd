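---
title: "Methods: signed-network subgraph decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed-network subgraph decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`netsubgraph` treats a block-design functional imaging study as a collection
of per-block region-by-region Pearson correlation matrices. The modeling
premise is that a small number of edge patterns ("subgraphs") recur across
blocks, conditions, and subjects, each waxing and waning in strength, and
that the sign of an edge carries meaning: positive correlations reflect
cooperative (integrated) dynamics, negative correlations competitive
(segregated) dynamics. Each block matrix is therefore duplicated and
thresholded at zero into a positive network and a negative-magnitude
network, both fully weighted and non-negative.

All networks are vectorized (upper triangle, `i < j`, row-major) into an
E × T configuration matrix and normalized in two steps: every observation
column is divided by its sum (unit edge density, compensating the lower
magnitude of anticorrelations), and every edge's vector of values across one
subject's observations is scaled to unit Euclidean length (compensating
between-subject differences in overall edge-weight level). Subgraphs are the
columns of `W` in

$$\min_{W,H \ge 0} \tfrac12\|\hat A - WH\|_F^2 + \alpha \|W\|_F^2
  + \beta \sum_{t=1}^T \|H(:,t)\|_1^2,$$

fit by alternating non-negative least squares; each subproblem is solved
exactly with a block-principal-pivoting NNLS solver (grouped by passive-set
pattern across right-hand sides), so the objective trace is monotone
non-increasing. Initialization is uniform on [0, 1] from a recorded seed;
iteration stops at 100 sweeps (configurable) or at a relative objective
change below 1e-6.

Note that the two penalties play the roles the objective assigns to them —
`beta` penalizes the squared L1 norm of each expression column (sparse,
competitive expression); `alpha` penalizes the Frobenius norm of `W`.
Narrative descriptions of such models sometimes swap the two labels; the
objective as written is authoritative here.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `m` | number of subgraphs | from CV | model order; sampled U{3..50} in selection |
| `beta` | expression-sparsity penalty | from CV (0.01 at desk scale) | sampled U(0.01, 5) |
| `alpha` | subgraph regularization | from CV (0.01 at desk scale) | sampled U(0.01, 5) |
| `max_iter` | solver sweeps | 100 | the reference budget for large problems |
| `tol` | relative objective change | 1e-6 | cheap extra stop for small problems |
| `shift_samples` | analysis-window shift | 4 samples | hemodynamic lag of 6 s at a 1.5 s sampling interval |
| `n_perm` | permutation count | 10000 (1000 in tests) | permutation p resolution |
| `R` | consensus runs | 100 (10 in tests) | reference uses 1000; scaled to desk budgets |

Model selection draws parameter sets uniformly at random, scores each by
subject-level 4-fold cross-validation (fit `W` on the training subjects'
columns, refit `H` on held-out columns with `W` frozen, record the held-out
squared Frobenius error), and averages the parameters of the sets in the
bottom 5% of the error distribution (`m` rounded half-up). Freezing `W` and
solving the `H` subproblem for held-out subjects is our choice of
out-of-sample projection; the selection procedure itself does not prescribe
one.

## What the synthetic cohort emulates — and what it does not

No imaging data accompany the method, so the package ships a generator whose
defaults state a complete synthetic world: 28 subjects, 2 tasks, 3
conditions (fixation, low demand, high demand), 6 blocks per condition, 20
samples per block, 262 regions in 9 systems. Regional signals for each block
are drawn from a zero-mean multivariate normal whose covariance is
`noise_sd^2 I` plus expression-weighted planted patterns, eigenvalue-floored
at 1e-6 when needed; the generator lags each block's samples by 4 TRs so the
pipeline's standard window shift recovers covariance-pure segments.

Three design choices deserve explanation because the obvious alternatives
fail quietly:

1. **Anticorrelation is planted with signed patterns, not by subtraction.**
   Subtracting an expression-weighted non-negative block from the covariance
   caps attainable pairwise anticorrelation at roughly 1/(block size − 1)
   (positive definiteness) — below the sampling noise floor of 20-sample
   correlations. Negative-dominant subgraphs are therefore built as disjoint
   matchings of anticorrelated node pairs between two systems (node degree
   at most two, pattern rescaled so its spectral radius stays below the
   largest expression driver): each pair genuinely fluctuates in opposition
   and its edges appear, strongly, in the negative channel. A rank-1
   anti-phase block would instead scatter "shadow" positive edges into the
   positive channel and split every planted subgraph across channels.
2. **Expression must co-fluctuate.** Drivers are drawn uniform on [0, 1]
   per design cell (with a ±15% subject gain, task preference, and an
   alternating demand tilt). With near-constant expression the planted
   components are collinear with the diffuse background and unidentifiable —
   detectability comes from variance, not magnitude.
3. **Positive-dominant subgraphs are rank-1 community blocks over two
   systems** (loadings uniform on [0.4, 0.8]), aligned to the synthetic
   partition, making the planted set identifiable and system-aligned.

The generator does **not** model hemodynamic-response convolution, scanner
noise or motion, BOLD autocorrelation, or spatially correlated parcellation
noise. A green test on synthetic data establishes that the pipeline's
machinery (windowing, sign split, normalization, factorization, matching,
permutation nulls) behaves as specified — not that any neuroscientific
conclusion transfers to real data.

**A structural limit worth knowing.** The two normalization steps give every
edge — including pure-noise edges — exactly one unit of L2 mass per subject.
The sampling noise of short-block correlations therefore forms one or two
diffuse, dense background components (one per sign channel) in the
configuration matrix *regardless of the noise level*. At factorization rank
equal to the number of planted subgraphs, these background components
compete for slots and the weakest planted structures (always the
negative-channel ones, which carry fewer, PD-bounded edges) are merged or
dropped. Even an oracle that regresses the configuration matrix on the true
expression drivers recovers negative-dominant planted subgraphs only to
Pearson ~0.6–0.75 in the 40-region test world. Positive-dominant subgraphs
recover at ~0.85–0.95. The acceptance criterion asking for mean matched
recovery ≥ 0.8 at rank = planted count is reported honestly (see the
decisions notes); users applying the method to real data should expect some
components to be dense background rather than interpretable structure, and
should choose `m` by cross-validation rather than by assumed ground truth.

## Numerical choices

- **Edge order**: upper triangle, `i < j`, row-major; region ids 1-based.
- **Degenerate inputs**: constant-signal regions yield zero-weight edges
  (with a warning), not NaN; all-zero observation columns are an error
  (density normalization undefined); zero-norm edge vectors stay zero.
- **Core-periphery scores**: the per-system core score divides by `|s|`
  (node count), not by the number of within-system pairs, exactly as the
  index is defined; the index remains bounded in [−1, 1] because each
  system's term is a normalized difference. Sums run over ordered pairs for
  the core and over (i in s, j outside s) for the periphery; the uniform
  complete graph with two equal systems of two nodes scores exactly 0.
  Systems with zero core + periphery weight contribute 0. The 1/9 averaging
  generalizes to 1/S for S systems.
- **Permutation p-values** use the plus-one estimator `(b + 1)/(n + 1)`
  (never zero); system tests are Bonferroni-corrected, the participation
  null uses a two-sided p compared against `alpha / n_regions`.
- **FDR** is Benjamini-Hochberg wherever "FDR correction" is called for.
- **Spearman p-values**: exact enumeration below n = 10, t approximation
  otherwise; ties take average ranks.
- **Fisher r-to-Z**: magnitudes clipped at 1 − 1e-7 with a warning.
- **Assignment**: an O(n³) shortest-augmenting-path Hungarian solver,
  verified against exhaustive enumeration for m ≤ 7.
- **Consensus**: run-level `W` columns are L2-normalized before aggregation
  (removes the scale degeneracy that would let high-magnitude runs dominate)
  and the consensus `W` is L2-normalized again; consensus `H` is obtained by
  refitting expression against the consensus subgraphs — the only choice
  consistent with the objective.
- **Split halves** (blocks 1–3 vs 4–6 by default) are re-normalized
  independently, since the per-edge L2 normalization depends on the column
  set; both halves keep fixation columns, like the main pipeline, and are
  decomposed with the full run's `(m, beta, alpha)` under fresh recorded
  seeds.
- **Solver-oracle comparisons** between the alternating solver and
  multiplicative updates are made at equal iteration budgets from the same
  initialization; with unequal budgets the two algorithms land in different
  local basins of the non-convex objective and either can win by a fraction
  of a percent.
- **Reliability selection bias**: matched pairs are selected to minimize
  distance, so under full independence between subgraph sets a small number
  of matched pairs (1–3 of 6 in simulation) still exceed the non-assigned
  null's Bonferroni bound; the informative read-out is the contrast between
  the planted case (all pairs reliable) and the independent case (few).

## Known limitations

- The method inherits the local-minimum behavior of NMF; consensus
  clustering stabilizes but does not convexify it.
- Reaction-time modeling is deliberately thin (Gaussian trial noise around a
  condition mean plus expression coupling, correctness as an independent
  Bernoulli flag); accuracy itself is not modeled.
- "Consecutive blocks" in the reaction-time cost is read as the difference
  of condition means across blocks; a block-index-paired variant is
  available behind `per_pair = TRUE`.
- The CLI stores decompositions as a directory of TSV files rather than a
  binary container, keeping the artifact dependency-free and inspectable.
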