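---
title: "Gene selection with neighborhood-preserving multi-objective PSO: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene selection with neighborhood-preserving multi-objective PSO: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anpmopso)
```

# The problem

Microarray expression panels measure thousands of genes over tens to a few
hundred samples. Classifying such samples (tumour subtype, outcome class)
requires selecting a handful of genes out of thousands: wrapper selection
treats the subset as the decision variable and a classifier's accuracy as
part of the objective. Because accuracy, subset size, and the preservation
of the data's local geometry pull in different directions, the package
treats selection as a three-objective optimization problem and returns a
Pareto archive of trade-off subsets rather than a single "winner" by a
fixed weighting.

The optimizer, ANPMOPSO (adaptive neighborhood-preserving multi-objective
particle swarm optimization), combines four ingredients:

1. **WNPEE** — a weighted neighborhood-preserving ensemble embedding used
   as the dimensionality-reduced reference geometry;
2. **Sobol-sequence initialization** of the swarm;
3. a **differential-evolution (DE/rand/1) adaptive velocity term**; and
4. an **archive selection score** mixing harmonic-mean distance (HMD, a
   diversity measure) with neighborhood-preservation quality.

# WNPEE: the embedding model

Let $X \in \mathbb{R}^{D\times N}$ hold $N$ samples in columns. For each
neighbourhood size $k_g$ in `k_list` a directed $k$NN graph is built
(Euclidean distances, ties to the smaller sample index), and LLE-style
reconstruction weights $W_g$ solve, row by row,
$\min \|x_i - \sum_j W_{g,ij} x_j\|^2$ subject to $\sum_j W_{g,ij} = 1$,
via the local Gram system with ridge $10^{-3}\,\mathrm{tr}(G)$. The
ensemble is coupled through simplex weights $\alpha$ with exponent $r > 1$:

$$J(A,\alpha)=\sum_g \alpha_g^r\;
\mathrm{tr}\!\left(A^\top X (I-W_g)^\top (I-W_g) X^\top A\right),
\qquad \textstyle\sum_g \alpha_g = 1 .$$

Both alternating steps minimize this one objective exactly: for fixed
$\alpha$ the projection $A$ collects the $d$ generalized eigenvectors of
$XMX^\top a=\lambda (XX^\top + \varepsilon I) a$ with smallest eigenvalues
($M=\sum_g \alpha_g^r (I-W_g)^\top(I-W_g)$, $\varepsilon =
10^{-6}\,\mathrm{tr}(XX^\top)/D$ since $XX^\top$ is rank-deficient whenever
$D \gg N$), and for fixed $A$ the closed-form update
$\alpha_g \propto (1/\mathrm{tr}_g)^{1/(r-1)}$ follows from the Lagrangian.
This exponent-$r$ coupling is what makes the recorded loss trace provably
non-increasing — a property the test suite asserts on random instances —
and it reduces *exactly* to plain NPE when the ensemble has one graph.
Reconstruction weights are solved once per graph in the input space; only
$\alpha$ and $A$ iterate. Eigenvector signs are fixed by making the
largest-magnitude entry positive, so fits are reproducible and permutation
of samples merely permutes the embedding.

Defaults: `k_list = c(5, 10, 15)` (clipped to $N-1$),
`d = min(20, N - 2)`, `r = 2`, convergence when the loss changes by less
than `1e-8`.

# Sobol initialization

Swarm positions start from a Gray-code Sobol sequence scaled to the decision
bounds, including the initial all-zeros point (a `skip_zero` flag drops it).
Dimensions 1–8 use published Joe–Kuo direction numbers; higher dimensions
use primitive polynomials over GF(2) enumerated algorithmically with
deterministically generated odd initial direction integers, which satisfies
Sobol's validity conditions ($m_i$ odd, $m_i < 2^i$) for every dimension.
An optional seeded digital-shift scramble (off by default) decorrelates
repeated experiments; full nested scrambling is intentionally not
implemented, as nothing in the package consumes it.

# The three objectives

For a binary mask over the $L$ genes (decoded from the continuous particle
position by `position > theta`, default $\theta=0.6$):

* **CA** — percent accuracy of an extreme learning machine (ELM) trained on
  the masked training features and scored on the validation split. The ELM
  has one hidden layer of `hidden_units = 100` sigmoid units with
  uniform$(-1,1)$ random weights under a per-mask derived seed, and
  ridge-regularized ($10^{-6}$) least-squares output weights on one-hot
  targets.
* **NF** — the subset size (an empty decode is penalized with $L+1$, so it
  can never pollute the archive).
* **NP_dist** — a neighborhood-preservation distance between the subset
  feature space and the reference geometry (the WNPEE embedding of the full
  normalized data; a flag switches to the raw full-gene space). For each
  sample, its $j$-th nearest reference-space neighbour is matched with its
  $j$-th nearest subset-space neighbour, and the Euclidean distance between
  those two points is measured *in the subset space*, averaged over
  $j \le k$ ($k = 10$) and samples. The value is zero exactly when the
  neighbour orderings agree; matching both neighbour lists inside one space
  keeps the comparison dimensionally well-posed. For reporting next to
  larger-is-better structure scores (ANO, rank correlation) the package
  also provides `np_score = 1/(1 + NP_dist)`.

Internally the optimizer minimizes $(100-\mathrm{CA},\ \mathrm{NF},\
\mathrm{NP})$; fitness is memoized per mask and fully seeded, so evaluation
is a pure function of (mask, data, seed).

# The optimizer

Velocities follow the constriction-style rule
$v' = w v + c_1 r_1 (pbest - x) + c_2 r_2 (gbest - x) + DE_v$ with
$w = 0.7298$, $c_1 = c_2 = 1.49445$, fresh uniform multipliers per
dimension, a velocity clamp of $\pm 0.2\times$ the decision range, and
position clamping to the bounds. The DE term builds a DE/rand/1 mutant
$x_{r1} + F (x_{r2} - x_{r3})$ ($F = 0.5$) from three distinct members of
the particle's 10-nearest neighbourhood in decision space, applies binomial
crossover against the current position with $CR = 0.5$ (one coordinate
always survives from the mutant), and scales the displacement by a
rank-adaptive factor $K \in [0.2, 0.8]$ mapped linearly from the particle's
non-domination rank — worse-ranked particles get larger perturbations.
Personal bests update under Pareto dominance; a mutually non-dominated
challenger replaces the incumbent with probability one half.

**Archive and selection score.** New and old solutions merge; only the
mutually non-dominated set is kept (exact duplicate decision vectors are
dropped; distinct positions with equal objectives — equivalent Pareto-set
members — are kept, which is what lets the optimizer cover several
equivalent Pareto subsets on multimodal problems). Each entry's HMD is the
harmonic mean of its distances to the other members in per-objective
min–max-normalized objective space, with HMD $=0$ for duplicates. The
combined score is the convex combination
$S = \beta\,\widetilde{\mathrm{HMD}} + (1-\beta)\,\widetilde{\mathrm{NP}}$
($\beta = 0.5$), where the tilde terms are min–max normalized within the
archive and oriented so that **low $S$ = isolated and structure-preserving**
($\widetilde{\mathrm{HMD}} = 1 - \mathrm{minmax}(\mathrm{HMD})$). This
orientation is the only one under which the three published behaviours
coexist: lower $S$ preferred, duplicates penalized first, and
archive truncation that preserves spread. Over-cap archives drop the
highest-$S$ entries in batches of at most a tenth of the excess,
recomputing HMD and $S$ between batches. Leaders (`gbest`) are drawn
uniformly from the lowest-$S$ decile, with a floor of five entries: gene-mode
fronts are often smaller than ten solutions, and a literal decile would
collapse all leadership onto a single solution, which measurably causes
premature convergence.

On benchmark problems there is no embedding, so the NP term of $S$ is a
decision-space crowding surrogate: the (negated) mean distance to the
entry's $k$ nearest archive neighbours in decision space, so entries on
sparsely covered equivalent Pareto subsets are favoured. This surrogate is
isolated in one function and used nowhere else.

**Returned subset.** The optimizer returns the archive, and in gene mode a
`SelectionResult` for the "best solution found": the archive entry with the
highest stratified 5-fold cross-validated accuracy on the *training* split
(ties: fewer genes, then holdout CA). The holdout CA drives the search; the
CV estimate is the more reliable judge of the final few candidates and never
touches held-out samples.

# Benchmarks and metrics

Eleven multimodal multi-objective problems are provided: MMF1–MMF8, the
SYM-PART simple and rotated problems, and the three-variable Omni-test.
These are problems whose decision spaces contain several equivalent Pareto
subsets mapping onto one front; definitions follow the multimodal
benchmarking literature (Yue, Qu & Liang 2018; Rudolph et al. 2007;
Deb & Tiwari 2005). For the two-branch MMF constructions the deviation term
uses the distance to the *nearer* of the two optimal-curve copies, which
makes both stated Pareto-set branches exactly optimal (the deviation enters
only through even functions, so on-branch objective values are unchanged).
Reference Pareto sets are sampled analytically at `make_problem()` time, and
reference fronts are the analytic trade-off curves sampled on a grid united
with the Pareto-set image, filtered to be strictly decreasing — hence exactly
mutually non-dominated while the set maps onto the front to floating
precision.

Metrics: exact sweep-line bi-objective hypervolume (reported as 1/HV,
smaller is better), error rate $1-\mathrm{acc}$, the IGDX/PSP family in
decision space (`igdx` is the mean over the obtained set of the minimum
*squared* distance to the reference set; `psp = CR/IGDX` with the
unsquared, reference-averaged IGDX and the per-dimension cover rate CR, and
`inv_psp = 1/psp` — all three are reported so neither orientation
convention is silently guessed), average neighborhood overlap, and the
classical Spearman rank-difference formula with average-rank ties.

**Hypervolume reference points.** These are part of the metric's
definition, not of the optimizer, and the package records them in every
benchmark summary. MMF1–MMF8 have fronts inside $[0,1]^2$ and use the
conventional $(1.1, 1.1)$. SYM-PART fronts span $[0,4]^2$ and use $1.1\times$
the nadir, $(4.4, 4.4)$. The Omni-test front is the radius-3 arc in the
third quadrant; its published evaluations use $(5,5)$, for which the true
front's 1/HV is $1/(25 + 30 + 9\pi/4) \approx 0.01611$, matching the values
reported across algorithms in the multimodal benchmarking literature. All
reference points are per-problem fields and configurable.

The benchmark protocol sizes the swarm at $100 \times N_{var}$ particles
with $4000 \times N_{var}$ fitness evaluations and aggregates 15
independent runs; `run_benchmark()` implements it, and
`scripts/acceptance.R` re-runs it end to end.

# The synthetic microarray generator

`generate_synthetic()` emulates the structure of public microarray panels
(2,000–10,000 genes, 50–200 samples, 2–5 classes) with a known ground
truth, so selection can be validated without external downloads. Defaults,
chosen once to mirror the hardest multi-class case of the emulated panels:
`n_classes = 5`, `n_informative = 5` one-vs-rest markers (marker $j$ is
up-shifted by `effect_size * noise_sd` in class $((j-1) \bmod C)+1$, so a
multi-class panel genuinely needs several markers), `n_redundant = 20`
noisy copies of the markers calibrated to a Pearson correlation of 0.8 with
their parents, `noise_sd = 1`, `effect_size = 2`, balanced classes, and a
deterministic stratified 2/3–1/3 train/test split. Min–max normalization is
per gene and is computed on the training samples only whenever a split is
present, so no information leaks from held-out data (the scaling-before-
or-after-split convention is not standardized in the field; this package
always scales on the training split).

What the generator does *not* emulate: heavy-tailed and batch-structured
noise, probe-level artefacts, class imbalance, and gene–gene correlation
beyond the single redundant block. Passing recovery tests on this generator
therefore demonstrates correct mechanics of the optimizer and objectives,
not performance claims on real tumour panels.

A note on recovery experiments: with the redundant block enabled, a
0.8-correlated copy of a marker can classify a small holdout perfectly, so
"the selected subset contains the true markers" is not identifiable — any
optimizer may legitimately return a copy. Recovery studies in the test
suite therefore plant markers among pure-noise genes (`n_redundant = 0`);
the redundant block is exercised by its own calibration tests.

# Numerical choices and degenerate inputs

* Gram-system ridge $10^{-3}\,\mathrm{tr}(G)$; eigenproblem ridge
  $10^{-6}\,\mathrm{tr}(XX^\top)/D$ — standard LLE/NPE practice for
  $D \gg N$.
* Ties in all neighbour searches break to the smaller sample index;
  eigenvector signs are canonicalized; `order()`-based tie-breaks make every
  run bit-reproducible under its seed.
* Zero per-graph loss puts the whole $\alpha$ mass on the zero-loss graphs
  (the $r\to$ limit case); zero distances give HMD $=0$; a constant
  objective column contributes zero to normalized scores; an empty gene
  decode receives worst-case objectives instead of erroring.
* One global seed fans out to per-component seeds through a counter-based
  derivation (`derive_seed`), so toggling one component does not shift the
  random stream of another.
* Problem sizes in the shipped tests are deliberately compact — e.g. a
  200-gene, 150-sample panel for recovery studies and 15-run benchmark
  summaries — chosen so the full suite re-runs in minutes while leaving
  every pipeline stage (embedding, swarm, archive, metrics) genuinely
  exercised.

# Known limitations

* Exact hypervolume is bi-objective only (all supported benchmarks are
  bi-objective); the gene-mode three-objective front is evaluated by
  accuracy/size/preservation rather than 3-D hypervolume.
* The ELM is the only wrapper classifier, as in the method this package
  implements; the fitness seed policy makes accuracies reproducible but
  still classifier-noise-limited on small validation splits.
* WNPEE solves a $D \times D$ generalized eigenproblem; for panels with
  $D \gtrsim 10^4$ genes a univariate pre-filter (`reference = "raw"` or
  external screening) is the practical route.
* Sobol direction numbers beyond dimension 8 are valid but not
  uniformity-optimized; at gene-mode dimensionalities this matters little,
  and all published-value dimensions (the benchmark problems) use the
  published table.
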