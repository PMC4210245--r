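---
title: "Methods: inventory, likelihood-ratio integration, and network prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inventory, likelihood-ratio integration, and network prioritization}
  %\VignetteEncoding{UTF-8}
---

This vignette records the statistical model behind each stage of the
package, the parameter choices and their rationale, the numerical
conventions, and what the synthetic benchmark does and does not
demonstrate.

## 1. Protein inventory

### Model

The feature space is a binary gene-by-experiment detection matrix: entry
`(i, j)` is 1 when gene product `i` was identified in proteomic
experiment `j`. Mitochondrial purifications are contaminated to varying
degrees, so single-experiment membership calls are unreliable; the
classifier treats the 0/1 columns as features and learns which detection
profiles indicate genuine mitochondrial proteins.

The classifier is AdaBoost.M1 over one-feature decision stumps. On binary
features a stump is fully described by its feature index and the feature
value that votes positive, and the degenerate stump whose split carries no
information reduces to a constant vote — we include it, because it is the
intercept of the ensemble and without it a boosted vote over 0/1 features
can only express symmetric majority thresholds, not the asymmetric count
thresholds that unequal detection rates demand. Ties between candidate
stumps break toward the lowest feature index, and polarity ties toward the
value-1 rule; training involves no randomness, so the model is a
deterministic function of the data and input order. Boosting stops early
at a perfect weak learner (its capped vote already dominates) or when no
stump beats chance.

Quality is estimated by stratified 10-fold cross-validation. We stratify
(rather than partition completely at random) so that both classes appear
in every fold even at small sample sizes; the partition is otherwise a
seeded uniform shuffle. Sensitivity is `TP/(TP+FN)` and the false
discovery rate `FP/(FP+TP)`; a zero denominator raises a classed error
(`mitofln_undefined_metric`) rather than silently returning 0, because a
silent 0 is indistinguishable from a genuine measurement.

### Tier policy

`assemble_inventory()` implements the voting policy: the high-confidence
tier is the union of classifier positives and the curated gold-standard
positives (curated genes the classifier missed are restored, since
curation outranks prediction); remaining genes are middle-confidence when
they occur in the reference compendium or in more than `vote_threshold`
experiments, else low-confidence. "More than five" is read strictly:
`vote_threshold = 5` means at least 6 detections. The three tiers
partition the gene universe exactly.

## 2. Evidence integration

### Likelihood ratios and naive Bayes

Gold-standard positives are unordered pairs sharing at least one
pathway/complex annotation; negatives are pairs where both genes are
annotated but share no term. For each evidence source the scores observed
on gold pairs are binned, and bin `b` receives

```
LR_b = ((pos_b + c) / (pos_tot + B c)) / ((neg_b + c) / (neg_tot + B c))
```

with `B` bins and pseudocount `c`. Under conditional independence of
evidences given the class, a pair's composite likelihood ratio is the
product of its per-evidence bin LRs and the posterior odds are the prior
odds times that product. The package accumulates the product in the log
domain; an exact-identity test confirms agreement with the direct product
to 12 significant digits.

Choices, and why:

- **Binning: equal-frequency (quantile), default 5 bins.** Quantile bins
  are robust to the skewed score distributions typical of similarity and
  correlation measures, and 5 bins keeps at least tens of gold pairs per
  bin at the problem sizes used here. When a score takes at most `n_bins`
  distinct values (binary or categorical evidence) the distinct values
  themselves become the bins.
- **Smoothing: Laplace pseudocount 1.** Guarantees every bin LR is finite
  and positive even when a bin holds no negatives (or positives); with
  pseudocount 0 the raw count ratio is recovered exactly.
- **Missing evidence contributes factor 1.** Naive Bayes tolerates missing
  data by dropping the factor; no imputation is attempted, and missingness
  is assumed uninformative (see the generator below, which enforces
  exactly this assumption).
- **Out-of-range scores clamp to the end bins**, since the outer bins are
  open-ended; categorical values never seen in training contribute the
  neutral factor 1.
- **Prior odds default 1**, so cutoffs act on the LR scale directly.
- **Coverage screening**: the fraction of gold pairs an evidence scores;
  0.20 is the conventional inclusion floor. Low-coverage evidences can
  still be fitted and inspected individually.
- **Independence screening**: pairwise Pearson correlation of evidence
  scores on commonly covered gold pairs, with fewer than 3 common
  observations reported as not assessable (`NA`).

### Cutoff and network

The TP/FP ratio over gold pairs is computed as a function of the LR
cutoff; where the ratio is at least 1, calling a pair "linked" is at
least 50% precise. `select_cutoff()` returns the smallest evaluated
cutoff whose ratio reaches the target (ties toward the smaller cutoff, to
preserve network coverage). Edges at or above the cutoff, weighted by
their composite LR, form the FLN; genes with no retained edge are dropped
from the node set but kept in an isolated-gene registry so that rankings
can still cover the full inventory. Network summary statistics are
average neighbors `2E/N` and density `2E/(N(N-1))`.

Two pair-counting conventions coexist: the combinatorial `n(n-1)/2`, used
for all internal computation, and a squared-halved convention
`floor(n^2/2)` that some published inventories use when quoting potential
linkage counts; `pair_count()` exposes both so either figure can be
reproduced deliberately.

### Integration cross-validation

Five stratified folds over the gold standard; per fold, LR models are
fitted on four folds and the held-out pairs are scored by each single
evidence, by the full integrated product, and by scale-restricted subsets
(genome-scale vs mitochondria-specific). Pooled held-out scores give one
ROC per model with trapezoidal AUC. On synthetic data with several
informative, conditionally independent evidences, the integrated model's
AUC exceeds every single evidence's — the package asserts this
statistically over 10 simulation seeds (allowing one exception) rather
than as a fixed number, because the margin depends on the draw.

## 3. Prioritization

All four algorithms operate on the transition model: symmetric weighted
adjacency `A`, weighted degrees `D`, row-stochastic `W = D^-1 A`, and
`L = I - W`.

**Orientation.** The update `p <- t(W) p` propagates probability mass
from seeds outward along transition probabilities; the alternative
orientation (`W p`) mixes incoming neighborhoods instead. The equations
as usually written are ambiguous on this point, so the package fixes the
transpose convention and verifies each algorithm against a dense oracle:
PRP against the direct linear solve `beta (I - (1-beta) W')^{-1} p`, KSM
against explicit matrix-power sums, HKDR against the dense matrix
exponential `exp(-alpha L') p_0`, and AAR against full subset
enumeration.

- **AAR.** Per iteration, `m` seeds are sampled and every gene outside
  the sample accrues its summed linkage weight to the sampled seeds; the
  final score divides each gene's accumulated sum by the number of
  iterations in which that gene was eligible (not sampled). The
  normalization is per-gene eligibility, not the raw iteration count:
  genes that are themselves seeds are only scoreable in iterations that
  exclude them, and dividing by the global count would penalize them
  artificially. Default 100 iterations; `m` equal to the full seed set is
  the deterministic limit (score = summed adjacency to all seeds).
- **PRP.** Power iteration from the prior, stopping when the L1 change
  drops below `tol` (default 1e-10); non-convergence raises a classed
  error carrying the residual. Mass lost at zero-degree (dangling) nodes
  is re-injected by renormalizing to sum 1 each step; on networks without
  zero-degree nodes the renormalization is inert. `beta = 1` returns the
  prior exactly. Default `beta = 0.3`.
- **KSM.** `K` sparse matrix-vector products accumulated; scores total
  `K` when all reached nodes have positive degree. Default `K = 6`.
- **HKDR.** `N` applications of `(1 - alpha/N) I + (alpha/N) W'`;
  `alpha = 0` is the identity. The integer iteration count `N` is the
  parameter conventionally swept (2-7) with the diffusion rate `alpha`
  fixed at 1 but independently configurable — `N` is the only integer
  parameter in the recurrence, and small `N` under-diffuses usefully on
  modular networks.
- **Zero-degree nodes** are excluded from normalization, score 0, and are
  flagged; they sort into the terminal tie band of any ranking.

Rankings order by descending score with ties broken by ascending gene
identifier (deterministic everywhere); seeds are excluded unless
requested, and optional bands split candidates by score tertiles.

### Evaluation

Leave-one-out: for each disease with at least two genes in the network
(smaller sets are skipped and logged), each member is held out and
re-ranked from the remaining members. The negative pool for specificity
is every network gene not annotated to the disease under evaluation.
Trials pool across diseases into one ROC — matching the
single-curve-per-algorithm presentation — with per-disease curves
available by subsetting the records. The score axis is the normalized
rank `rank/pool`, which makes pools of different sizes commensurable, and
the curve is evaluated at every attainable rank fraction so the
trapezoidal AUC equals the exact rank-based AUC (reversing all rankings
maps AUC to `1 - AUC` exactly). Parameter sweeps report AUC per grid
point (HKDR `N = 2..7`, PRP `beta = 0.01..0.95`, KSM `K = 2..9`), with
ties toward the smaller parameter value.

## 4. The synthetic-data generator

The generator emulates exactly the statistical structure the pipeline
assumes, with ground truth recorded:

- **World**: `n_mito` mitochondrial plus `n_nonmito` contaminant genes;
  pathway memberships sampled without replacement from the mitochondrial
  genes (sizes uniform on a configurable interval), from which the gold
  standard derives; genes may carry several annotations.
- **Detections**: independent Bernoulli per gene per experiment with
  class-specific rates. The benchmark default — 23 experiments, detection
  probability 0.6 for mitochondrial genes versus 0.1 for contaminants —
  represents a realistic mid-abundance protein in repeated organelle
  purifications: detected more often than not when genuine, sporadically
  when a contaminant.
- **Evidence**: class-conditional score distributions per evidence
  (Normal and Beta families; both classes must share a family so the
  supports coincide). Normal suits correlation-like scores, Beta suits
  bounded similarity scores. Coverage is applied uniformly at random,
  independent of class — the same "missingness is uninformative"
  assumption the integration makes; informative missingness is
  deliberately not simulated.
- **Disease modules**: disjoint gene sets planted in a built network by
  multiplying internal edge weights by `boost`; internal edges absent
  from the network are created at the network's median edge weight (times
  `boost`) so the boost stays interpretable across networks. `boost = 1`
  is an exact no-op — edges are only added when a genuine boost is
  requested, since silently densifying the network at the identity
  setting would contradict the parameter's meaning.

Every generator is a pure function of its integer seed: RNG state is
scoped and restored, so calls are reproducible and never perturb the
caller's random stream.

**What passing synthetic tests shows — and does not.** The benchmark
demonstrates correctness of the estimators and algorithms under the
model's own assumptions (conditional independence of evidences,
uninformative missingness, class-conditional i.i.d. scores, Bernoulli
detections). Real proteomic and genomic evidence violates these in known
ways: evidences correlate (hence the PCC screen), detection varies by
tissue and abundance, and score distributions are rarely clean parametric
families. Absolute performance numbers from the synthetic benchmark
(AUCs, sensitivities) therefore characterize the implementation, not any
real dataset.

## 5. Problem sizes and runtime choices

The test suite and the acceptance script use a standard benchmark world of
120 mitochondrial + 60 contaminant genes with 12 pathways (about 450
positive and 2200 negative gold pairs), three evidences, and planted
modules of 5 genes — sizes at which every estimate is stable across seeds
while the full suite completes in well under a minute of compute per
stage. Large-sample checks (bin-LR recovery, chance-level AUC) use 1e5
fabricated gold pairs, where the binomial error on a bin LR is a few
percent. Classifier benchmarks use 1000 + 1000 genes over 23 experiments,
matching the feature-space width of the motivating data.

## 6. Known limitations

- Evidence preprocessing (computing semantic similarity, phylogenetic
  profiles, co-expression correlations from raw data) is out of scope:
  evidence arrives as generic pairwise score tables.
- The naive Bayes combination is used as-is even when the PCC screen
  flags correlated evidences; down-weighting or decorrelating dependent
  evidences is not implemented.
- The AdaBoost implementation targets binary detection features only;
  continuous features would need threshold stumps.
- Only the selected boosted classifier is provided; the broader classifier
  comparison that motivated its selection is not reproduced.
- LOOCV re-runs the ranking algorithm per held-out gene; on networks far
  larger than the inventory scale (~1e3 nodes) a batched implementation
  would be preferable.
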