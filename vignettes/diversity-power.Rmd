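---
title: "Power analysis for diversity-based microbiome studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power analysis for diversity-based microbiome studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`divpower` supports the two inferential routes of a group-comparison
microbiome study and the power analysis of both:

1. **Univariate (alpha) route.** Each sample is summarized by one diversity
   value; groups are compared with the Kruskal–Wallis test. Power and sample
   size can be computed in closed form once an effect size (Cohen's *d*) is
   available, because for two groups the Kruskal–Wallis test is equivalent to
   the Wilcoxon–Mann–Whitney (WMW) test.
2. **Multivariate (beta) route.** Samples are compared pairwise through a
   dissimilarity; groups are compared with PERMANOVA. No closed-form power
   theory applies — the F-like statistic does not follow an F distribution —
   so power is estimated *empirically*, by resampling pilot or simulated data.

This vignette records the statistical definitions, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical/design decisions a maintainer would want explained.

# Diversity metrics

**Alpha.** Observed richness counts features with abundance strictly
positive. Shannon's index is the natural-log entropy $-\sum p_i \ln p_i$
(the natural log is the convention under which an even community of $s$ taxa
scores $\ln s$). Simpson's index defaults to the Gini–Simpson form
$1 - \sum p_i^2$, which lies in $[0, 1]$ and *increases* with diversity;
the inverse form $1/\sum p_i^2$ and the dominance form $\sum p_i^2$ are
selectable, and the three are algebraically interconvertible (tested).
Chao1 uses the bias-corrected estimator
$$\hat S = s + \frac{F_1 (F_1 - 1)}{2 (F_2 + 1)},$$
with $F_1, F_2$ the singleton and doubleton counts. The bias-corrected
denominator $2(F_2 + 1)$ is used deliberately: the variant with $2 F_2$ (or
a mis-typeset $2(F_2-1)$) is undefined or negative when doubletons are rare,
which is the norm in sparse amplicon tables. Chao1 requires integer counts
and refuses real-valued (e.g. perturbed) tables rather than rounding
silently. Faith's PD is the sum of branch lengths of the subtree spanning
the observed taxa *including the path to the root of the supplied rooted
tree*; the root-inclusive convention is one consistent resolution of the
ambiguity a single observed taxon creates (the "spanning subtree" of one
leaf is otherwise empty), and matches `picante::pd(include.root = TRUE)`,
against which it is cross-tested.

No rarefaction or subsampling-to-even-depth is applied anywhere: metrics are
computed on tables as given, and depth handling is the user's upstream
decision.

**Beta.** Bray–Curtis follows
$1 - 2\sum_f \min(x_{if}, x_{jf}) / (S_i + S_j)$ on abundances *as given*
(totals, not proportions — so it is not invariant to per-sample rescaling,
which is tested both ways). Jaccard is one minus shared-over-union on
presence/absence. Unweighted UniFrac is the branch length leading
exclusively to one sample's taxa divided by the branch length leading to
either sample's taxa; it depends on presence/absence only (binarizing the
table leaves it unchanged, tested). Weighted UniFrac is
$\sum_i b_i \, |A_i/A_T - B_i/B_T|$ over branches; the absolute value is
required for the sum to be a distance. The *raw* (non-normalized) form is
the default; `normalized = TRUE` divides by $\sum_i b_i (A_i/A_T + B_i/B_T)$
to bound it by 1. All four implementations are verified against brute-force
per-edge enumeration oracles on random trees.

Internally the two phylogenetic metrics share a sparse edge-by-tip indicator
matrix built in one postorder pass; per-sample edge masses are then a single
sparse matrix product, and all pairwise distances reduce to (weighted)
Manhattan distances between rows of a samples-by-edges matrix, computed by
`vegan::vegdist`. This makes whole-matrix UniFrac on a 338-sample,
1995-feature, ~4000-edge problem take about a second.

**Group centroid distances** embed the dissimilarity matrix by principal
coordinates, keep negative-eigenvalue axes as imaginary coordinates, and
measure each sample's squared distance to its group centroid as (real-axis
squared distance) − (imaginary-axis squared distance), clipped at zero —
standard dispersion-analysis practice for semi-metric dissimilarities like
Bray–Curtis, delegated to `vegan::betadisper(type = "centroid")` and
verified against direct coordinate arithmetic on Euclidean inputs.

# Group tests and effect sizes

`kruskal_wallis()` wraps `stats::kruskal.test`, i.e. the statistic with the
standard $12/(N(N+1))$ normalization, midrank ties and the usual tie
correction, with a $\chi^2_{k-1}$ reference distribution. Tie correction
matters here because resampling with replacement duplicates samples and real
alpha values tie often. When every observation is identical the
tie-corrected statistic is 0/0; the test then returns $H = 0$, $p = 1$, and
the empirical-power engine counts such replicates as non-rejections so that
the denominator $K$ is never reduced. Effect sizes: the rank eta-squared
$\eta^2 = (H - k + 1)/(N - k)$, and for two groups Cohen's
$d = |m_1 - m_2| / \sqrt{(s_1^2 + s_2^2)/2}$.

The **equal-weight pooled SD** (rather than $n$-weighted pooling) is a
deliberate convention: effect sizes here are typically read off published
"mean (SD)" pilot tables whose group sizes differ, and equal-weight pooling
is the convention that makes such table-derived effects reproducible without
knowing the group sizes.

`permanova()` uses the distance-based decomposition
$SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2$,
$SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$, $SS_B = SS_T - SS_W$,
and pseudo-$F = (SS_B/(g-1))/(SS_W/(n-g))$. On univariate Euclidean input
this is algebraically the classical one-way ANOVA F, which is one of the
test oracles (the other is `vegan::adonis2`, which matches to full
precision). The permutation p-value uses $(b + 1)/(k + 1)$ — the observed
statistic counts as one permutation — so $p = 0$ is impossible and the
smallest attainable p is $1/(k+1)$; the literal fraction $b/k$ differs by at
most $1/(k+1)$. The default is 9,999 permutations; unit tests use a few
hundred. Effect sizes: Cohen's $f^2 = SS_B/SS_W$ and
$$\omega^2 = \frac{SS_B - (g-1)\, MS_W}{SS_T + MS_W},$$
the standard total-SS denominator (a variant with $SS_{effect}$ in the
denominator can exceed 1 and is not used).

PERMANOVA assumes exchangeability; when the empirical-power engine feeds it
tables resampled *with replacement*, duplicated samples (zero mutual
distance) are permuted as ordinary units. This is a documented limitation of
resampling-based PERMANOVA power estimation, mitigated by the null
calibration test, which confirms the nominal rejection rate under exactly
this duplication regime.

# Analytic power

For the two-sample t test the power at group sizes $n_1, n_2$ is the
noncentral-t tail beyond the central-t critical value, with
$\mathrm{ncp} = d\sqrt{n_1 n_2 / N}$ and $df = N - 2$. For the WMW test the
**A.R.E. method** is used: both the noncentrality and the degrees of freedom
are multiplied by the asymptotic relative efficiency of WMW against the t
test — $3/\pi \approx 0.955$ for a normal parent distribution (the default),
or the distribution-free lower bound 0.864 (`parent = "min"`). With
A.R.E. = 1 the machinery degenerates exactly to the t test (tested). Because
$3/\pi < 1$, WMW power never exceeds t-test power at the same $(d, n)$ under
the normal parent, and that ordering is checked over a grid. A two-group
Kruskal–Wallis test is the WMW test, so these calculations serve the alpha
route directly; analytic Kruskal–Wallis power for $k > 2$ groups requires
specifying the population offsets under the alternative and is out of scope.

For balanced one-way ANOVA the power uses the noncentral F distribution with
$\lambda = f^2 N$ and df $(g - 1, N - g)$.

`sample_size()` inverts these by integer search and reports the *achieved*
power (which slightly exceeds the request). Two conventions coexist, each
matching what practitioners' standard software does for the corresponding
test:

* **t/WMW**: search over integer group sizes respecting the allocation
  ratio ($n_2 = \mathrm{round}(r\, n_1)$) — group sizes must be integers.
* **ANOVA (omnibus)**: search over the *total* N, the convention used by
  G*Power for the fixed-effects omnibus one-way test, reporting the
  per-group size $N/g$, possibly fractional (e.g. a total of 85 for two
  groups is reported as 42.5 per group). The balanced integer-per-group
  reading can differ by one sample in borderline cases; the total-N search
  is the one that reproduces standard software output.

Internally everything is `stats::pt/qt/pf/qf`; at large df the noncentral-t
power agrees with the normal-approximation closed form within 0.005
(tested), and `stats::power.t.test` is a test oracle (it drops the
opposite-tail rejection mass, so two-sided comparisons agree to ~$10^{-3}$
at small n and exactly one-sided).

# Empirical power

Given two source tables $X_1, X_2$ (pilot data or a simulation) the engine
draws, for each per-group size $n$ on a grid, $K$ replicate datasets of $n$
rows sampled independently **with replacement** from each source, runs the
chosen test at level $\alpha$, and reports
$$EPr(n) = \frac{\#\{\text{replicates with } p < \alpha\}}{K}$$
with a 95% binomial confidence interval. Defaults follow common
retrospective practice: grid 5..50 by 5, $K = 1000$ for alpha tests,
$K = 100$ for beta tests (each beta replicate runs a permutation test),
$\alpha = 0.01$.

Reproducibility: one master seed spawns an independent sub-seed per
(grid point, replicate), so curves are bit-reproducible and insensitive to
the order in which grid points are evaluated. Within a replicate, the
subsample indices and the PERMANOVA permutation stream come from that
replicate's seed.

Computation: a resampled sample *is* a row of its source, so per-sample
alpha values are computed once on the sources and sliced per replicate, and
the pooled distance matrix is computed once and sliced per replicate. The
slow path that recomputes everything from each resampled table exists behind
`recompute = TRUE` and the two paths are asserted identical in the tests.

# The synthetic-data generator

Two base regimes are provided, chosen to bracket the community structures
that matter for power behaviour:

* `community_spec()` (default): a **sparse, skewed, stool-like** community —
  169 samples by 1995 features, feature proportions from a log-normal
  rank-abundance curve (log-scale SD `skew = 2`), per-sample compositions
  Dirichlet-multinomial with concentration `theta = 20` (strong
  overdispersion), negative-binomial depths (mean 5000, size 10). These
  values were calibrated once so that the mean per-sample observed richness
  is about 70 of 1995 features with Shannon near 3.2 and Gini–Simpson near
  0.9 — the scale of a human-gut amplicon survey.
* `dense_community_spec()`: a **dense, homogeneous** community
  (Poisson-log-normal counts, `skew = 0.8`, depth 5000, log-noise SD 0.8)
  with per-sample richness around 70% of the feature pool, Shannon near 6.7
  and between-sample Bray–Curtis near 0.5 with small spread — the regime in
  which small systematic abundance shifts are detectable at realistic sample
  sizes.

Perturbation scenarios:

* `apply_presence_absence(x, fraction)` zeroes a random set of
  `round(fraction * m)` feature columns in every sample — a global removal,
  so the perturbed support is a subset of the original and presence/absence
  metrics see the difference.
* `apply_differential_abundance(x, q, affected_fraction)` multiplies a
  random quarter (by default) of the columns by $1 + q/100$ in every sample.
  Presence/absence is preserved *exactly*, which is the structural reason
  purely presence/absence metrics (Jaccard, unweighted UniFrac) have no
  power against this scenario — an ordering the acceptance tests verify.

The tree is a random pure-birth topology with independent exponential(1)
branch lengths; the UniFrac properties under test do not depend on the tree
prior. `two_group_alpha_effect()` manufactures a two-group dataset whose
realized Cohen's d on a chosen alpha metric hits a target within 15%
(bisection on a skew multiplier for group 2), used to cross-check empirical
Kruskal–Wallis power against the analytic WMW prediction.

**What the generator does not emulate.** Real amplicon data have taxonomic
block structure, batch effects, depth-composition coupling and much heavier
between-sample dispersion heterogeneity than a Dirichlet-multinomial. In
particular, under the sparse default the within-group dispersion is large
relative to the deterministic shifts of the differential-abundance scenario,
so at shift percentages of a few percent *all* metrics are near the null
there — the scenario only becomes detectable on the dense base at larger
sample sizes. Passing tests therefore demonstrate the engine's statistical
correctness (null calibration, orderings, analytic/empirical agreement), not
that any particular real study at these sizes would achieve these powers.

# Numerical choices and degenerate inputs

* Symmetry tolerance for distance matrices is $10^{-10}$ absolute; matrices
  are symmetrized as $(d + t(d))/2$ on read and diagonals forced to zero.
* Newick branch lengths are mandatory; a missing length is an error, never a
  silent zero. Trees are written with 17 significant digits so round-trips
  hold to $10^{-12}$.
* Features present in a table but absent from the tree are an error unless
  pruning is requested explicitly (`prune = TRUE`); silent intersection
  hides bugs.
* All-zero samples make Shannon/Simpson and every dissimilarity undefined
  and are rejected.
* Ties in `min()`/set operations need no tie-breaking; everything is double
  precision.
* Degenerate test replicates (all values tied; groups of one) are handled as
  described above: non-rejections and errors respectively, never silent
  drops.

# Problem sizes in the test suite

The test suite exercises the full default community (169 × 1995) for the
calibration checks: null rejection rates for all five alpha metrics
(K = 1000 per grid point, n ∈ {5, 15, 30}) and all four beta metrics
(K = 100, 999 permutations), scenario-structure checks at K = 50, a
six-point power curve at K = 200, and the analytic/empirical cross-check at
K = 500 — sizes chosen so the whole suite runs in well under a minute on one
CPU while keeping the binomial confidence intervals tight enough for the
99%-level calibration assertions. Metric-level oracles run on random trees
of ≤ 20 leaves where brute-force edge enumeration is cheap.

# Known limitations

* Analytic PERMANOVA power is intentionally absent: the pseudo-F does not
  follow an F distribution, so the only honest route is the empirical
  engine.
* Analytic Kruskal–Wallis power for more than two groups is out of scope
  (requires alternative-specific population offsets).
* Resampling with replacement duplicates samples; PERMANOVA permutes them as
  exchangeable units (see above).
* The multivariate protocol reports observed $\omega^2$ and $f$ ranges
  across iterations as *descriptions of the pilot run*, not as inputs to any
  F-based sample-size formula — using them that way would be exactly the
  mistake the empirical engine exists to avoid.
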