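---
title: "Differential dependencies and mutually exclusive feature sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential dependencies and mutually exclusive feature sets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depmex)
```

# The problem

Genome-wide CRISPR-Cas9 knockout screens assign every gene a quantitative
dependency score in each cell line (CERES-scale scores: around -1 for
common-essential genes, around 0 for non-dependencies). For most genes the
score distribution across a cell-line panel is unimodal. For a biologically
interesting minority it is bimodal: a subset of *responsive* lines is
strongly affected by the knockout while the *background* population is not.
Such *differential dependencies* are candidate selective targets, and the
natural follow-up question is which somatic mutations or cell types mark
the responsive lines. Because driver alterations of one pathway tend to be
*mutually exclusive* across tumors, the marker is often not a single
mutation but a small, approximately mutually exclusive set.

`depmex` implements the full chain: mixture-model scoring of differential
dependencies, construction of a binary feature matrix from annotated
mutations and cancer types, exact combinatorial search for the
best-associated approximately-exclusive feature set, and permutation-based
significance with FDR control. A seeded synthetic-cohort generator with
planted ground truth makes every stage testable offline.

# Scoring model

Each profile (one gene's scores across $n$ samples, z-scored) is fit with a
one-component t distribution and a two-component t mixture by EM. The t
family absorbs the heavy tails typical of screen scores. Model selection
uses BIC, $\mathrm{BIC} = p\ln n - 2\ell$, with $p = 3$ for the single t
(location, scale, df) and $p = 7$ for the mixture ($2\times 3$ plus one
mixing weight); a profile is a two-component ("2C") differential dependency
iff the mixture BIC is smaller.

For a 2C profile, posterior scores come from a two-component *Gaussian*
mixture fit of the same data (following the reference protocol, which
separates the selection family from the scoring family; the two fits are
initialized independently). The per-sample 2C score is the log posterior
odds
$$d_j = \ln \Pr(z_j = 2 \mid p_j) - \ln \Pr(z_j = 1 \mid p_j),$$
with component 1 the component with the smaller mean, so negative scores
mean stronger dependency. Samples are hard-assigned to their more probable
component; the smaller class is the responsive component (tie: component 1,
logged — the model assumes a true minority exists). The profile direction
is *increased* when the responsive component is component 1.

EM details (chosen where the protocol is silent): k-means-style plus a
quantile-split initialization and 5 random restarts, all deterministic
given the seed; convergence when the log-likelihood improves by less than
1e-8 (capped at 200 iterations); scale floor $\sigma \ge 10^{-6}$; t
degrees of freedom per component by the Liu–Rubin digamma-equation update,
bounded to $[2.1, 100]$; restarts whose solution collapses onto fewer than
two hard-assigned points are rejected (spike guard). Natural logarithms
throughout. Missing values are dropped per profile and propagate as missing
2C scores.

A 6-sigma outlier prefilter (`sigma_outlier_filter`) is available and
matches the screen-literature criterion (at least one sample at least six
sample standard deviations from the profile mean). `run_pipeline` does
*not* apply it by default: on light-tailed two-component profiles with a
sizable minority the criterion is never met (a fraction $f$ of mass can sit
at most $\sqrt{(1-f)/f}$ standard deviations out), so chaining it would
contradict the synthetic world this package is validated on. The 3-sigma /
20% variant is implemented as specified but note that "20% of samples
beyond 3 sd" is unattainable for z-scores computed on the profile itself
(Chebyshev caps that fraction at 1/9); it is only meaningful for inputs
whose dispersion is dominated by a different reference scale.

`norm_lrt` provides the NormLRT comparison statistic,
$2[\ell(\text{skew-t}) - \ell(\text{Gaussian})]$, with the Azzalini skew-t
fit by direct likelihood optimization from several slant starting points.
It is comparison-only and not part of the pipeline.

# Feature construction

Mutations are consumed pre-annotated (OncoKB-annotator-style columns), so
runs are deterministic and offline. Silent / other-conserving calls are
excluded. For each OncoKB-curated gene, calls map to at most three
features: not-oncogenic calls (Likely Neutral, Inconclusive, Unknown — and
Resistance, which the reference rules predate; it is mapped with the
not-oncogenic group and logged) to `GENE(O)`; oncogenic calls with
(Likely) Gain-of-function effect to `GENE(A)`; with (Likely)
Loss-of-function to `GENE(I)`; with any other effect to `GENE(O)`.
Cancer-type features are one indicator row per label and are disjoint by
construction. Mutation and cancer-type blocks concatenate after aligning
samples by id.

# The association objective

For a 2C profile with direction *increased*, let
$S = \sum_{d_j < 0} d_j$ and $d'_j = d_j / |S|$, so the responsive-side
mass of $d'$ sums to $-1$ (for *decreased*, $S$ sums the positive side and
the responsive mass is $+1$). Dividing by $|S|$ rather than $S$ keeps
responsive samples negative under the increased-direction minimization —
the signed division printed in the reference would flip the objective's
sense; the choice is verified against exhaustive enumeration. The
co-occurrence penalty is $\rho_j = -|d'_j|$ (increased) or $+|d'_j|$
(decreased).

The weight of a feature set $M$ is
$$W(M) = \sum_{j \in \Gamma(M)} d'_j - (c_j(M) - 1)\,\rho_j,$$
where $\Gamma(M)$ is the set of covered samples and $c_j(M)$ counts the
*penalty groups* of $M$ covering sample $j$: the same gene's (I) and (O)
features form one group — a second hit on an already-inactivated gene is
not evidence against exclusivity (two-hit exception) — and every other
feature counts separately. Exclusive coverage is rewarded by the full 2C
mass; each extra co-occurring group costs $|d'_j|$. With all
$d'_j = \rho_j = 1$ the weight reduces to the classical Dendrix weight
$2|\Gamma(M)| - \sum_{m \in M} |\Gamma(m)|$, which the tests assert on
random matrices.

The optimum over all sets of size at most $k$ ($k = 3$ for mutation-only
runs, $5$ with cancer types) is found *exactly*. No MILP solver is
available in the deployment image, so the integer program is solved by an
equivalent depth-first branch-and-bound: in the canonical maximize form
$U(M) = \sum_{j\in\Gamma(M)} v_j - (c_j - 1)|d'_j|$ (with $v = -d'$ or
$+d'$ by direction), a feature can contribute at most its positive-$v$
coverage mass, giving an admissible bound from suffix top-$k$ sums.
Features are explored in sorted-label order, include-branch first, and the
incumbent is replaced only on strict improvement, which makes the
first-found optimum the lexicographically smallest optimal set (shorter
prefixes first) — the documented tie-break. The empty set (weight 0) is
returned when no set improves on it: a harmful set is never reported.
Exhaustive enumeration (`solve_exclusive_cover_enum`) is kept as an
independent oracle and the acceptance suite asserts equality of the two
routes on hundreds of random instances, two-hit cases included.

# Model selection and significance

*Conditional model selection.* The size of the optimal set is not known a
priori, so each member is tested by permuting its own row across samples
(count preserved) and recomputing the set weight; $p_m$ is the add-one
fraction of permutations at least as extreme as the observed weight. The
worst feature is removed if $p_m$ exceeds the removal threshold (reference
protocol: $10^{-4}$ over 10,000 permutations) and the procedure repeats on
the reduced set, whose weight becomes the new observed statistic. Note the
add-one estimator floors $p$ at $1/(N+1)$: the $10^{-4}$ threshold is
attainable only with $N \ge 9{,}999$. Reduced-budget runs (tests) scale the
threshold as $2/(N+1)$ so the rule keeps its meaning.

*Fixed-margin significance.* The retained set's weight is compared against
optimal weights recomputed on randomized cohorts with the *full* mutation
table's margins preserved: one binary row per distinct mutation identity
(gene, variant, annotation — including mutations outside OncoKB), curveball
trade-chain randomization (default 5 trades per row, a fresh chain per
permutation), regrouping into features by the same rules, and re-solving
with the same $k$ and no model selection. Cancer-type rows, whose margins
are fixed by construction, are held fixed. The empirical p-value uses the
add-one estimator, so $p \in [1/(N+1), 1]$; the reference estimator (which
can be 0) is recovered as $N \to \infty$. Two computational devices do not
change the counted statistic: the permutation search is seeded with an
incumbent just below the observed value (it only needs to resolve whether
the permuted optimum reaches the observed one), and sampling stops early
when the 99% binomial CI for $p$ lies above a reporting threshold (default
0.25, safely above the q = 0.2 discovery band; the reference protocol says
"up to 500,000" without a rule). A `permute_features_directly` switch
randomizes the feature matrix itself — faster, approximate, and labeled as
such.

Across all profiles tested in a run (each in its own responsive direction
by default), Benjamini–Hochberg q-values are computed as one family and
associations are reported at $q \le 0.2$.

# Synthetic cohorts

The generator states the world the package is validated in, mirroring a
processed dependency screen:

* 769 samples by default; dependency profiles on the z-score scale (unit
  marginal variance), because that is what the scoring module consumes.
  A differential gene has responsive fraction $\pi = 0.23$ (the reference
  cohort's average responsive share) and component separation
  $\Delta\mu = 4$ pooled within-component standard deviations, so
  $\sigma_c = 1/\sqrt{1 + \pi(1-\pi)\Delta\mu^2}$; 87% of differential
  genes have increased direction (446/511 in the reference cohort).
* Planted features: per differential gene, 3 features partition 90% of the
  responsive samples; a covered sample carries a second planted feature
  with probability $1 - \text{exclusivity}$ (default exclusivity 0.95).
  Planted classes cycle through (A)/(I)/(O) so the two-hit machinery is
  exercised. Records carry 1–3 distinct protein changes per feature so the
  identity-level permutation matrix is non-trivial.
* Background mutations: gamma-mixed Bernoulli — per-sample rate multiplier
  $\mathrm{Gamma}(h, h)$ (default $h = 1$) times a per-feature base rate
  (default 0.03, log-uniform jitter) — giving the over-dispersed per-sample
  burdens (hypermutator-like) seen in real cohorts; half of the decoy
  genes are OncoKB-annotated (and become decoy features), half only
  contribute to the permutation margins.
* Optional cancer-type labels with gamma-weighted frequencies; a flag
  plants one type-driven dependency (responsive set = one type).

What the generator does **not** emulate: gene–gene correlation of
dependency profiles, guide-level CERES estimation, mutational signatures,
and realistic linkage between mutations and cancer types. A green
end-to-end test therefore establishes correctness of the algorithmic chain
on cohorts with the stated marginal structure, not performance on real
DepMap data.

# Numerical choices and edge cases

* Ties: equal-weight optimal sets resolve to the lexicographically
  smallest label set; equal-size mixture components designate component 1
  (smaller mean) responsive; both are logged.
* Weight comparisons use a 1e-9 tolerance in both solvers (identical tie
  semantics); the BIC identity is exact.
* Degenerate inputs: zero-variance profiles raise a typed error and are
  skipped (with a warning) by matrix-level operations; profiles with fewer
  than 20 finite values are not fit; an instance with no responsive-side
  mass ($S = 0$) is rejected.
* All randomness flows through named sub-seeds derived from one master
  seed (kept below $2^{31}$), so identical configuration and seed give
  byte-identical outputs; the C++ kernels draw from R's RNG.

# Known limitations

* No covariate adjustment (mutation burden, growth rate) in the
  significance model; the fixed-margin null conditions on burdens instead.
* One feature set per profile; alternative or secondary sets are not
  searched.
* The branch-and-bound is exact but worst-case exponential; for very large
  feature panels at large $k$ the reference MILP formulation with a
  commercial solver would be the production route.
* p-values are floored at $1/(N+1)$; extremely small reference p-values
  are reproducible only with correspondingly large budgets.
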