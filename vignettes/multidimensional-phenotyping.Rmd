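---
title: "Multidimensional clinical phenotyping: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional clinical phenotyping: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the two-stage unsupervised phenotyping procedure, the
statistical machinery underneath it, the parameters that matter, and
the places where a design was genuinely open and a choice had to be
made.

## Why unsupervised Random Forests?

Clinical feature tables mix continuous measurements (age, FEV1% and
FVC% predicted, height, weight, BMI, Brasfield chest-radiograph
score), binary flags (pancreatic sufficiency, organism presence) and
categorical groupings (gender, CFTR mutation class). Distance-based
clustering on such data forces arbitrary scaling and coding decisions.
The Random Forest proximity sidesteps this: a classifier is trained to
tell real subjects from a *synthetic* contrast class, and the fraction
of trees in which two subjects co-occupy a terminal node is a
similarity that is invariant to monotone rescaling of any variable and
natively accommodates mixed types.

The synthetic class is built by sampling each variable independently,
with replacement, from its own empirical marginal (the
"independent-marginals" scheme, implemented in
`make_synthetic_contrast()`). It therefore has exactly the right
marginals but no joint dependence; a forest that separates real from
synthetic has learned the dependence structure, and its proximities
concentrate on subjects that sit in the same region of that joint
structure. The alternative contrast (uniform sampling over the
variable ranges) changes marginals as well as dependence; the
marginal-preserving scheme is the established default and the one
implemented. One consequence worth knowing: if the real data carry
little redundancy across variables, a marginal-product row is often
indistinguishable from a real one and the real-vs-synthetic OOB error
is legitimately high; it drops as cross-variable structure grows. The
OOB error of the unsupervised forest is therefore a diagnostic of how
much joint structure exists, not a quality score to optimise.

## The forest

Trees are unpruned CART classifiers grown on bootstrap samples of size
*n* drawn with replacement. At each node `mtry` candidate variables
are drawn without replacement and the split with the largest Gini
impurity decrease is taken. Defaults follow the standard practice for
classification forests: `n_trees = 1500` for a production phenotyping
run, `mtry = floor(sqrt(p))`, `min_node_size = 1` (grow to purity).
Deliberate numerical choices:

* **Zero-gain splits are admitted.** Any split with both children
  non-empty is a candidate even if its immediate Gini gain is zero.
  Pure interactions (XOR-like structure) have zero-gain first splits,
  and refusing them would blind the forest to them. Termination is
  still guaranteed because children are strictly smaller than their
  parent and pure nodes stop.
* **Deterministic tie-breaks.** Equal-gain candidates resolve to the
  lowest variable index, then the lowest threshold (continuous) or the
  lowest level-subset code (categorical). Categorical splits use
  exhaustive subset enumeration, feasible because clinical categorical
  variables here have at most a handful of levels.
* **Reproducible randomness.** The forest runs its own seeded
  xoroshiro128+ stream; the per-tree substream is a fixed hash of
  (seed, tree index), so growing a larger forest never reshuffles the
  earlier trees, and results are identical across platforms and across
  R sessions regardless of the session RNG state.
* **Proximity convention.** Every row is run down every tree
  (all-tree convention), `P[i,j]` = co-leaf count / `n_trees`; an
  OOB-pairs-only variant is available via
  `compute_proximity(oob_only = TRUE)`. The all-tree convention is the
  historical default of the software family this method comes from and
  is what the tests' brute-force pair-tracing oracle verifies.
* **OOB statistics.** A row is predicted by majority vote over trees
  where it is out of bag (ties to the lowest class index); rows never
  OOB — vanishingly rare at realistic `n_trees` — are excluded from
  the error denominator and counted.

Permutation importance is the mean over trees of the drop in that
tree's OOB accuracy after permuting one variable among the tree's OOB
rows, with its standard error across trees. A constant variable has
importance exactly zero (permutation is the identity). A caution
learned from the package's own null experiments: for a *single* fixed
dataset with permuted labels, importances are not centred at zero —
the fixed label vector has chance associations with the features, and
the trees genuinely learn them. Zero-centring holds across replicate
null datasets, and that is how the test suite checks calibration.

## PAM, and when it is optimal

`pam_cluster()` implements the classical two-phase algorithm on the
precomputed dissimilarity `D = 1 − P`: greedy BUILD seeding, then
steepest-descent SWAP (the single best medoid/non-medoid exchange per
iteration) until no exchange strictly reduces total cost. All ties
break to the lowest row index, so the clustering is reproducible
without any seed. Known behaviour, verified against exhaustive
enumeration on small instances: the result is never below the
exhaustive optimum (it is a feasible solution) and is swap-stable, but
like any local search it can terminate in a local optimum. On
unstructured random instances this happens for roughly one instance in
ten — for this package's steepest-descent implementation and for the
canonical reference implementation alike — while on dissimilarities
with genuine cluster structure (the regime this pipeline produces) the
exhaustive optimum is reached in ≥95% of small instances. `k` is a
user input throughout; the method offers no internal criterion for
choosing it, and runs at several `k` (3–6) are the intended usage.

## Classical MDS

`classical_mds()` double-centers `−D∘D/2` and eigendecomposes
(via the standard `cmdscale` machinery), keeping the leading
non-negative eigenvalues. Because `1 − proximity` is generally
non-Euclidean, negative eigenvalues occur; they are truncated and
their relative mass reported (`negative_eigenvalue_mass`) as a quality
diagnostic — small values mean the 2-D picture is a faithful summary.
Eigenvector signs are fixed (largest-magnitude coordinate positive) so
plots reproduce across runs; beyond that the embedding is defined only
up to rotation/reflection, which is how the tests compare embeddings
(Procrustes residual, not raw coordinates).

## The two-stage pipeline

`run_two_stage()` chains: unsupervised forest on all schema variables
→ PAM → supervised forest on the initial classes (OOB error +
importance) → unsupervised forest on the top `n_top_variables`
variables → PAM → supervised forest on the final classes + MDS. Two
design points were genuinely open:

* **The selected-variable set is always data-driven.** The historical
  analyses this procedure descends from report slightly different
  "top eight" lists in different places (one includes the radiographic
  score, another gender); the pipeline therefore never hardcodes a
  set — `select_top_variables()` takes whatever ranks highest at the
  user's `k`. With importance estimated from a finite forest the
  boundary ranks carry sampling noise: in the package's own
  noise-spiked simulations the eight planted variables are recovered
  exactly in most runs, with an occasional swap of the weakest planted
  variable (BMI, informative only through height and weight) for a
  noise column at 300 trees.
* **Class lettering.** Letters are cosmetic but must be deterministic
  to be comparable across runs and cohorts: A, B, C, … are assigned by
  ascending mean age×FEV1% product, so A is always the lowest accrued
  lung-health class.

Stage-specific forests use fixed derived seeds from the one
configuration seed, making the whole `PhenotypeResult` reproducible
byte for byte (the CLI determinism test asserts exactly this).

## Derived variables and severity bands

`derive_features()` computes BMI = weight/height² (kg/m²) and the
accrued lung-health score age×FEV1% (years·percent), validating any
stored values against recomputation (warning past 1% relative
discrepancy). `severity_band()` splits the product axis at 1000 and
1600 (severe < 1000 ≤ moderate ≤ 1600 < mild); the boundaries are
"approximately" known, so the exact closed/open convention here is a
determinism choice and both cutoffs are arguments. Organism presence
follows the two-positive-cultures rule: present iff ≥2 positive
cultures in the 365 days up to and including the subject's reference
date (`aggregate_microbiology()`); the window boundary is half-open on
the old side.

## Enrichment

`class_trait_enrichment()` tests every class against the rest of the
cohort for every trait (and requested trait pairs, as logical ANDs)
with the two-sided Fisher exact test; the odds ratio reported is the
conditional-MLE (0 and ∞ are meaningful and kept; the sample OR ad/bc
is also emitted). p-values are Benjamini–Hochberg adjusted; the
adjustment family defaults to *all* class×trait tests of the run — the
widest defensible family — with a per-trait alternative
(`family = "per_trait"`). Significance is called at adjusted p < 0.05.
A trait constant across the cohort yields p = 1 with OR reported as 1
and a note, rather than silently disappearing.

## Stability across cohorts

Two independent clusterings of overlapping cohorts carry arbitrary
labels. `match_classes()` aligns them by maximising total overlap on
the shared subjects over all k! label permutations (exact for the k ≤
6 used here; matching by profile similarity would depend on variable
scaling, whereas overlap matching is parameter-free and testable).
`transition_report()` then counts origin→destination moves,
per-origin-class leaving proportions (*p* Transitions),
per-destination arrival fractions (*f* Transitions), and death or
transplant tallies by origin class; subjects with events are excluded
from the transition denominator and reported only in the tallies.

## The synthetic cohort generator

`simulate_cohort()` draws each subject's latent class from mixing
weights; continuous variables from per-class normals truncated (by
inverse-CDF sampling) at physiologic adult bounds — age 18–80 y, FEV1%
15–140, FVC% 15–150, height 1.40–2.00 m, weight 35–120 kg, Brasfield
rounded to an integer in 3–25; FVC% is floored at 0.9×FEV1% to keep
spirometry plausible; BMI and the age×FEV1% product are computed, never
drawn; traits are per-class Bernoulli flags. `simulate_followup()`
ages survivors forward with mild spirometry/weight drift, moves each
subject out of class with probability 1 − persistence (redrawing all
class-conditional variables from the destination class), applies
per-class death/transplant hazards, and appends new patients.

The presets are documented synthetic designs, not measurements: their
class means were chosen to echo published adult-CF phenotype
*descriptions* qualitatively (a low-product low-BMI class, an older
male low-product class, female-dominated classes differing in lung
function, a well-nourished high-product class with frequent pancreatic
sufficiency and residual-function CFTR mutations) with means roughly
2–3 within-class SDs apart — deliberately well-separated, because the
presets' job is to provide recoverable ground truth for validating the
machinery. Problem sizes used by the tests and the acceptance script —
n = 211 at 300 trees for the five-class preset, n = 200 with ten noise
columns for selection recovery, 100–1000 replicates for
enrichment/stability calibration — are the package's validation
choices, sized so the whole suite runs in about a minute.

What the generator deliberately does **not** emulate: realistic
longitudinal FEV1 decline, correlated trait co-occurrence beyond class
membership, registry-calibrated covariance between anthropometry and
spirometry, missingness, or measurement error. Passing the recovery
tests therefore demonstrates that the machinery is correct and that
the procedure recovers latent structure *of the planted kind*; it does
not certify that any particular real cohort contains such structure,
nor that k classes is the right description of one.

## Known limitations

* Complete-case policy: rows with any missing schema variable are
  rejected at load (with a line-numbered report); there is no
  imputation and no surrogate splits.
* PAM is exact only in its swap neighbourhood; rare local optima are
  possible (see above). `k` must be supplied.
* The 1−proximity dissimilarity is non-Euclidean; MDS coordinates are
  a diagnostic picture, not a metric embedding (watch
  `negative_eigenvalue_mass`).
* Fisher/BH enrichment treats classes as fixed once clustered;
  p-values do not account for the classes having been estimated from
  the same data. Enrichment findings are descriptive associations, as
  in the clinical literature this follows.
* Odds-ratio confidence intervals and covariate-adjusted enrichment
  are out of scope.
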