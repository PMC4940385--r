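---
title: "Measuring economy and symmetry in segment inventories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring economy and symmetry in segment inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonogeom)
```

## The model

A segment inventory coded on K binary features is a set of s vertices
of the K-dimensional hypercube. Three descriptive statistics summarize
its geometry — its shape up to relabeling of dimensions and polarities:

* **Economy.** The contrasts of an inventory usually fit on far fewer
  than K dimensions. A feature subset is *sufficient* when projecting
  the segments onto it keeps them all distinct, and *irreducible* when
  no single feature can be dropped. These irreducible sufficient
  subsets are the inventory's *variant representations*; the median of
  their sizes is the contrastive dimension p. Economy is
  Econ = (s − (p + 1)) / (2^p − (p + 1)), which is 0 for the sparsest
  inventory attainable with p irreducible dimensions (s = p + 1,
  because with s segments any irreducible set has at most s − 1
  features) and 1 for a saturated hypercube (s = 2^p).
* **Local symmetry.** N_mp counts segment pairs at Hamming distance 1
  on a reduced representation — occupied hypercube edges, the minimal
  pairs or "oppositions" of classical phonology.
* **Global symmetry.** N_im sums, over the contrastive dimensions, the
  absolute difference between the number of + and − segments; 0 means
  every dimension splits the inventory in half.

Raw N_mp and N_im are strongly constrained by s and k (and N_im
additionally by N_mp): a saturated 3-cube *must* have N_mp = 12 and
N_im = 0. The statistics are therefore rank-normalized: Loc is the
normalized rank of N_mp among the values attainable at (s, k), and
Glob the normalized *descending* rank of N_im among the values
attainable at (s, k, N_mp), so that each statistic only carries the
information not already fixed by the quantities before it (size →
economy → local → global). When only one value is attainable the
statistic is omitted for that variant; an inventory's score is the
median over its variant representations, omitted entirely when every
variant is determined.

## Attainable-value tables

Which N_mp values are attainable at a given (s, k) is established
constructively. `enumerate_geometries()` enumerates all s-subsets of
the k-cube exhaustively when the raw count C(2^k, s) is at most
`budget` (default 200,000), keeping the irreducible ones — every
dimension must carry at least one minimal pair — and deduplicating by
geometry. Larger spaces are sampled under a fixed seed: uniform draws
of s distinct vertices, mixed (30%) with a constructive draw that
first lays down a random dimension-spanning chain of k + 1 vertices
(irreducible by construction) and fills up with random vertices. The
mixture matters because in sparse regimes a uniform draw is almost
never irreducible, while the chain-seeded draw always is; sampling is
not uniform over geometries, but the tables only need the *set* of
attained values, and every attested variant representation is unioned
into the lists regardless, so observed data are always rankable.

Geometric distinctness is decided by a canonical key invariant under
column permutation, per-column polarity flip and row order — exactly
the operations that leave N_mp and N_im unchanged. The key is the
BLISS canonical form (via igraph) of a vertex-colored graph encoding
the matrix: one node per segment, two polarity nodes per column, one
pairing node per column; its color-preserving automorphisms are
exactly the hypercube symmetries. For k ≤ 5 the exhaustive path
instead computes orbits directly under the explicit signed-permutation
group, which is faster and was cross-checked against both the graph
canonicalization and brute-force orbit enumeration.

## The contrastive search

`find_specs_exact()` walks the power set bottom-up: level m candidates
are formed by adding one feature to each insufficient level-(m − 1)
subset, and a sufficient candidate is admitted as a variant
representation when removing any single feature breaks sufficiency
(this single-removal test is complete: a sufficient proper subset of
smaller size would make some single-feature removal sufficient too).
Constant features are pruned first — they can never distinguish
anything — and sufficiency is tested with pair-coverage bitsets, so
each test is a few word operations.

The exhaustive frontier can explode on large inventories, so
`find_specs_capped()` expands at most `cap` frontier subsets per level
(default 1000, configurable and recorded with every spec set),
uniformly subsampled under a seed; the rest are recorded as skipped. A
sufficient set that properly contains a skipped subset is discarded
even though the direct removal test would settle its status — a
deliberately conservative guard, kept because it is the documented
behavior of the search this implements; `strict = TRUE` drops the
guard and relies on the removal test alone. When no frontier was ever
truncated the capped search provably equals the exhaustive one and is
flagged exact. The level-wise search starts at subsets of size 1. In
the rare event that heavy truncation discards every candidate, one
greedily reduced irreducible set is returned (flagged non-exact) so
the inventory still gets scored.

Even-count medians make p fractional (e.g. variant sizes {2, 3} give
p = 2.5); Econ is then computed with real exponentiation 2^p. For
p = 1 the denominator vanishes and Econ is undefined; such inventories
(two segments) are dropped from economy analyses with their omission
reason recorded.

## Null models

Four control families, all size-matched one-to-one to the natural
inventories and drawn from the pool of the matched subsystem:

* `segment_freq` — attested feature combinations, probability
  proportional to the number of languages containing each combination;
* `segment_uniform` — attested combinations, uniform;
* `feature_freq` — each feature value of each segment an independent
  coin with the pooled empirical +1 probability (computed from raw
  encodings over segment tokens, per subsystem);
* `feature_uniform` — independent fair coins.

Inventories are sets, so duplicate draws are rejected and redrawn in
every family; for segment controls this is equivalent to successive
weighted sampling without replacement. Feature-control probabilities
are clipped away from 0 and 1 so a feature constant in the pool cannot
make the sampler degenerate. Controls flow through the identical
search → enumeration → scoring path as the naturals, including the
omission bookkeeping.

Separation between score distributions is quantified by the
Mann-Whitney AUC (ties one half), with percentile bootstrap intervals
(defaults: 1000 resamples, 95%, resampling each group independently).
`compare_external_set()` scores an external inventory set against
repeated size-matched subsamples of the naturals.

## The synthetic generator

`gen_database()` emulates the statistical shape of a typological
database: a pool of `pool_size` distinct combinations on K features
with Zipf-decaying cross-linguistic weights (exponent 1 by default),
and languages built by sequential weighted sampling without
replacement, sizes following a shifted negative binomial clipped to
[3, min(40, pool_size)]. The default scale (K = 23, 688 combinations,
536 languages) mirrors a large typological database. A `duplicate_rate`
fraction of languages receives an alias label sharing another
segment's encoding, exercising the encodability filter — languages in
which two segments share a feature vector are removed, independently
per subsystem, since their geometry would depend on sounds the
encoding cannot distinguish.

The geometry bias enters *generation*, not post-hoc filtering: a
candidate segment's log-weight is log(Zipf) + beta_loc · (new minimal
pairs created) − beta_glob · (imbalance increase). With both betas
zero this reduces *exactly* to the frequency-proportional law of the
segment controls, so the pipeline can be held to a true null: any
natural-vs-control AUC away from 0.5 would be a false positive of the
machinery itself. What the generator does not emulate: phonetic
substance (no articulatory or perceptual space), transcription noise,
areal or genealogical dependence between languages. Passing the
recovery experiment therefore shows the *statistical machinery* is
calibrated and sensitive, not that real inventories behave like the
generator.

## Problem sizes and numerical choices

The calibration experiment (`run_recovery_experiment()`) uses K = 9,
a pool of 150 combinations, 300 languages with sizes 3–25, search cap
200 and 800 sampled configurations per (s, k) key. These sizes were
chosen so that the attainable-value tables stay dense relative to the
spaces involved while a full two-arm experiment (null and biased) runs
in minutes on a single core; the analysis drivers use the same scale.
With them, the null AUCs land within a few points of 0.5 and a
beta_loc = 2 bias lifts the Loc AUC to about 0.6 — a deliberately
weak detection threshold; at 300 languages the AUC's sampling noise
is a couple of points, so individual runs land on either side of it
and the calibration suite pins the check to a fixed seed.

Other conventions worth stating explicitly:

* Ties in rank lists cannot occur (lists hold distinct values);
  `loc_score`/`glob_score` error on values absent from the lists
  rather than interpolating, since absence means the tables were not
  built over the data being scored.
* Scoring an inventory whose statistic is omitted in every variant
  yields `NA` with a reason column, and groups with no defined scores
  produce `NA` comparison rows flagged `"undefined"` rather than
  errors.
* Subsystem predicates are configuration, not inference: vowels are
  [+syllabic], consonants [−syllabic], stops/affricates [−syllabic,
  −sonorant, −continuant] by default, and any database using different
  class definitions can supply its own rules.
* Every stochastic stage (frontier subsampling, enumeration sampling,
  control generation, bootstrap) takes a seed derived from one base
  seed, making whole runs bit-reproducible.

## Decorrelation

After rank normalization the three statistics are mutually
uncorrelated *by construction* when pooled at the granularity of the
rank tables themselves: one entry per attainable (s, k, N_mp) value
for the Econ–Loc pair, one per (s, k, N_mp, N_im) value for the pairs
involving Glob. Within any stratum the normalized ranks are equally
spaced over [0, 1], so their mean is 1/2 regardless of the stratum,
and the covariance with any stratum-level quantity vanishes;
`decorrelation_check()` verifies this to floating-point precision.
Pooling over *geometries* instead (every distinct configuration once,
`pooled_geometry_scores()`) does not share this property: strata
differ in how geometries distribute over their attainable values, and
measurable correlations (of order 0.1–0.3 between Econ and Loc on
small pools) appear. The package treats the value-level construction
as the designed meaning of "decorrelated" and keeps the geometry-level
view as a diagnostic of how unevenly geometries populate the value
lists.

## Interfaces

The package's interface is its functions plus the numbered drivers
under `analysis/` (simulate → encode → score → calibrate); there is no
shell wrapper. On-disk formats are plain text: a TSV/CSV feature table
(rows = segments, "+"/"−" cells), a long CSV inventory table
(language_id, segment_label), JSON for rank-table caches, ground
truth and run logs, CSV for all score and summary tables.

## Known limitations

* The capped search's conservative guard can discard genuinely
  irreducible representations under heavy truncation, slightly biasing
  p upward for very large inventories; `strict = TRUE` trades fidelity
  to that rule for completeness.
* Sampled attainable-value lists can miss extreme values in very large
  (s, k) strata, compressing Loc/Glob ranks there; attested
  augmentation guarantees rankability but not completeness.
* A dispersion statistic (summed pairwise distances) is deliberately
  out of scope, as are contrastive-hierarchy (ordered-feature)
  analyses, IPA parsing and any phonetic interpretation of the
  features; segments are opaque labels with ±1 vectors.
* More than 30 non-constant features per inventory are unsupported
  (subset bitmasks); typological feature systems sit well below this.
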