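# phonogeom

Tools for studying the *geometry* of phonological segment inventories.
Languages do not assemble their sound systems by drawing segments at
random: inventories tend to be **economical** (the contrasts between
their sounds fit on few independent feature dimensions), **locally
symmetric** (rich in minimal pairs such as /p/–/b/, /t/–/d/ — pairs of
segments differing on exactly one feature) and **globally symmetric**
(balanced between the + and − values of each feature). `phonogeom`
implements the statistics that measure these three tendencies, the null
models they are compared against, and a synthetic database generator
with known ground truth so the whole analysis can be validated end to
end. It is aimed at phonological typologists and cognitive scientists
working with segment databases coded in binary distinctive features.

## The statistics

An inventory of *s* segments, encoded on binary features (±1), occupies
*s* vertices of a feature hypercube. Its *variant representations* are
the irreducible feature subsets sufficient to keep all segments
distinct; *p* is the median size of these subsets.

- **Econ** = (s − (p + 1)) / (2^p − (p + 1)): how fully the inventory
  occupies the 2^p cells its contrastive dimensions define (0 =
  sparsest possible, 1 = saturated hypercube).
- **N_mp** = #{(i, j) : d(p_i, p_j) = 1}, the number of minimal pairs,
  with d the Hamming distance on the reduced representation. **Loc** is
  N_mp rank-normalized to [0, 1] among the values attainable at the
  inventory's size and dimension.
- **N_im** = Σ_k |Σ_i p_{i,k}|, the summed feature imbalance. **Glob**
  is N_im rank-normalized (descending, so balanced = 1) among the
  values attainable given size, dimension *and* N_mp.

The attainable-value lists are built by exhaustively enumerating — or,
where the space is too large, seeded sampling of — *geometrically
distinct* irreducible configurations (distinct up to feature
reordering, polarity flips and segment reordering), pooled with every
variant representation observed in the data. Natural inventories are
compared against four families of size-matched random controls
(frequency-matched / uniform segment draws, frequency-matched / uniform
independent feature draws) via ROC/AUC with bootstrap intervals.

## Worked example

```r
library(phonogeom)

# three vowels /i u ɑ/ on (back, round, low)
m <- rbind(i = c(-1, -1, -1), u = c(1, 1, -1), a = c(1, -1, 1))
sp <- find_specs_exact(m)
sp
#> Variant representations of <matrix>: 3 spec(s), sizes 2, p = 2 (exact)
```

Any two of the three features distinguish the three vowels, so there
are three variant representations and p = 2. Scoring a saturated cube:

```r
economy_score(8, 3)            # [1] 1      -- 8 segments fill 2^3 cells
e <- enumerate_geometries(8, 4)
range(e$stats$n_mp)            # [1]  4 10  -- attainable minimal-pair counts
sort(unique(e$stats$n_im[e$stats$n_mp == 10]))
#> [1]  8 10 12                -- attainable imbalances given N_mp = 10
```

A full synthetic analysis, from simulation to AUC tables, is in the
numbered drivers under `analysis/` (run them in order from the
repository root); `vignettes/inventory-geometry.Rmd` explains the
method and every default.

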