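# iondist

Spatial statistics of monoatomic ions around amino acids in protein
structures.

A large fraction of deposited protein structures contain resolved ions —
Zn²⁺, Ca²⁺, Mg²⁺, Cl⁻ and friends. `iondist` is for structural
bioinformaticians who want to treat those ions statistically rather than
site-by-site: it anchors a canonical local coordinate frame on every
amino-acid residue, maps nearby ions into that frame, and aggregates the
resulting spatial distributions into count/probability tables that drive
three analyses:

1. **Pair statistics** — counts of 'ion–amino acid' pairs (an ion within
   6 Å of a residue's geometry center), radial/angular/octant histograms,
   and the side-chain preference ratio
   *R* = *N*<sub>s</sub>/(*N*<sub>s</sub> + *N*<sub>c</sub>) with the
   shrunken radius *r*<sub>a</sub> = 6 − max(*r*<sub>c</sub>, *r*<sub>s</sub>).
2. **Clustering** — amino acids clustered (complete linkage) by the
   rotation-maximized correlation between their 3-D ion density maps.
3. **Ion-type prediction** — naive-Bayes ranking of candidate ion types at
   a query position,
   *p*(**r**, ion) = ∏<sub>{aa}</sub> *p*(aa, ion) / (*p*(aa) *p*(ion)),
   with an octant-resolved refinement that replaces the pair term by
   *p*(aa, ion, octant) in each neighbor's frame.

The residue frame has its origin at the geometry center (unweighted mean
of the heavy atoms), x̂ toward the backbone N, ŷ the orthogonalized
direction toward the carboxyl C, ẑ = x̂ × ŷ; local coordinates are
invariant under rigid motion of the structure. A synthetic-fixture
generator plants residues under arbitrary rigid transforms and ions at
chosen (r, θ, φ), so the full pipeline is testable against known ground
truth without downloading a single structure.

## Worked example

Plant a Zn²⁺ ion 2.5 Å from a cysteine's geometry center, write it
through standard PDB, and ask the pipeline what it sees:

```r
library(iondist)
library(dplyr)
set.seed(1)

spec <- list(
  residues = tibble(aa = c("CYS", "HIS"), rotation = random_rotation(2),
                    tx = c(0, 4), ty = 0, tz = 0, resno = 1:2),
  ions = tibble(ion = "Zn2+", anchor = 1L, r = 2.5, theta = 2.2, phi = -1.9))
fx <- make_pdb_fixture(spec)
st <- read_structure(fx$text, "DEMO")
find_pairs(st)[, c("aa", "ion", "r", "octant")]
#> # A tibble: 1 × 4
#>   aa    ion       r octant
#>   <chr> <chr> <dbl>  <int>
#> 1 CYS   Zn2+   2.50      7
```

The ion is recovered at exactly its planted radius, in octant 7 (the
−x/−y/−z sector of the cysteine frame implied by θ = 2.2, φ = −1.9).
Training a statistics database on this toy structure and scoring the
ion's own position ranks the right type first:

```r
stats <- ion_stats(st)
pos <- c(st$ions$x, st$ions$y, st$ions$z)
predict_ion_type(stats, st, pos, mode = "octant", true_ion = "Zn2+",
                 ions = default_ion_candidates())
#> <ion_prediction>
#> # A tibble: 11 × 3
#>   ion   log_score  rank
#>   <chr>     <dbl> <dbl>
#> 1 Zn2+      -1.51   1
#> 2 Br-       -2.16   6.5
#> 3 Ca2+      -2.16   6.5
#> 4 Cl-       -2.16   6.5
#> 5 Cu2+      -2.16   6.5
#> # ℹ 6 more rows
#>   true ion Zn2+ at rank 1.0
```

Zn²⁺ gets the highest log-score (the observed pair beats the smoothed
background), and the ten never-observed candidates tie at the average of
ranks 2–11. On real data you would point `ion_run("build-stats", ...)` at
a directory of PDB files (optionally restricted by a non-redundant ID
list), then `summarize`, `cluster`, `predict`, or `evaluate`; a thin
command-line wrapper lives in `inst/cli/iondist.R`.

See the vignette (`vignettes/ion-distributions.Rmd`) for the model, the
estimation choices, and the planted-recovery study design.

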