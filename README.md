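# plumeRecruit

Estimating relative survival (recruitment) of larval fish from two
river-plume nursery habitats to the age-0 juvenile stage, from multilocus
codominant (microsatellite) genotypes.

Turbid river plumes are hypothesized to shelter fish larvae from visual
predators and boost their food supply. Testing whether that advantage
carries through to *recruitment* requires tracking which nursery each
surviving juvenile came from. When the larval pools of two plumes are weakly
genetically differentiated, genotype assignment provides that natural tag:
every juvenile in the mixed late-summer pool is assigned to its most likely
larval source population, and the assigned source proportions are compared
with the proportions expected from larval production alone.

`plumeRecruit` is a complete, tested implementation of this analysis for R,
aimed at fisheries ecologists and population geneticists working with
microsatellite panels (the canonical setting is 12 loci, 5–25 alleles per
locus, between-plume F<sub>ST</sub> of roughly 0.005–0.01).

## What is inside

* **Data model and I/O** — `genotype_dataset` (unordered allele pairs,
  explicit missing data, group labels, coordinates, life stage); GenePop
  reader/writer; delimited readers for site and weekly larval abundance
  tables.
* **Population-genetic statistics** — exact-style Monte Carlo
  Hardy–Weinberg tests, permutation linkage-disequilibrium tests,
  Weir–Cockerham F<sub>ST</sub> (θ) with permutation significance, Monte
  Carlo exact tests of allele-frequency differentiation with Fisher
  combination, and three-level hierarchical AMOVA (years / plumes within
  years / within plumes), all authored in the package.
* **Genotype assignment** — Rannala–Mountain Bayesian and classical
  frequency-method likelihoods; leave-one-out self-assignment for
  first-generation migrant screening (default flag below 60%); Monte Carlo
  exclusion tests (Paetkau-style simulated genotypes); the two-step
  juvenile assignment (exclusion below 10% to both sources, then rank-based
  assignment at ≥ 70%), with threshold sensitivity sweeps.
* **Recruitment comparison** — transmissometry habitat classification
  (turbid above 6.0 m⁻¹, contradictory sites flagged), peak weekly larval
  abundance ratios, observed-versus-expected recruitment χ² (1 df,
  uncorrected), weekly ANOVA, and spatial-mixing t-tests.
* **Synthetic studies** — a Balding–Nichols generator producing complete
  studies (structured genotypes, migrants, juvenile mixtures under
  differential survival, overdispersed abundance surveys with
  transmissometry and coordinates) with full truth tables, so every stage
  is verifiable without downloads.

The core statistic of the recruitment comparison: with observed assigned
counts *O* and larval production ratio *r*, expected counts are
*E = r · N* over the *N* successfully assigned juveniles, and

χ² = Σ (O − E)² / E,  df = 1.

A positive residual *O − E* for a plume means survival through the first
summer was disproportionately high for larvae from that plume.

## A worked example

```r
library(plumeRecruit)

# a one-year synthetic study: F_ST 0.05, 2:1 survival advantage to the
# turbid (Maumee) plume
st  <- simulate_study(sim_config(fst = 0.05, seed = 42,
                                 survival = c(Detroit = 1, Maumee = 2)))
rep <- run_study(st, assignment_config(n_simulated = 2000), seed = 43)
rep
#> == year 06 ==
#>   larval theta = 0.0280
#>   assignment counts:  D06 M06 failed excluded unusable total
#>   61  49      4       16        0   130
#>   recruitment X2 = 18.102, p = 2.094e-05
```

Of 130 juveniles, 61 assign to the Detroit larval group and 49 to the
Maumee group; 4 are ambiguous and 16 are excluded from both sources. The
larval production ratio in this simulation is 73:27 Detroit:Maumee, so 49
Maumee juveniles out of 110 assigned far exceeds the ~30 expected under
equal survival — the χ² of 18.1 (p ≈ 2 × 10⁻⁵) correctly detects the
simulated survival advantage.

The same test on printed yearly counts runs directly:

```r
recruitment_chi_square(c(55, 32), c(0.73, 0.27))
#> recruitment chi-square: X2 = 4.223, df = 1, p = 0.03987
#>           [,1]  [,2]
#> observed 55.00 32.00
#> expected 63.51 23.49
#> residual -8.51  8.51
```

## Documentation

The methods vignette (`vignettes/plume-recruitment-methods.Rmd`) documents
the model and its assumptions, every tunable parameter with its default and
rationale, the numerical conventions (add-one Monte Carlo p-values,
log-sum-exp normalization, tie handling at thresholds), what the synthetic
generator does and does not emulate, and known limitations.
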