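# pbapportion

Mass-balance source apportionment of lead pollution from stable lead
isotope fingerprints.

## The problem

Soil and sediment lead near industrial sites is typically a mixture from
several emitters (smelter ore, coal combustion, regional background, ...).
Because the four stable lead isotopes — 204Pb, 206Pb, 207Pb, 208Pb — do not
measurably fractionate in environmental processing, each source carries a
fixed isotopic *fingerprint*: its abundance vector
x = (x204, x206, x207, x208), Σx = 1, or equivalently three independent
ratios such as (²⁰⁸Pb/²⁰⁴Pb, ²⁰⁷Pb/²⁰⁴Pb, ²⁰⁶Pb/²⁰⁴Pb). `pbapportion`
estimates how much of a sample's total lead mass each candidate source
contributed.

## The model

Conservation of each isotope's mass gives, for n sources with abundance
vectors x⁽ⁱ⁾ and contribution fractions fᵢ,

    Σᵢ fᵢ x⁽ⁱ⁾ = x⁽ˢᵃᵐᵖˡᵉ⁾,   Σᵢ fᵢ = 1.

Counting the underlying unknowns (four isotope masses plus one fraction per
source: 5n) against the available equations (4n + 4) shows the system is
solvable up to **four** sources — exactly determined at n = 4 — and
unidentifiable beyond; the package enforces this. Fractions are
sign-unrestricted: a negative fraction flags lead from a source outside the
candidate set. For two sources a closed-form solution in the chained ratios
k₁..k₉ is provided, and the full 4n+4-equation solver with per-source
isotope masses serves as an independently coded cross-check. The classical
three-source Gobeil model, which balances the ratios ²⁰⁶Pb/²⁰⁷Pb and
²⁰⁸Pb/²⁰⁶Pb directly instead of the isotope masses, is included for
comparison (`solve_gobeil()`, `compare_models()`) together with synthetic
end-member generation, parameter-recovery experiments and Monte-Carlo error
propagation at MC-ICP-MS noise levels (relative s.d. 0.02%–0.09%).

## Worked example

The package bundles an industrial-park survey: 32 soil samples around a
lead–zinc smelter plus four end-member sources (coking-plant coal, smelter
ore, power-plant coal, regional background).

```r
library(pbapportion)

tbl     <- guanzhong_survey()
sources <- table_sources(tbl)
sample  <- table_samples(tbl)[[14]]   # sample N-1000, 1000 m north

solve_mass_balance(sources, sample)
#> <pb_apportion> sample 'N-1000' (mass_balance_reduced)
#>   coking_coal  -13.86% [negative]
#>   smelter_ore  +57.25%
#>   power_coal   +41.24%
#>   background   +15.37%
#>   residual norm 8.67e-18, condition number 62.4
```

The smelter ore dominates this sample (57.25% of its lead mass), the
power-plant coal contributes 41.24% and the regional background 15.37%. The
*negative* coking-coal fraction (−13.86%) means the sample's fingerprint
lies outside the simplex spanned by the four candidates — diagnostic of an
unmodeled source (the sampling point is near a road and village, i.e.
vehicle exhaust and household coal). Propagating instrument noise through
the solver:

```r
monte_carlo_uncertainty(sources, sample, noise_model(5e-4, seed = 1),
                        replicates = 1000)
#>        source estimate   lower   upper  width
#> 1 coking_coal  -0.1386 -0.1510 -0.1264 0.0246
#> 2 smelter_ore   0.5725  0.5447  0.5994 0.0547
#> 3  power_coal   0.4124  0.3735  0.4492 0.0758
#> 4  background   0.1537  0.1285  0.1801 0.0517
```

The negative fraction is robust to measurement error, not a noise artifact.
`case_study()` runs all 32 samples, flags every sample with a negative
fitted fraction, averages the valid ones, and diffs the computed table
against the bundled published values cell by cell. `system_dimensions(n)`
reports the equation/unknown counts, e.g.:

```r
system_dimensions(4)
#> <pb_sysdim> 4 sources: 20 unknowns, 20 equations -> solvable (identifiable)
```

A thin command-line wrapper lives at `inst/cli/pbapportion.R`
(`apportion`, `dims`, `closed-form`, `gobeil`, `simulate`, `case-study`).

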