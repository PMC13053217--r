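# deboreal

Tools for quantifying climate-driven **thermal restructuring of benthic
macroalgal communities** from paired historical/modern quadrat resurveys,
together with the sea-surface-temperature (SST) extreme-event and trend
statistics needed to interpret those shifts.

The package is written for benthic ecologists comparing a historical
quadrat survey (e.g. 1970s SCUBA transects scored on a Braun-Blanquet
scale) against a modern resurvey of the same quadrats, and asking not just
*whether* the community changed, but *which thermal process* drove the
change.

## The statistics at its core

**Species temperature index (STI).** For species *s* with latitudinal range
[lat_min, lat_max], the STI is the unweighted mean of a latitude-binned
(0.1°) coastal SST climatology over the bins inside the range:

    STI_s = mean{ SST(b) : lat_min <= b <= lat_max }

**Community temperature index (CTI).** For a quadrat with cover fractions
c_s, the CTI is the abundance-weighted mean STI:

    CTI = sum_s c_s * STI_s / sum_s c_s

**Affinity and the four processes.** Species with STI above the mean STI of
the historically documented community are *warm-affinity*; the rest are
*cold-affinity*. A cover change Δc_s then contributes to one of four
processes:

| affinity | Δcover > 0     | Δcover < 0        |
|----------|----------------|-------------------|
| warm     | tropicalization | detropicalization |
| cold     | borealization   | deborealization   |

`decompose_cti_change()` averages cover within 1-m depth bins (correcting
the shallow bias typical of historical sampling), L1-normalizes |Δcover|
within each bin, accrues the weights to their processes, and averages bins
equally. `estimate_cti_shift()` gives the CTI change with a paired
percentile-bootstrap CI (or a year-stratified depth-spline model).

Community restructuring is tested from first principles: Bray-Curtis
dissimilarity `sum|x-y| / sum(x+y)`, one-way PERMANOVA by label
permutation (exhaustive when feasible), PCoA-based dispersion homogeneity,
and SIMPER per-species contributions. Daily SST series get maximal-run
heat-event detection (stress: >= 18 °C for >= 14 days; mortality /
reproductive failure: >= 20 °C for >= 7 days), Mann-Kendall + Sen's slope
trend tests, logistic event-frequency odds, and a GCV-smoothed decadal
warming rate with residual-bootstrap CI.

Synthetic-data generators (`gen_climatology()`, `gen_paired_surveys()`,
`gen_sst_series()`) produce every input with a ground-truth ledger, so the
whole pipeline is validated by parameter recovery.

## Worked example

```r
library(deboreal)

# a synthetic world: 48 paired quadrats (1972 vs 2023), 12 species,
# per-quadrat CTI shift drawn around +1.4 degC
world <- gen_paired_surveys(community_scenario(seed = 42))
ct    <- cti_table(world$pairs, world$sti_table)
estimate_cti_shift(ct, n_boot = 2000, seed = 42)
#> CTI shift: +1.339 degC (95% CI: 1.128 to 1.545; paired_bootstrap, n = 48 pairs)

decompose_cti_change(world$pairs, world$sti_table)
#> process decomposition (equal-weighted 1-m depth bins):
#>   tropicalization       0.0%
#>   deborealization     100.0%
#>   borealization         0.0%
#>   detropicalization     0.0%

cm <- community_matrix(world$pairs, species = world$sti_table$species)
permanova(bray_curtis_matrix(cm$x), cm$groups, n_perm = 999, seed = 42)
#> permutation test: statistic = 10.6368, p = 0.001 (999 permutations)
```

The estimated shift (+1.34 °C) is the bootstrap mean of the per-quadrat
CTI differences and matches the generator's ledger for this seed
(`world$ledger$realized_delta_cti`, 1.339); the CI covers the configured
+1.4 °C truth. The decomposition attributes the whole CTI rise to
deborealization — loss of cold-affinity cover — because this scenario
realizes the shift by thinning cold species, and the PERMANOVA confirms
the 1972-vs-2023 compositional difference at the smallest attainable
p-value for 999 permutations.

SST side:

```r
sw <- gen_sst_series(sst_scenario(trend_per_decade = 0.33,
        events = data.frame(year = 1994, start_doy = 195,
                            length = 16, level = 18.6), seed = 42))
head(detect_stress_events(sw$series), 2)
#>   start_date   end_date length threshold   kind
#> 1 1989-08-01 1989-08-14     14        18 stress
#> 2 1994-07-13 1994-07-31     19        18 stress
trend_rate(annual_means(sw$series, "summer"), n_boot = 500, seed = 42)
#> rate 0.322 degC/decade (95% CI 0.301-0.340)
```

The injected 1994 block is recovered (widened by warm noise around it);
late-series events appear spontaneously as the warming trend pushes summer
peaks over 18 °C; and the configured 0.33 °C/decade rate is inside the
bootstrap CI.

## Command line

```sh
Rscript inst/cli/deboreal.R simulate --seed 1 --out-dir runs/demo
Rscript inst/cli/deboreal.R sti --climatology runs/demo/climatology.csv \
    --species runs/demo/species.csv --out runs/demo/sti.csv
Rscript inst/cli/deboreal.R report --config config.json --out report.json
```

Run `Rscript inst/cli/deboreal.R --help` for all subcommands
(simulate, sti, cti, shift, decompose, community, events, trends, report).

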