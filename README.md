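# forcarb

Forest carbon stock estimation and economic valuation from sub-compartment
stand inventories.

Forest-resource monitoring in China records, for every sub-compartment,
the area, vegetation type, dominant species group, age group, functional
zone and standing timber volume. `forcarb` turns such a table into a
vegetation carbon account for a reserve-scale study system (seven arbor
species dominated by *Pinus yunnanensis*, plus economic forests and
shrubland), quantifies how much the choice of volume-to-carbon conversion
matters, and monetizes the resulting stocks. It is aimed at ecologists and
forest managers producing regional carbon accounts from inventory data.

## Methods at the core

Four conversions for the arbor layer, all computed from the same records:

| method | formula |
|---|---|
| age-stratified BEF | C = Σᵢⱼ Vᵢⱼ · Dᵢ · BEFᵢⱼ · (1+Rᵢⱼ) · CFᵢ |
| pooled BEF | C = Σᵢ Vᵢ · Dᵢ · BEFᵢ · (1+Rᵢ) · CFᵢ |
| volume conversion | C = V · δ · ρ · γ  (δ=1.90, ρ=0.5, γ=0.5) |
| linear biomass–volume | B = aV + b per species, C = B · CFᵢ |

with V standing volume (m³), D basic wood density (t/m³), BEF the
aboveground/stem biomass expansion factor, R the root-to-shoot ratio and
CF the carbon fraction; all parameters ship as auditable CSVs. Economic
forests and shrubland (area only, no volume) use mean per-hectare biomass
(23.7 and 19.76 t/hm², CF 0.47). Methods are compared by relative error
against their mean, exact Wilcoxon signed-rank tests and Spearman rank
correlations over per-species stocks. Carbon monetizes as
V = 44/12 · C · P under a market-mean price (27.76 CNY/tCO₂e, eight 2019
pilot markets) and an optimal carbon-sink price (10.11 USD/tC → 19.02
CNY/tCO₂e), averaged.

Because the original record-level survey is not public, the package
includes a seeded synthetic inventory generator plus marginal-total
calibration (`zixi_fixture()`) that reproduces every published marginal of
the study system, so the whole pipeline is runnable and testable
end-to-end. See the vignette (`vignettes/forest-carbon-accounting.Rmd`)
for the model details and the calibration assumptions.

## Worked example

```r
library(forcarb)

inv <- zixi_fixture()           # 2,483-record calibrated inventory
summarize_inventory(inv, "vegetation_type")
#>   vegetation_type n_records area_hm2 volume_m3
#> 1 arbor                2418  14448.   1417181.
#> 2 economic               40    376.         0
#> 3 non_stocked            15     59.3        0
#> 4 shrub                  10     56.4        0

compare_methods(inv)
#> Mean total: 609240.03 tC
#>   variable_bef            690891.45 tC  RE  +13.40%
#>   bef                     672600.04 tC  RE  +10.40%
#>   volume_conversion       673161.37 tC  RE  +10.49%
#>   continuous_bcf          400307.25 tC  RE  -34.29%
#> ...all pairwise Wilcoxon p > 0.05, all Spearman rho = 1.000

veg <- vegetation_stocks(inv, arbor_method = "bef")
report <- build_report(veg, group_dimension = "vegetation_type")
report
#>   vegetation_type area_hm2 carbon_tC proportion_pct density_tC_per_hm2
#> 1 arbor            14448.    672600.        99.3                 46.6
#> 2 economic           376.      4192.         0.619               11.1
#> 3 shrub               56.4      524.         0.0773               9.29
#> total: 14880.28 hm2, 677315.24 tC, density 45.52 tC/hm2, mean value 5808.88 wan CNY
```

Reading the output: the arbor layer holds 99.30% of the reserve's carbon;
the four conversion methods agree in rank (rho = 1) and show no
significant pairwise differences, with the pooled-BEF and
volume-conversion totals closest to the four-method mean; the whole
vegetation stock of ≈677,315 tC (45.52 tC/hm²) is worth ≈58.09 million
CNY as the mean of the two price schemes.

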