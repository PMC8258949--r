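# recessiveBurden

Estimating birth incidence, carrier counts and current patient numbers for
autosomal-recessive ultra-rare disease from population allele frequencies,
with rhizomelic chondrodysplasia punctata (RCDP) — a peroxisomal disorder of
plasmalogen biosynthesis caused by biallelic variants in *PEX7*, *GNPAT*,
*AGPS*, *FAR1* or *PEX5* (PTS2-domain-encoding region only) — as the
motivating application.

For ultra-rare recessive disorders, classical registry epidemiology
undercounts: patients are scattered, underdiagnosed, and cohorts are tiny.
Large population sequencing datasets (gnomAD, TopMed) see the *carriers*
instead, in the thousands. This package implements the genetic-epidemiology
chain that turns per-variant carrier counts into a disease-burden estimate:

1. **Variant filtering.** A variant contributes if it is clinically reported
   pathogenic, predicted loss of function (stop gained, frameshift, canonical
   splice donor/acceptor, start lost), or a missense called damaging by
   *both* SIFT and PolyPhen-2. Clinically benign reports exclude a variant
   outright; genes can be restricted to a genomic interval (e.g. *PEX5* to
   the PTS2 domain).
2. **Aggregate allele frequency.** Per gene and dataset,
   `q = Σᵢ ACᵢ/ANᵢ` over included variants, with a modified-Wald
   (Agresti–Coull) 95% confidence interval; the CI bounds propagate
   componentwise through every later stage.
3. **Hardy–Weinberg conversion.** Genotype (affected) prevalence `q²` —
   which counts homozygotes and compound heterozygotes alike, since
   `(Σqᵢ)² = Σqᵢ² + Σᵢ≠ⱼ qᵢqⱼ` — and carrier frequency `2pq`.
4. **Birth incidence.** `Iᵧ = q² · Bᵧ` against a historic live-birth series
   (anchored to 2018 births for the headline rate).
5. **Life-table aging.** A discrete mortality model (default: 75% survival
   to age 5, 2%/yr to 14, 8%/yr from 15, no survival past 34) converts the
   incidence history into the expected number of patients alive today:
   `P = Σₐ I₍ᵧ₋ₐ₎ · S(a)`, plus the age distribution in 5-year bins.

A seeded synthetic-data generator emulates the inputs (binomial AC draws at
sequencing-cohort scale, decoy variants for every exclusion rule, birth
series, a 66-patient survival cohort), so the whole pipeline is testable
offline.

## Worked example

```r
library(recessiveBurden)

spec   <- presetSimulationSpec(seed = 42)   # five RCDP-scale genes, two regions
sim    <- simulateVariantTable(spec)
births <- simulateBirthSeries(spec, 1970:2020)
cfg    <- burdenConfig(genes = spec$genes$gene,
                       dataset_regions = c("US-TopMed" = "US",
                                           "EU5-gnomAD-NFE" = "EU5"),
                       population_sizes = c(US = 328e6, EU5 = 324e6))
report <- runFullModel(sim$variants, births, NULL, cfg)
report
#> BurdenReport: 5 gene(s) x 2 region(s)
#>   reference year: 2020 | anchor year: 2018 | confidence: 0.95
#>   EU5: 10.8 births/yr (8.7-13.5), 187 patients (150-232), 2384k carriers
#>   US: 15.5 births/yr (12.4-19.5), 274 patients (219-344), 2383k carriers

formatBurdenTable(geneTable(report))[1:5, ]
#>    gene region births births_lo births_hi carriers_thousands patients patients_lo patients_hi
#> 1  PEX7     US   10.5       8.6      12.7               1090      184         152         224
#> 2 GNPAT     US    3.8       2.9       4.9                655       67          51          86
#> 3  AGPS     US    0.2       0.1       0.4                157        4           2           7
#> 4  FAR1     US    0.8       0.5       1.2                304       14           9          21
#> 5  PEX5     US    0.3       0.1       0.5                176        5           2           8
```

Reading the output: under the simulated mutational landscape, *PEX7*
dominates (10.5 affected US births/yr at 2018 birth levels; about 1.09
million US carriers), and the two regions together hold ~461 living
patients (95% range 370–576):

```r
combineRegions(regionTotals(report))[, c("patients", "patients_lo", "patients_hi")]
#>   patients patients_lo patients_hi
#> 1 460.5568    369.7961    575.9031
```

The default mortality model itself:

```r
buildDefaultMortalityTable()
#> MortalityTable: ages 0-34 (survival capped at max age)
#>   S(5) = 0.7500, S(15) = 0.6128, S(34) = 0.1257, S(35) = 0
#>   expected lifetime (sum of S(a), a = 0..34): 17.55 years
```

All of these numbers come from synthetic data; real regional estimates
require real allele-frequency extracts and birth series in the documented
TSV dialects. `reportedBurdenEstimates()` ships the previously reported
per-gene US/EU5 figures for checking the aggregation arithmetic.

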