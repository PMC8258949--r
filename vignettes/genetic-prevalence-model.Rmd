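---
title: "Estimating recessive disease burden from population allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recessive disease burden from population allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recessiveBurden)
```

# The model

`recessiveBurden` estimates the burden of an autosomal-recessive ultra-rare
disease — affected births per year, carriers, and the number of patients
alive today — from the carrier signal in large population sequencing
datasets. The package was built around rhizomelic chondrodysplasia punctata
(RCDP), caused by biallelic pathogenic variants in one of five plasmalogen
biosynthesis genes (*PEX7*, *GNPAT*, *AGPS*, *FAR1*, and *PEX5* restricted to
the PTS2-domain-encoding region), but nothing in the machinery is specific to
that disease.

The chain, per gene $g$ and region $r$:

$$q_{gr} = \sum_{i \in \text{included}} \frac{AC_i}{AN_i}, \qquad
  \text{prevalence} = q^2, \quad \text{carriers} = 2(1-q)q,$$

$$I_y = q^2 B_y, \qquad
  P = \sum_{a=0}^{A_{\max}} I_{(Y-a)}\, S(a), \quad
  S(a) = \prod_{k<a}(1-m_k),$$

with $B_y$ the live births in year $y$, $Y$ the reference year, $m_k$ the
annual mortality rate at age $k$, and $S$ truncated to zero past the maximum
lifespan $A_{\max}$.

## Assumptions

* **Random mating / Hardy–Weinberg equilibrium** within each region, no
  inbreeding correction ($F = 0$). Under HWE, $q^2$ with $q$ the *summed*
  per-variant frequency counts compound heterozygotes correctly:
  $(\sum_i q_i)^2 = \sum_i q_i^2 + \sum_{i \ne j} q_i q_j$.
* **Full penetrance at birth** of any biallelic pathogenic genotype, and no
  excess fetal mortality — both push the estimate upward.
* **Cross-gene double heterozygotes are negligible** and are not modelled.
* **Genetic prevalence is constant over the historic birth window**: the
  same $q^2$ multiplies every year's births back to the earliest cohort.
  Drift and migration over five decades are ignored.
* **One frequency dataset represents one region** (a US cohort for the US, a
  non-Finnish-European cohort applied uniformly to the pooled EU5 region:
  UK + Germany + France + Italy + Spain with one summed birth series).
* **The same mortality model applies to every gene and severity class** —
  survival data for such diseases rarely resolve subtype-specific curves.

# Variant inclusion

`classifyVariants()` is a total, deterministic decision procedure with an
explicit precedence (first match wins): interval restriction, clinical
benign, clinical pathogenic, predicted loss of function, SIFT/PolyPhen-2
concordant missense, discordant missense, everything else. Three choices
here were genuinely open and are this package's decisions:

* **PolyPhen "possibly damaging" counts as damaging.** Prediction-based
  inclusion asks for "damaging" calls without distinguishing PolyPhen
  grades; the permissive mapping is the default and the input encoding
  (`damaging_or_probably_damaging`) keeps the decision visible upstream.
* **Clinical assertions outrank predictions in both directions**, and
  variants with *uncertain* clinical significance fall through to the
  prediction rules. The `rule_fired` field flags every decision so a curator
  can audit and override by editing the input's `clinical` column.
* **Non-canonical splice-region variants are never auto-included**: cryptic
  splicing outcomes are not reliably predictable, so only canonical
  donor/acceptor sites count as loss of function.

The interval restriction is configuration, not code: no coordinates are
hardcoded for the PTS2 region, since those depend on genome build and
transcript set.

# Confidence intervals and their propagation

Per-variant counts are binomial, so the pooled frequency gets a modified
Wald (Agresti–Coull) interval: add $z^2/2$ pseudo-successes and failures,
then apply the Wald formula; clamp to $[0,1]$ and flag clamping. The exact
normal quantile is the default; `z_convention = "plus2"` gives the common
"add 2 and 2" simplification (they agree to well within reporting
precision at these scales).

How to build *one* interval from *many* sites with different allele numbers
is not determined by the method itself. Three strategies are exposed, and
the choice is recorded in report metadata rather than resolved silently:

* `effective_mean` (default): an effective binomial with
  $n = \overline{AN}$, $x = \mathrm{round}(\hat q\, n)$ — symmetric, and
  exactly recovers the single-site interval;
* `min_an`: same with $n = \min AN$, conservative;
* `per_variant_sum`: sum of per-variant bounds, the widest.

A gene with *no* included variants is a legitimate empty aggregate
($\hat q = 0$ with the $x = 0$ upper bound): real extracts do miss genes in
one cohort. The upper bound then needs an allele number; the package falls
back to the mean AN of the gene's records, then of the dataset, then to a
configurable `fallback_an` (default 250,000 alleles, the scale of a
~125,000-individual cohort).

Every later transform — squaring, $2pq$ on $[0, 0.5]$ (a domain error
beyond, where $2pq$ is non-monotone), multiplication by births, population
and survival weights, summation — is monotone, so the confidence bounds
propagate componentwise (lo with lo, hi with hi) end to end. No delta
method, no resampling; the reported range is exactly the allele-frequency
range pushed through the model, which is also why only allele-frequency
uncertainty (not mortality-model uncertainty) appears in the output.

# The mortality model

A discrete-time life table: $m_a$ is the probability of dying during the
year of age $a$ given survival to $a$; deaths occur at year boundaries; age
is completed years at the reference date. The packaged default is a
three-segment parameterization:

| segment | default | why |
|---|---|---|
| ages 0–4 | $r_0 = 1 - 0.75^{1/5} \approx 0.0559$/yr | calibrated so $S(5) = 0.75$ exactly, the one quantitative constraint the natural-history literature provides |
| ages 5–14 | 0.02/yr | a smooth decline consistent with the qualitative observation that most deaths are early; the published per-age rates for this range are not recoverable, so this segment is an explicit default, not a reconstruction |
| ages 15–$A_{\max}$ | 0.08/yr | the reported uniform adult rate |
| $A_{\max}$ | 34 | the reported maximum lifespan; $S(a) = 0$ for $a > 34$ regardless of rates |

The model is data, not code: any per-age vector supplied via
`MortalityTable()` or a CSV (`age, annual_mortality_rate`, contiguous ages)
replaces the default, and `validateMortalityRates()` returns diagnostics
(not exceptions) for pre-flight checks.

# Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `conf_level` | 0.95 | probability | applied at the allele-frequency stage and inherited by everything downstream |
| `anchor_year` | 2018 | year | births year for the headline incidence |
| `reference_year` | 2020 | year | evaluation date for current prevalence; the historic window is `reference_year - max_lifespan .. reference_year` |
| `max_lifespan` | 34 | years | must match the mortality table |
| `population_sizes` | — | individuals | carrier-scaling denominator; total population by default, an age-restricted denominator is equally defensible and is the caller's choice |
| `pool_strategy` | `effective_mean` | — | see above |
| `z_convention` | `exact` | — | normal quantile vs $z=2$ |
| `totals_mode` | `unrounded` | — | totals from unrounded gene rows; `sum_of_rounded` reproduces table conventions that round first (both are emitted in the JSON report) |
| `fallback_an` | 250,000 | alleles | empty-aggregate interval denominator |

# Numerical and reporting choices

* **Gap-filling** of birth series: a missing year takes the births of the
  nearest available year, ties to the earlier year — deterministic, flagged
  per filled row, and low-stakes because old cohorts contribute almost
  nothing after survival weighting.
* **Rounding is a display concern.** All slots hold unrounded values;
  `formatBurdenTable()` rounds births to one decimal, carriers to the
  nearest thousand, patients to integers, and confidence bounds *outward*
  (floor/ceil). Independently rounded gene rows can therefore disagree with
  the rounded totals row by a unit in the last place — an artifact of
  printing, not of arithmetic, and the reason `burdenTotals()` exposes both
  totals modes.
* **Degenerate inputs** are either valid empties (gene absent from a cohort)
  or named domain errors (AC > AN identifies the variant; an incidence gap
  names the missing year; pipeline errors carry their stage label).

# The synthetic-data generator

`simulateVariantTable()` splits each gene's true aggregate frequency across
its variants (flat Dirichlet, or equal shares), draws
$AC \sim \mathrm{Binomial}(2N, q_i)$ independently per variant and dataset at
$N = 125{,}000$ individuals, assigns consequences and prediction calls so the
intended variants pass the filter, and plants one decoy per exclusion rule.
`simulateBirthSeries()` produces level + trend + bounded-noise series;
`simulateSurvivalCohort()` draws ages at death from the life table's implied
distribution (default cohort size 66, the scale of the published
natural-history study). Everything is seeded and reproducible, and
`writeFixtureBundle()` emits exactly the TSV dialects the ingestion layer
reads.

What it emulates: binomial sampling noise at cohort scale, rare-variant
sparsity, per-rule filter traps, demographic input shapes. What it does
not: linkage between sites (the downstream model itself assumes independent
alleles, so matched assumptions are a feature for verification but a
limitation for realism), population substructure, sequencing error,
coverage-dependent AN variation, or annotation noise (real SIFT/PolyPhen
calls disagree with truth; synthetic ones are constructed consistent).
Passing tests therefore establish that the arithmetic chain is correct under
the model's own assumptions — not that the assumptions hold in any real
cohort.

The preset (`presetSimulationSpec()`) places five genes at frequencies with
the order-of-magnitude profile of the RCDP landscape (one dominant gene near
$q = 1.8\times10^{-3}$, one intermediate, three near zero) for demonstration;
reproducing real published numbers requires the real supplementary variant
lists and birth series, which are not redistributable here.

# Test design and problem sizes

The suite verifies each stage against independent oracles: frozen
Agresti–Coull bounds from an external reference implementation; brute-force
enumeration for compound-heterozygote coverage; an explicit per-cohort,
per-year aging loop (20 randomized configurations, agreement to $10^{-9}$
relative) against the vectorized pipeline; a zero-noise generator
configuration whose truth round-trips to $10^{-9}$; and frequentist
calibration — 500 replicates per true frequency
($10^{-4}$, $10^{-3}$) at 250,000 alleles, checking unbiasedness within
three Monte-Carlo standard errors and 95%-interval coverage inside
$[0.93, 0.99]$ (the modified Wald interval is approximate at extreme
proportions; exact nominal coverage is not expected). These sizes keep the
whole suite under a minute while leaving Monte-Carlo error well below the
tolerances tested.

# Known limitations

* Estimates are upper-bound-flavoured: full penetrance, no fetal loss, and
  permissive missense inclusion all inflate $q$.
* In-silico prediction concordance is a crude pathogenicity proxy; the
  filter cannot rescue a pathogenic variant labelled benign upstream, nor
  reject a benign variant with concordant damaging predictions unless
  clinically reported.
* One mortality model for all genotypes and severities.
* EU5 is one pooled region with one frequency source; country-level
  decomposition is out of scope.
* Only allele-frequency uncertainty is propagated; the mortality table and
  birth series enter as point values.
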