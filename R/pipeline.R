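#' Run configuration
#'
#' Collects every tunable constant of the model in one validated list. The
#' defaults encode the study conditions the model was built for: 95%
#' confidence, birth incidence anchored to 2018 births, prevalence evaluated
#' in 2020, maximum lifespan 34, and a dataset-to-region mapping pairing a
#' US sequencing cohort with the US and a non-Finnish-European cohort with
#' the pooled EU5 region (UK + Germany + France + Italy + Spain, one summed
#' birth series with the European frequencies applied uniformly).
#'
#' @param genes character vector of disease gene symbols to model
#' @param dataset_regions named character vector, dataset label -> region label
#' @param population_sizes named numeric, region -> individuals (carrier
#'   scaling denominator; total population by default — exposed because an
#'   age-restricted denominator is an equally defensible choice)
#' @param region_restrictions named list, gene -> list(chrom, start, end);
#'   e.g. confining PEX5 to the PTS2-domain-encoding interval
#' @param conf_level confidence level in (0, 1)
#' @param reference_year year at which current prevalence is evaluated
#' @param anchor_year year whose births anchor the headline incidence
#' @param max_lifespan last attainable age (must match the mortality table)
#' @param pool_strategy,z_convention see [aggregateGeneFrequency()]
#' @param totals_mode see [burdenTotals()]
#' @param fallback_an allele number for empty aggregates
#' @return a list of class `burden_config`
#' @export
burdenConfig <- function(genes,
                         dataset_regions,
                         population_sizes,
                         region_restrictions = list(),
                         conf_level = 0.95,
                         reference_year = 2020L,
                         anchor_year = 2018L,
                         max_lifespan = 34L,
                         pool_strategy = "effective_mean",
                         z_convention = "exact",
                         totals_mode = "unrounded",
                         fallback_an = 250000) {
  stopifnot(conf_level > 0, conf_level < 1, max_lifespan >= 0,
            length(genes) >= 1, !is.null(names(dataset_regions)))
  regions <- unique(unname(dataset_regions))
  missing_pop <- setdiff(regions, names(population_sizes))
  if (length(missing_pop)) {
    stop(sprintf("no population size configured for region(s): %s",
                 paste(missing_pop, collapse = ", ")))
  }
  structure(list(genes = genes,
                 dataset_regions = dataset_regions,
                 population_sizes = population_sizes,
                 region_restrictions = region_restrictions,
                 conf_level = conf_level,
                 reference_year = as.integer(reference_year),
                 anchor_year = as.integer(anchor_year),
                 max_lifespan = as.integer(max_lifespan),
                 pool_strategy = pool_strategy,
                 z_convention = z_convention,
                 totals_mode = totals_mode,
                 fallback_an = fallback_an),
            class = "burden_config")
}

#' Age an incidence series into current prevalence
#'
#' Life-table conversion of incidence to prevalence: every historic birth
#' cohort is aged to the reference year, so the expected number of living
#' patients of age a is n_a = I_(reference_year - a) * S(a) for
#' a = 0..max_age, and the total is their sum. Computed componentwise on
#' (point, lo, hi).
#'
#' @param incidence data.frame from [annualBirthIncidence()]; must cover birth
#'   years `reference_year - max_age .. reference_year` without gaps
#' @param table a [MortalityTable-class]
#' @param reference_year evaluation year
#' @return list: `total` (count triplet), `by_age` (data.frame
#'   `age, point, lo, hi`)
#' @export
ageStructuredPrevalence <- function(incidence, table, reference_year) {
  ages <- 0:maxAge(table)
  need <- reference_year - ages
  idx <- match(need, incidence$year)
  if (anyNA(idx)) {
    stop(sprintf("incidence series is missing year %d within the prevalence window",
                 need[which(is.na(idx))[1]]))
  }
  s <- survivalToAge(table, ages)
  by_age <- data.frame(age = ages,
                       point = incidence$point[idx] * s,
                       lo = incidence$lo[idx] * s,
                       hi = incidence$hi[idx] * s)
  total <- estTriplet(sum(by_age$point), sum(by_age$lo), sum(by_age$hi))
  list(total = total, by_age = by_age)
}

AGE_BIN_WIDTH <- 5L

bin_age_distribution <- function(by_age, region) {
  bin_lo <- (by_age$age %/% AGE_BIN_WIDTH) * AGE_BIN_WIDTH
  lab <- sprintf("%d-%d", bin_lo, bin_lo + AGE_BIN_WIDTH - 1L)
  agg <- aggregate(by_age[, c("point", "lo", "hi")],
                   by = list(age_bin = lab, bin_lo = bin_lo), FUN = sum)
  agg <- agg[order(agg$bin_lo), ]
  data.frame(region = region, age_bin = agg$age_bin,
             patients = agg$point, patients_lo = agg$lo, patients_hi = agg$hi,
             stringsAsFactors = FALSE)
}

#' Run the full burden model
#'
#' Orchestrates the chain variant filtering -> pooled allele frequency with
#' confidence interval -> Hardy-Weinberg genotype and carrier prevalence ->
#' annual birth incidence -> life-table aging -> current prevalence and age
#' distribution, for every configured gene and region, with the confidence
#' range propagated componentwise end to end.
#'
#' @param variants variant data.frame or path to a variant TSV
#' @param births birth-series data.frame or TSV path (`region, year, births`)
#' @param mortality a [MortalityTable-class], a mortality CSV path, or `NULL`
#'   for the packaged default
#' @param config a [burdenConfig()]
#' @return a [BurdenReport-class]
#' @export
runFullModel <- function(variants, births, mortality = NULL, config) {
  stopifnot(inherits(config, "burden_config"))
  if (is.character(variants)) variants <- readVariantTable(variants, "tsv")
  else variants <- validateVariantRecords(variants)
  if (is.character(births)) births <- readBirthSeries(births)
  table <- if (is.null(mortality)) {
    buildDefaultMortalityTable(max_age = config$max_lifespan)
  } else if (is.character(mortality)) {
    readMortalityTable(mortality)
  } else mortality
  if (maxAge(table) != config$max_lifespan) {
    stop(sprintf("mortality table max age (%d) disagrees with configured max lifespan (%d)",
                 maxAge(table), config$max_lifespan))
  }

  calls <- classifyVariants(variants, config$region_restrictions)
  regions <- unique(unname(config$dataset_regions))
  window <- (config$reference_year - config$max_lifespan):config$reference_year

  rows <- list(); age_rows <- list(); filled_years <- list()
  for (region in regions) {
    datasets <- names(config$dataset_regions)[config$dataset_regions == region]
    rb <- births[births$region == region, c("year", "births")]
    if (!nrow(rb)) stop(sprintf("incidence stage: no birth series for region %s", region))
    v_region <- variants[variants$dataset %in% datasets, , drop = FALSE]
    c_region <- calls[variants$dataset %in% datasets, , drop = FALSE]
    # each region maps to one frequency dataset in the study design; if several
    # datasets are mapped they are pooled as one set of records
    v_region$dataset <- region
    c_region$dataset <- region
    for (gene in config$genes) {
      agg <- tryCatch(
        aggregateGeneFrequency(v_region, c_region, gene, dataset = region,
                               conf_level = config$conf_level,
                               pool_strategy = config$pool_strategy,
                               z_convention = config$z_convention,
                               fallback_an = config$fallback_an),
        error = function(e) stop(sprintf("allele-frequency stage (%s, %s): %s",
                                         gene, region, conditionMessage(e))))
      q <- estTriplet(agg$q_hat, agg$q_lo, agg$q_hi, max = 1)
      gp <- genotypePrevalence(q)
      cf <- carrierFrequency(q)
      carriers <- carriersInPopulation(cf, config$population_sizes[[region]])
      inc <- tryCatch(
        annualBirthIncidence(gp, rb, union(window, config$anchor_year)),
        error = function(e) stop(sprintf("incidence stage (%s, %s): %s",
                                         gene, region, conditionMessage(e))))
      filled_years[[region]] <- inc$year[inc$filled]
      prev <- tryCatch(
        ageStructuredPrevalence(inc, table, config$reference_year),
        error = function(e) stop(sprintf("prevalence stage (%s, %s): %s",
                                         gene, region, conditionMessage(e))))
      anchor <- inc[inc$year == config$anchor_year, ]
      rows[[paste(gene, region)]] <- data.frame(
        gene = gene, region = region,
        n_variants = agg$n_variants,
        q_hat = q[["point"]], q_lo = q[["lo"]], q_hi = q[["hi"]],
        births = anchor$point, births_lo = anchor$lo, births_hi = anchor$hi,
        carriers = carriers[["point"]], carriers_lo = carriers[["lo"]],
        carriers_hi = carriers[["hi"]],
        patients = prev$total[["point"]], patients_lo = prev$total[["lo"]],
        patients_hi = prev$total[["hi"]],
        birth_prev_100k = birthPrevalencePer100k(anchor$point, anchor$births),
        stringsAsFactors = FALSE)
      ab <- prev$by_age
      ab$gene <- gene
      ab$region <- region
      age_rows[[paste(gene, region)]] <- ab
    }
  }
  gene_table <- do.call(rbind, rows)
  rownames(gene_table) <- NULL
  by_age_all <- do.call(rbind, age_rows)
  age_dist <- do.call(rbind, lapply(regions, function(r) {
    sub <- by_age_all[by_age_all$region == r, ]
    summed <- aggregate(sub[, c("point", "lo", "hi")],
                        by = list(age = sub$age), FUN = sum)
    bin_age_distribution(summed, r)
  }))
  rownames(age_dist) <- NULL
  excluded <- calls[!calls$included, c("variant_id", "dataset", "rule_fired")]
  new("BurdenReport",
      geneTable = gene_table,
      totals = burdenTotals(gene_table, config$totals_mode),
      ageDistribution = age_dist,
      metadata = list(reference_year = config$reference_year,
                      anchor_year = config$anchor_year,
                      conf_level = config$conf_level,
                      dataset_regions = as.list(config$dataset_regions),
                      pool_strategy = config$pool_strategy,
                      z_convention = config$z_convention,
                      totals_mode = config$totals_mode,
                      max_lifespan = config$max_lifespan,
                      provenance = list(
                        excluded_variants = excluded,
                        gap_filled_years = filled_years)))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
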