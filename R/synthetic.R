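# Fictional but chromosome-plausible coordinates for generated variants;
# generated files are labelled synthetic in their headers/sidecars.
GENE_LOCI <- list(
  PEX7  = list(chrom = "chr6",  start = 137143800, end = 137235000),
  GNPAT = list(chrom = "chr1",  start = 231242500, end = 231280000),
  AGPS  = list(chrom = "chr2",  start = 177392000, end = 177539000),
  FAR1  = list(chrom = "chr11", start = 13690200,  end = 13758000),
  PEX5  = list(chrom = "chr12", start = 7341600,   end = 7371000)
)

#' Specify a synthetic study
#'
#' Defines the conditions the generator emulates: per-gene true pathogenic
#' allele frequencies in the ultra-rare range, allele-count draws at
#' sequencing-cohort scale (default 125,000 individuals, the size class of
#' the large population datasets the model consumes), region demography, and
#' a natural-history survival cohort (default 66 patients, the size of the
#' published RCDP cohort).
#'
#' @param genes data.frame with columns `gene`, `q_true` (aggregate pathogenic
#'   allele frequency, <= 0.01), `n_variants`
#' @param cohort_size sequenced individuals per dataset (alleles = 2x)
#' @param regions data.frame `region, dataset, population, annual_births,
#'   births_noise_sd`
#' @param survival_cohort_size patients in the simulated survival study
#' @param seed RNG seed (mandatory; recorded in the truth sidecar)
#' @return list of class `simulation_spec`
#' @export
simulationSpec <- function(genes, cohort_size = 125000L, regions,
                           survival_cohort_size = 66L, seed) {
  stopifnot(all(c("gene", "q_true", "n_variants") %in% names(genes)),
            all(c("region", "dataset", "population", "annual_births") %in% names(regions)),
            !missing(seed))
  if (any(genes$q_true > 0.01)) {
    stop("q_true above 0.01 is outside the ultra-rare regime this generator emulates")
  }
  if (any(genes$n_variants < 1)) stop("each gene needs at least one variant")
  if (is.null(regions$births_noise_sd)) regions$births_noise_sd <- 0
  structure(list(genes = genes, cohort_size = as.integer(cohort_size),
                 regions = regions,
                 survival_cohort_size = as.integer(survival_cohort_size),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Disease-scale preset simulation
#'
#' Five genes with aggregate frequencies at the order of magnitude seen in
#' the RCDP mutational landscape — one dominant gene (PEX7-like, q near
#' 1.8e-3), one intermediate, and three near-zero genes — two regions at US
#' and EU5 demographic scale. For demonstration and testing; real estimates
#' require real frequency extracts.
#'
#' @param seed RNG seed
#' @return a `simulation_spec`
#' @export
presetSimulationSpec <- function(seed = 20210706L) {
  simulationSpec(
    genes = data.frame(
      gene = c("PEX7", "GNPAT", "AGPS", "FAR1", "PEX5"),
      q_true = c(1.76e-3, 1.15e-3, 2.8e-4, 4.0e-4, 2.8e-4),
      n_variants = c(12L, 10L, 4L, 4L, 2L)),
    cohort_size = 125000L,
    regions = data.frame(
      region = c("US", "EU5"),
      dataset = c("US-TopMed", "EU5-gnomAD-NFE"),
      population = c(328e6, 324e6),
      annual_births = c(3.79e6, 2.4e6),
      births_noise_sd = c(3e4, 2e4)),
    seed = seed)
}

split_q <- function(q_true, k, fixed_proportions = FALSE) {
  if (fixed_proportions || k == 1L) {
    rep(q_true / k, k)
  } else {
    w <- rgamma(k, shape = 1) # Dirichlet(1,...,1) weights
    q_true * w / sum(w)
  }
}

#' Simulate a variant annotation/frequency table
#'
#' Splits each gene's true aggregate frequency across its variants (flat
#' Dirichlet by default, equal shares with `fixed_proportions = TRUE`), draws
#' AC ~ Binomial(2 x cohort_size, q_i) independently per variant and dataset
#' (`as_expectation = TRUE` sets AC to round(2 N q_i) instead, for exact
#' round-trip checks), assigns consequences and prediction calls so every
#' intended variant passes the inclusion filter, and appends one decoy per
#' exclusion rule and gene x dataset: a clinically benign variant, a
#' discordant missense, a non-canonical splice-region variant, and — for
#' genes with a configured interval restriction — an out-of-region variant.
#' Sites are simulated as independent (no linkage), matching the random-mating
#' independence the downstream model itself assumes.
#'
#' @param spec a [simulationSpec()]
#' @param region_restrictions as in [classifyVariants()]; used to place
#'   in-region true variants and out-of-region decoys
#' @param as_expectation use expected counts instead of binomial draws
#' @param fixed_proportions equal split of q_true across variants
#' @return list: `variants` (TSV-dialect data.frame), `truth` (list with
#'   per-gene q_true, per-variant frequencies, decoy ids, seed)
#' @export
simulateVariantTable <- function(spec, region_restrictions = list(),
                                 as_expectation = FALSE,
                                 fixed_proportions = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  an <- 2L * spec$cohort_size
  included_cons <- c("stop_gained", "frameshift", "missense",
                     "splice_donor", "splice_acceptor")
  rows <- list(); truth_variants <- list(); decoy_ids <- character()
  for (g in seq_len(nrow(spec$genes))) {
    gene <- spec$genes$gene[g]
    k <- spec$genes$n_variants[g]
    qs <- split_q(spec$genes$q_true[g], k, fixed_proportions)
    locus <- GENE_LOCI[[gene]]
    if (is.null(locus)) locus <- list(chrom = "chrN", start = 1e6, end = 2e6)
    rr <- region_restrictions[[gene]]
    lo <- if (!is.null(rr)) rr$start else locus$start
    hi <- if (!is.null(rr)) rr$end else locus$end
    pos <- as.integer(round(seq(lo, hi, length.out = k + 2L)))[2:(k + 1L)]
    cons <- included_cons[((seq_len(k) - 1L) %% length(included_cons)) + 1L]
    for (d in seq_len(nrow(spec$regions))) {
      dataset <- spec$regions$dataset[d]
      ac <- if (as_expectation) as.integer(round(an * qs)) else rbinom(k, an, qs)
      vid <- sprintf("%s_v%02d", gene, seq_len(k))
      rows[[paste(gene, dataset)]] <- data.frame(
        variant_id = vid, gene = gene, chrom = locus$chrom, pos = pos,
        ref = "A", alt = "T", consequence = cons,
        sift = ifelse(cons == "missense", "deleterious", "unknown"),
        polyphen = ifelse(cons == "missense", "damaging_or_probably_damaging",
                          "unknown"),
        clinical = ifelse(seq_len(k) == 1L, "reported_pathogenic", "unreported"),
        AC = ac, AN = an, dataset = dataset, stringsAsFactors = FALSE)
      # decoys: one per exclusion rule, drawn at a small fixed frequency
      dq <- 2e-5
      dec_ac <- if (as_expectation) as.integer(round(an * dq)) else rbinom(3, an, dq)
      decoys <- data.frame(
        variant_id = sprintf("%s_decoy_%s", gene,
                             c("benign", "discordant", "other")),
        gene = gene, chrom = locus$chrom,
        pos = pos[1] + 1:3,
        ref = "G", alt = "C",
        consequence = c("missense", "missense", "splice_region"),
        sift = c("deleterious", "deleterious", "unknown"),
        polyphen = c("damaging_or_probably_damaging", "benign", "unknown"),
        clinical = c("reported_benign", "unreported", "unreported"),
        AC = dec_ac, AN = an, dataset = dataset, stringsAsFactors = FALSE)
      if (!is.null(rr)) {
        out_pos <- if (rr$start > locus$start) locus$start else locus$end
        decoys <- rbind(decoys, data.frame(
          variant_id = sprintf("%s_decoy_region", gene),
          gene = gene, chrom = locus$chrom, pos = as.integer(out_pos),
          ref = "G", alt = "C", consequence = "stop_gained",
          sift = "unknown", polyphen = "unknown", clinical = "unreported",
          AC = if (as_expectation) as.integer(round(an * dq)) else rbinom(1, an, dq),
          AN = an, dataset = dataset, stringsAsFactors = FALSE))
      }
      rows[[paste(gene, dataset, "decoys")]] <- decoys
      decoy_ids <- union(decoy_ids, decoys$variant_id)
    }
    truth_variants[[gene]] <- data.frame(variant_id = sprintf("%s_v%02d", gene, seq_len(k)),
                                         q_i = qs)
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  list(variants = variants,
       truth = list(q_true = setNames(spec$genes$q_true, spec$genes$gene),
                    variant_frequencies = truth_variants,
                    decoy_ids = decoy_ids,
                    cohort_size = spec$cohort_size,
                    seed = spec$seed,
                    as_expectation = as_expectation,
                    note = "synthetic data: independent sites, no linkage"))
}

#' Simulate a historic birth series
#'
#' Level + optional linear trend + bounded Gaussian noise, floored at zero
#' and rounded to integers; deterministic under a fixed seed.
#'
#' @param spec a [simulationSpec()]
#' @param years integer years to generate
#' @param trend additive births per year (default 0)
#' @return data.frame `region, year, births`
#' @export
simulateBirthSeries <- function(spec, years, trend = 0) {
  stopifnot(inherits(spec, "simulation_spec"), length(years) >= 1)
  set.seed(spec$seed + 1L)
  years <- sort(unique(as.integer(years)))
  do.call(rbind, lapply(seq_len(nrow(spec$regions)), function(d) {
    lvl <- spec$regions$annual_births[d]
    sdv <- spec$regions$births_noise_sd[d]
    b <- lvl + trend * (years - years[1]) +
      if (sdv > 0) rnorm(length(years), 0, sdv) else 0
    data.frame(region = spec$regions$region[d], year = years,
               births = pmax(0, round(b)), stringsAsFactors = FALSE)
  }))
}

#' Simulate a natural-history survival cohort
#'
#' Draws each patient's age at death from the distribution a
#' [MortalityTable-class] implies: P(death during age a) = S(a) m_a, with all
#' probability mass beyond the lifespan cap assigned to the maximum age
#' (death before the (max_age + 1)th birthday). The empirical survival curve
#' converges to S(a) within binomial error.
#'
#' @param table a [MortalityTable-class]
#' @param n patients
#' @param seed RNG seed
#' @return integer vector of ages at death (completed years)
#' @export
simulateSurvivalCohort <- function(table, n, seed) {
  set.seed(seed)
  ages <- 0:maxAge(table)
  s <- survivalToAge(table, ages)
  pmf <- s * mortalityRates(table)
  pmf[length(pmf)] <- pmf[length(pmf)] + prod(1 - mortalityRates(table))
  sample(ages, n, replace = TRUE, prob = pmf)
}

#' Write a simulated fixture bundle
#'
#' Emits exactly the file dialects the ingestion layer consumes —
#' `variants.tsv`, `births.tsv` — plus `truth.json` (generator ground truth)
#' so a simulated bundle can be fed straight back into [runFullModel()].
#'
#' @param spec a [simulationSpec()]
#' @param dir output directory
#' @param years years for the birth series
#' @param region_restrictions passed to [simulateVariantTable()]
#' @param ... further arguments to [simulateVariantTable()]
#' @return invisibly, named paths of the files written
#' @export
writeFixtureBundle <- function(spec, dir, years = 1970:2020,
                               region_restrictions = list(), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateVariantTable(spec, region_restrictions = region_restrictions, ...)
  births <- simulateBirthSeries(spec, years)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             births = file.path(dir, "births.tsv"),
             truth = file.path(dir, "truth.json"))
  write.table(sim$variants, paths["variants"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(births, paths["births"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
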