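test_that("the generator is reproducible bit-for-bit under a fixed seed", {
  spec <- simulationSpec(
    genes = data.frame(gene = "PEX7", q_true = 1e-3, n_variants = 4L),
    regions = data.frame(region = "US", dataset = "US-TopMed",
                         population = 328e6, annual_births = 3.8e6,
                         births_noise_sd = 3e4),
    seed = 123)
  expect_identical(simulateVariantTable(spec), simulateVariantTable(spec))
  expect_identical(simulateBirthSeries(spec, 1970:2020),
                   simulateBirthSeries(spec, 1970:2020))
  spec2 <- simulationSpec(genes = spec$genes, regions = spec$regions, seed = 124)
  expect_false(identical(simulateVariantTable(spec)$variants$AC,
                         simulateVariantTable(spec2)$variants$AC))
})

test_that("spec validation rejects out-of-regime or infeasible inputs", {
  g <- data.frame(gene = "X", q_true = 0.05, n_variants = 3L)
  r <- data.frame(region = "US", dataset = "D", population = 1e6,
                  annual_births = 1e4)
  expect_error(simulationSpec(genes = g, regions = r, seed = 1), "ultra-rare")
  g2 <- data.frame(gene = "X", q_true = 1e-3, n_variants = 0L)
  expect_error(simulationSpec(genes = g2, regions = r, seed = 1),
               "at least one variant")
})

test_that("each decoy class is excluded by its intended rule and truth ids match", {
  rr <- list(PEX5 = list(chrom = "chr12", start = 7341600, end = 7350000))
  spec <- simulationSpec(
    genes = data.frame(gene = c("PEX7", "PEX5"), q_true = c(1e-3, 2e-4),
                       n_variants = c(4L, 2L)),
    regions = data.frame(region = "US", dataset = "US-TopMed",
                         population = 328e6, annual_births = 3.8e6),
    seed = 11)
  sim <- simulateVariantTable(spec, region_restrictions = rr)
  calls <- classifyVariants(sim$variants, rr)
  merged <- merge(sim$variants, calls, by = c("variant_id", "dataset"))
  expect_equal(unique(merged$rule_fired[grepl("decoy_benign", merged$variant_id)]),
               "excluded_benign")
  expect_equal(unique(merged$rule_fired[grepl("decoy_discordant", merged$variant_id)]),
               "excluded_discordant")
  expect_equal(unique(merged$rule_fired[grepl("decoy_other", merged$variant_id)]),
               "excluded_other")
  expect_equal(unique(merged$rule_fired[grepl("decoy_region", merged$variant_id)]),
               "excluded_region")
  # every intended variant is included; every decoy excluded
  is_decoy <- merged$variant_id %in% sim$truth$decoy_ids
  expect_true(all(merged$included[!is_decoy]))
  expect_true(all(!merged$included[is_decoy]))
})

test_that("a decoy-only table drives the aggregate frequency to zero", {
  spec <- simulationSpec(
    genes = data.frame(gene = "PEX7", q_true = 1e-3, n_variants = 2L),
    regions = data.frame(region = "US", dataset = "US-TopMed",
                         population = 328e6, annual_births = 3.8e6),
    seed = 21)
  sim <- simulateVariantTable(spec)
  decoys <- sim$variants[sim$variants$variant_id %in% sim$truth$decoy_ids, ]
  calls <- classifyVariants(decoys)
  agg <- aggregateGeneFrequency(decoys, calls, "PEX7", "US-TopMed")
  expect_equal(agg$q_hat, 0)
})

test_that("replicated draws estimate the true aggregate frequency without bias", {
  q_true <- 1e-3
  an <- 250000L
  n_rep <- 500
  q_hat <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    spec <- simulationSpec(
      genes = data.frame(gene = "PEX7", q_true = q_true, n_variants = 4L),
      cohort_size = an %/% 2L,
      regions = data.frame(region = "US", dataset = "US-TopMed",
                           population = 328e6, annual_births = 3.8e6),
      seed = 1000L + i)
    sim <- simulateVariantTable(spec, fixed_proportions = TRUE)
    v <- sim$variants[!sim$variants$variant_id %in% sim$truth$decoy_ids, ]
    q_hat[i] <- sum(v$AC / v$AN)
  }
  # binomial sampling theory: var(q_hat) ~ q_true / AN for rare alleles
  mc_se <- sqrt(q_true / an / n_rep)
  expect_lt(abs(mean(q_hat) - q_true), 3 * mc_se)
})

test_that("birth series generation honours level, trend and noise settings", {
  spec <- simulationSpec(
    genes = data.frame(gene = "PEX7", q_true = 1e-3, n_variants = 1L),
    regions = data.frame(region = "US", dataset = "US-TopMed",
                         population = 328e6, annual_births = 3.8e6,
                         births_noise_sd = 0),
    seed = 31)
  flat <- simulateBirthSeries(spec, 2000:2010)
  expect_true(all(flat$births == 3.8e6))
  ramp <- simulateBirthSeries(spec, 2000:2010, trend = 1000)
  expect_equal(ramp$births, 3.8e6 + 1000 * (0:10))
  expect_true(all(simulateBirthSeries(spec, 1970:2020)$births >= 0))
})

test_that("a written fixture bundle feeds straight back into the pipeline", {
  dir <- tempfile("bundle")
  spec <- presetSimulationSpec(seed = 8)
  paths <- writeFixtureBundle(spec, dir)
  expect_true(all(file.exists(paths)))
  variants <- readVariantTable(paths[["variants"]], "tsv")
  births <- readBirthSeries(paths[["births"]])
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 8L)
  cfg <- burdenConfig(genes = spec$genes$gene,
                      dataset_regions = c("US-TopMed" = "US",
                                          "EU5-gnomAD-NFE" = "EU5"),
                      population_sizes = c(US = 328e6, EU5 = 324e6))
  rep <- runFullModel(variants, births, NULL, cfg)
  expect_s4_class(rep, "BurdenReport")
  expect_equal(nrow(geneTable(rep)), 10L)
})
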