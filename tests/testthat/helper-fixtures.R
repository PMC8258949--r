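# in-code fixtures: build variant records with sensible defaults
variant_row <- function(variant_id = "v1", gene = "PEX7", chrom = "chr6",
                        pos = 137150000L, ref = "A", alt = "T",
                        consequence = "missense", sift = "deleterious",
                        polyphen = "damaging_or_probably_damaging",
                        clinical = "unreported", AC = 5L, AN = 250000L,
                        dataset = "US-TopMed") {
  data.frame(variant_id = variant_id, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = alt, consequence = consequence, sift = sift,
             polyphen = polyphen, clinical = clinical, AC = AC, AN = AN,
             dataset = dataset, stringsAsFactors = FALSE)
}

variant_table <- function(...) {
  validateVariantRecords(do.call(rbind, list(...)))
}

write_variant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

flat_births <- function(region = "US", years = 1980:2020, level = 1e6) {
  data.frame(region = region, year = years, births = level)
}

# minimal single-gene config for pipeline tests
mini_config <- function(genes = "PEX7", reference_year = 2020L, ...) {
  burdenConfig(genes = genes,
               dataset_regions = c("US-TopMed" = "US"),
               population_sizes = c(US = 328e6),
               reference_year = reference_year, ...)
}
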