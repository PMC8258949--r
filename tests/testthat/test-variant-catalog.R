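test_that("a well-formed TSV parses into typed, validated records", {
  df <- rbind(variant_row("v1"), variant_row("v2", AC = 3L),
              variant_row("v3", consequence = "stop_gained",
                          sift = "unknown", polyphen = "unknown"))
  path <- write_variant_tsv(df)
  rec <- readVariantTable(path, "tsv")
  expect_equal(nrow(rec), 3L)
  expect_type(rec$AC, "integer")
  expect_type(rec$AN, "integer")
  expect_type(rec$pos, "integer")
  expect_equal(rec$variant_id, c("v1", "v2", "v3"))
})

test_that("malformed variant tables are rejected with named diagnostics", {
  ok <- variant_row()
  # missing mandatory column
  path <- write_variant_tsv(ok[, setdiff(names(ok), "AN")])
  expect_error(readVariantTable(path, "tsv"), "AN")
  # AC exceeding AN names the offending variant
  bad <- variant_row("vbad", AC = 12L, AN = 10L)
  expect_error(validateVariantRecords(bad), "vbad")
  # frequencies above 0.5 are not minor alleles
  expect_error(validateVariantRecords(variant_row(AC = 200000L, AN = 250000L)),
               "minor")
  # non-integer counts carry the row number
  nonint <- variant_row()
  nonint$AC <- "5.5"
  expect_error(validateVariantRecords(nonint), "row 1")
  expect_error(validateVariantRecords(variant_row(pos = 0L)), "pos")
  expect_error(validateVariantRecords(variant_row(consequence = "nonsense")),
               "consequence")
})

test_that("VCF INFO AC/AN extraction joins with sidecar annotations", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr6\t137150000\trs1805137\tT\tA\t.\tPASS\tAC=7;AN=251496",
    "chr6\t137151000\t.\tG\tA,C\t.\tPASS\tAC=2,3;AN=251496")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  sidecar <- data.frame(
    variant_id = c("rs1805137", "chr6-137151000-G-A", "chr6-137151000-G-C"),
    gene = "PEX7",
    consequence = c("stop_gained", "missense", "missense"),
    sift = c("unknown", "deleterious", "tolerated"),
    polyphen = c("unknown", "damaging_or_probably_damaging", "benign"),
    clinical = c("reported_pathogenic", "unreported", "unreported"),
    stringsAsFactors = FALSE)
  rec <- readVariantTable(path, "vcf", annotation_sidecar = sidecar,
                          dataset = "US-TopMed")
  expect_equal(nrow(rec), 3L) # multi-allelic site expands per alt allele
  r1 <- rec[rec$variant_id == "rs1805137", ]
  expect_equal(r1$AC, 7L)
  expect_equal(r1$AN, 251496L)
  expect_equal(r1$gene, "PEX7")
  expect_equal(r1$consequence, "stop_gained")
  expect_equal(r1$pos, 137150000L)
  expect_equal(r1$ref, "T"); expect_equal(r1$alt, "A")
  expect_equal(r1$clinical, "reported_pathogenic")
  expect_equal(r1$dataset, "US-TopMed")
  multi <- rec[rec$pos == 137151000L, ]
  expect_setequal(multi$AC, c(2L, 3L))
  expect_setequal(multi$alt, c("A", "C"))
})

test_that("inclusion rules fire in the documented precedence order", {
  cases <- list(
    # rule 5: concordant damaging missense is included
    list(variant_row(consequence = "missense", sift = "deleterious",
                     polyphen = "damaging_or_probably_damaging"),
         TRUE, "missense_concordant"),
    # rule 4: predicted LoF included regardless of predictions
    list(variant_row(consequence = "stop_gained", sift = "unknown",
                     polyphen = "unknown"),
         TRUE, "predicted_lof"),
    list(variant_row(consequence = "frameshift", sift = "unknown",
                     polyphen = "unknown"), TRUE, "predicted_lof"),
    list(variant_row(consequence = "splice_acceptor", sift = "unknown",
                     polyphen = "unknown"), TRUE, "predicted_lof"),
    list(variant_row(consequence = "start_lost", sift = "unknown",
                     polyphen = "unknown"), TRUE, "predicted_lof"),
    # rule 3: clinical pathogenic overrides discordant predictions
    list(variant_row(consequence = "missense", sift = "tolerated",
                     polyphen = "benign", clinical = "reported_pathogenic"),
         TRUE, "clinical"),
    # rule 2: clinical benign overrides concordant damaging predictions
    list(variant_row(consequence = "missense", sift = "deleterious",
                     polyphen = "damaging_or_probably_damaging",
                     clinical = "reported_benign"),
         FALSE, "excluded_benign"),
    # and overrides a LoF consequence too
    list(variant_row(consequence = "stop_gained", clinical = "reported_benign"),
         FALSE, "excluded_benign"),
    # rule 6: "both" requirement fails
    list(variant_row(consequence = "missense", sift = "deleterious",
                     polyphen = "benign"), FALSE, "excluded_discordant"),
    list(variant_row(consequence = "missense", sift = "unknown",
                     polyphen = "damaging_or_probably_damaging"),
         FALSE, "excluded_discordant"),
    # rule 7: non-canonical splice region is not auto-included
    list(variant_row(consequence = "splice_region", sift = "unknown",
                     polyphen = "unknown"), FALSE, "excluded_other"),
    list(variant_row(consequence = "inframe_indel"), FALSE, "excluded_other"),
    # uncertain clinical status falls through to predictions
    list(variant_row(consequence = "missense", clinical = "reported_uncertain"),
         TRUE, "missense_concordant"))
  for (case in cases) {
    call <- classifyVariants(validateVariantRecords(case[[1]]))
    expect_equal(call$included, case[[2]], info = case[[3]])
    expect_equal(call$rule_fired, case[[3]])
  }
})

test_that("a configured genomic interval restriction excludes outside variants", {
  rr <- list(PEX5 = list(chrom = "chr12", start = 7341600, end = 7350000))
  inside <- variant_row("in", gene = "PEX5", chrom = "chr12", pos = 7345000L,
                        consequence = "splice_acceptor", sift = "unknown",
                        polyphen = "unknown")
  outside <- variant_row("out", gene = "PEX5", chrom = "chr12", pos = 7360000L,
                         consequence = "stop_gained",
                         clinical = "reported_pathogenic")
  wrong_chrom <- variant_row("wc", gene = "PEX5", chrom = "chr11",
                             pos = 7345000L, consequence = "stop_gained")
  calls <- classifyVariants(variant_table(inside, outside, wrong_chrom), rr)
  expect_equal(calls$rule_fired, c("predicted_lof", "excluded_region",
                                   "excluded_region"))
  # region restriction outranks even a clinical pathogenic report
  expect_false(calls$included[2])
  # other genes are unrestricted
  other <- classifyVariants(variant_table(variant_row(pos = 1L)), rr)
  expect_true(other$included)
})

test_that("classification is deterministic and order-of-input independent", {
  set.seed(7)
  df <- do.call(rbind, lapply(1:20, function(i) {
    variant_row(paste0("v", i),
                consequence = sample(c("missense", "stop_gained",
                                       "splice_region"), 1),
                sift = sample(c("deleterious", "tolerated", "unknown"), 1),
                polyphen = sample(c("damaging_or_probably_damaging", "benign",
                                    "unknown"), 1),
                clinical = sample(c("reported_pathogenic", "reported_benign",
                                    "unreported"), 1))
  }))
  df <- validateVariantRecords(df)
  a <- classifyVariants(df)
  perm <- sample(nrow(df))
  b <- classifyVariants(df[perm, ])
  expect_equal(b$rule_fired[order(perm)], a$rule_fired)
  expect_equal(classifyVariants(df), a)
})

test_that("consequence-class summary partitions included mass per gene", {
  an <- 100000L
  df <- variant_table(
    variant_row("s1", consequence = "stop_gained", AC = 10L, AN = an),
    variant_row("m1", consequence = "missense", AC = 20L, AN = an),
    variant_row("m2", consequence = "missense", AC = 5L, AN = an),
    variant_row("f1", consequence = "frameshift", AC = 8L, AN = an),
    variant_row("f2", consequence = "frameshift", AC = 2L, AN = an),
    variant_row("x1", consequence = "missense", sift = "tolerated",
                polyphen = "benign", AC = 50L, AN = an))
  calls <- classifyVariants(df)
  summ <- consequenceClassSummary(df, calls)
  expect_equal(nrow(summ), 3L)
  # hand-computed per-class sums; the excluded discordant missense contributes
  # nothing
  expect_equal(summ$aggregate_af[summ$consequence == "stop_gained"], 10 / an)
  expect_equal(summ$aggregate_af[summ$consequence == "missense"], 25 / an)
  expect_equal(summ$aggregate_af[summ$consequence == "frameshift"], 10 / an)
  # class sums equal the gene aggregate from the allele-stats module
  agg <- aggregateGeneFrequency(df, calls, "PEX7", "US-TopMed")
  expect_equal(sum(summ$aggregate_af), agg$q_hat)
  # empty included set
  empty <- consequenceClassSummary(df, within(calls, included <- FALSE))
  expect_equal(nrow(empty), 0L)
})
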