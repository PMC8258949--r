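#' @importFrom stats qnorm rbinom rnorm rgamma setNames aggregate
#' @importFrom utils read.delim read.csv write.table
NULL

VARIANT_COLUMNS <- c("variant_id", "gene", "chrom", "pos", "ref", "alt",
                     "consequence", "sift", "polyphen", "clinical",
                     "AC", "AN", "dataset")

CONSEQUENCE_LEVELS <- c("missense", "stop_gained", "frameshift",
                        "splice_donor", "splice_acceptor", "splice_region",
                        "inframe_indel", "start_lost", "other")
LOF_CONSEQUENCES <- c("stop_gained", "frameshift", "splice_donor",
                      "splice_acceptor", "start_lost")
SIFT_LEVELS <- c("deleterious", "tolerated", "unknown")
POLYPHEN_LEVELS <- c("damaging_or_probably_damaging", "benign", "unknown")
CLINICAL_LEVELS <- c("reported_pathogenic", "reported_uncertain",
                     "reported_benign", "unreported")
INCLUSION_RULES <- c("clinical", "predicted_lof", "missense_concordant")
EXCLUSION_RULES <- c("excluded_benign", "excluded_discordant",
                     "excluded_region", "excluded_other")

#' Read a per-variant annotation/frequency table
#'
#' Ingests one record per variant x dataset. The TSV dialect is tab-separated
#' with a header row and columns `variant_id, gene, chrom, pos, ref, alt,
#' consequence, sift, polyphen, clinical, AC, AN, dataset` (gnomAD/TopMed
#' convention: AC = allele count, AN = allele number). The VCF dialect reads
#' `AC`/`AN` from INFO via \pkg{vcfR}; gene and annotation fields must then be
#' supplied through `annotation_sidecar`, joined on `variant_id`
#' (chrom-pos-ref-alt key or the VCF ID field when present).
#'
#' Multi-allelic VCF sites expand to one record per alt allele.
#'
#' @param path file path
#' @param dialect `"tsv"` or `"vcf"`
#' @param annotation_sidecar for `dialect = "vcf"`: data.frame or TSV path with
#'   columns `variant_id, gene, consequence, sift, polyphen, clinical`
#' @param dataset dataset label to stamp on VCF records (TSV carries its own)
#' @return data.frame of validated variant records
#' @export
readVariantTable <- function(path, dialect = c("tsv", "vcf"),
                             annotation_sidecar = NULL, dataset = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("variant file not found: %s", path))
  raw <- switch(dialect,
    tsv = read.delim(path, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE),
    vcf = read_variant_vcf(path, annotation_sidecar, dataset)
  )
  validateVariantRecords(raw, source = path)
}

read_variant_vcf <- function(path, annotation_sidecar, dataset) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the 'vcfR' package is required for dialect = 'vcf'")
  }
  if (is.null(dataset)) stop("dataset label required for VCF input")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ac <- vcfR::extract.info(vcf, "AC")
  an <- vcfR::extract.info(vcf, "AN")
  if (anyNA(ac) || anyNA(an)) stop("VCF records missing INFO AC or AN")
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    acs <- strsplit(ac[i], ",", fixed = TRUE)[[1]]
    if (length(acs) != length(alts)) {
      stop(sprintf("VCF record %s: %d ALT alleles but %d AC values",
                   fix$POS[i], length(alts), length(acs)))
    }
    id <- if (!is.na(fix$ID[i]) && nzchar(fix$ID[i]) && fix$ID[i] != ".") {
      rep(fix$ID[i], length(alts))
    } else {
      paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts, sep = "-")
    }
    data.frame(variant_id = id, chrom = fix$CHROM[i], pos = fix$POS[i],
               ref = fix$REF[i], alt = alts, AC = acs, AN = an[i],
               dataset = dataset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(annotation_sidecar)) {
    ann <- if (is.character(annotation_sidecar)) {
      read.delim(annotation_sidecar, sep = "\t", colClasses = "character")
    } else annotation_sidecar
    out <- merge(out, ann, by = "variant_id", all.x = TRUE, sort = FALSE)
  }
  for (col in c("gene", "consequence", "sift", "polyphen", "clinical")) {
    if (is.null(out[[col]])) out[[col]] <- NA_character_
  }
  out$sift[is.na(out$sift)] <- "unknown"
  out$polyphen[is.na(out$polyphen)] <- "unknown"
  out$clinical[is.na(out$clinical)] <- "unreported"
  out$consequence[is.na(out$consequence)] <- "other"
  out[, VARIANT_COLUMNS]
}

#' Validate variant records
#'
#' Enforces the record contract: mandatory columns, integer AC/AN,
#' 0 <= AC <= AN, AC/AN <= 0.5 (pathogenic alleles are minor alleles),
#' pos >= 1, known enumeration levels. Malformed rows raise row-numbered
#' errors.
#'
#' @param df data.frame of raw records
#' @param source label used in diagnostics
#' @return the validated data.frame with typed columns
#' @export
validateVariantRecords <- function(df, source = "variant table") {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing mandatory column(s): %s", source,
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[, VARIANT_COLUMNS]
  int_or_die <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) {
      stop(sprintf("%s: row %d: column '%s' is not an integer (value '%s')",
                   source, bad[1], col, x[bad[1]]))
    }
    as.integer(v)
  }
  df$pos <- int_or_die(df$pos, "pos")
  df$AC <- int_or_die(df$AC, "AC")
  df$AN <- int_or_die(df$AN, "AN")
  check_levels <- function(x, levels, col) {
    bad <- which(!x %in% levels)
    if (length(bad)) {
      stop(sprintf("%s: row %d: column '%s' has unknown value '%s'",
                   source, bad[1], col, x[bad[1]]))
    }
    x
  }
  df$consequence <- check_levels(df$consequence, CONSEQUENCE_LEVELS, "consequence")
  df$sift <- check_levels(df$sift, SIFT_LEVELS, "sift")
  df$polyphen <- check_levels(df$polyphen, POLYPHEN_LEVELS, "polyphen")
  df$clinical <- check_levels(df$clinical, CLINICAL_LEVELS, "clinical")
  if (any(df$pos < 1)) {
    stop(sprintf("%s: row %d: pos must be >= 1", source, which(df$pos < 1)[1]))
  }
  if (any(df$AN <= 0)) {
    stop(sprintf("%s: row %d: AN must be positive", source, which(df$AN <= 0)[1]))
  }
  bad <- which(df$AC < 0 | df$AC > df$AN)
  if (length(bad)) {
    stop(sprintf("%s: variant %s: AC (%d) outside [0, AN = %d]",
                 source, df$variant_id[bad[1]], df$AC[bad[1]], df$AN[bad[1]]))
  }
  bad <- which(df$AC / df$AN > 0.5)
  if (length(bad)) {
    stop(sprintf("%s: variant %s: allele frequency %.3g exceeds 0.5; records must be minor alleles",
                 source, df$variant_id[bad[1]], df$AC[bad[1]] / df$AN[bad[1]]))
  }
  rownames(df) <- NULL
  df
}

#' Classify variants for disease-model inclusion
#'
#' Applies the inclusion decision procedure to each record, in order:
#' \enumerate{
#'   \item outside the gene's configured genomic interval -> `excluded_region`
#'   \item clinically reported benign -> `excluded_benign`
#'   \item clinically reported pathogenic -> `clinical` (included)
#'   \item predicted loss of function (stop gained, frameshift, canonical
#'     splice donor/acceptor, start lost) -> `predicted_lof` (included)
#'   \item missense called deleterious by SIFT AND damaging (probably or
#'     possibly) by PolyPhen-2 -> `missense_concordant` (included)
#'   \item missense with discordant or unknown predictions -> `excluded_discordant`
#'   \item anything else (non-canonical splice region, inframe indel, ...) -> `excluded_other`
#' }
#' Clinical evidence outranks in-silico predictions in both directions;
#' non-canonical splice-region variants are never auto-included because
#' cryptic splicing outcomes are not reliably predictable.
#'
#' @param variants validated variant data.frame
#' @param region_restrictions named list, `gene -> list(chrom, start, end)`
#'   (1-based closed interval); genes absent from the list are unrestricted.
#'   Used e.g. to confine PEX5 to its PTS2-domain-encoding region.
#' @return data.frame with columns `variant_id, dataset, included, rule_fired`
#' @export
classifyVariants <- function(variants, region_restrictions = list()) {
  rule <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    rr <- region_restrictions[[v$gene]]
    rule[i] <-
      if (!is.null(rr) &&
          (v$chrom != rr$chrom || v$pos < rr$start || v$pos > rr$end)) {
        "excluded_region"
      } else if (v$clinical == "reported_benign") {
        "excluded_benign"
      } else if (v$clinical == "reported_pathogenic") {
        "clinical"
      } else if (v$consequence %in% LOF_CONSEQUENCES) {
        "predicted_lof"
      } else if (v$consequence == "missense" &&
                 v$sift == "deleterious" &&
                 v$polyphen == "damaging_or_probably_damaging") {
        "missense_concordant"
      } else if (v$consequence == "missense") {
        "excluded_discordant"
      } else {
        "excluded_other"
      }
  }
  data.frame(variant_id = variants$variant_id,
             dataset = variants$dataset,
             included = rule %in% INCLUSION_RULES,
             rule_fired = rule,
             stringsAsFactors = FALSE)
}

#' Aggregate allele frequency by molecular consequence class
#'
#' For included variants only, sums per-variant allele frequencies (AC/AN)
#' within each (gene, dataset, consequence) cell — the tabular analogue of a
#' mutational-landscape overview where mark size is proportional to the
#' aggregate allelic frequency of each consequence class.
#'
#' @param variants validated variant data.frame
#' @param calls output of [classifyVariants()] for the same records
#' @return data.frame `gene, dataset, consequence, aggregate_af, n_variants`
#' @export
consequenceClassSummary <- function(variants, calls) {
  stopifnot(nrow(variants) == nrow(calls))
  keep <- calls$included
  if (!any(keep)) {
    return(data.frame(gene = character(), dataset = character(),
                      consequence = character(), aggregate_af = numeric(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  }
  v <- variants[keep, ]
  af <- v$AC / v$AN
  agg <- aggregate(list(aggregate_af = af),
                   by = list(gene = v$gene, dataset = v$dataset,
                             consequence = v$consequence),
                   FUN = sum)
  cnt <- aggregate(list(n_variants = af),
                   by = list(gene = v$gene, dataset = v$dataset,
                             consequence = v$consequence),
                   FUN = length)
  out <- merge(agg, cnt, by = c("gene", "dataset", "consequence"))
  out$n_variants <- as.integer(out$n_variants)
  out <- out[order(out$gene, out$dataset, out$consequence), ]
  rownames(out) <- NULL
  out[, c("gene", "dataset", "consequence", "aggregate_af", "n_variants")]
}
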