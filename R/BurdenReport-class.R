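#' BurdenReport: per-gene, per-region disease-burden estimates
#'
#' The machine-readable end product of the pipeline: for every gene x region,
#' expected affected births per year at the anchor year, carrier counts, and
#' the current number of living patients, each as a (point, lo, hi) triplet;
#' per-region totals; and the age distribution of current patients in 5-year
#' bins up to the maximum lifespan. All slot values are unrounded — rounding
#' belongs to the formatting layer ([formatBurdenTable()]).
#'
#' @slot geneTable data.frame, one row per gene x region, columns
#'   `gene, region, q_hat, q_lo, q_hi, births, births_lo, births_hi,
#'   carriers, carriers_lo, carriers_hi, patients, patients_lo, patients_hi,
#'   birth_prev_100k`
#' @slot totals data.frame, one row per region, same burden columns (unrounded
#'   componentwise sums over genes)
#' @slot ageDistribution data.frame `region, age_bin, patients, patients_lo,
#'   patients_hi`
#' @slot metadata list: reference year, anchor year, confidence level,
#'   dataset-to-region mapping, strategy flags, provenance (excluded variants,
#'   gap-filled years)
#' @export
setClass("BurdenReport",
         representation(geneTable = "data.frame",
                        totals = "data.frame",
                        ageDistribution = "data.frame",
                        metadata = "list"))

setValidity("BurdenReport", function(object) {
  msgs <- character()
  burden_cols <- c("births", "births_lo", "births_hi",
                   "carriers", "carriers_lo", "carriers_hi",
                   "patients", "patients_lo", "patients_hi")
  if (!all(c("gene", "region", burden_cols) %in% names(object@geneTable))) {
    msgs <- c(msgs, "geneTable missing burden columns")
  }
  if (!all(c("region", burden_cols) %in% names(object@totals))) {
    msgs <- c(msgs, "totals missing burden columns")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn BurdenReport-class per-gene burden rows
#' @param report a BurdenReport
#' @export
geneTable <- function(report) report@geneTable

#' @describeIn BurdenReport-class per-region totals (unrounded)
#' @export
regionTotals <- function(report) report@totals

#' @describeIn BurdenReport-class current-patient age distribution
#' @export
ageDistribution <- function(report) report@ageDistribution

#' @describeIn BurdenReport-class run metadata and provenance
#' @export
reportMetadata <- function(report) report@metadata

setMethod("show", "BurdenReport", function(object) {
  cat("BurdenReport:", length(unique(object@geneTable$gene)), "gene(s) x",
      length(unique(object@geneTable$region)), "region(s)\n")
  cat("  reference year:", object@metadata$reference_year,
      "| anchor year:", object@metadata$anchor_year,
      "| confidence:", object@metadata$conf_level, "\n")
  for (i in seq_len(nrow(object@totals))) {
    t <- object@totals[i, ]
    cat(sprintf("  %s: %.1f births/yr (%.1f-%.1f), %.0f patients (%.0f-%.0f), %.0fk carriers\n",
                t$region, t$births, t$births_lo, t$births_hi,
                t$patients, t$patients_lo, t$patients_hi, t$carriers / 1000))
  }
})

#' Round half away from zero
#'
#' Reporting rounds with the convention of printed epidemiology tables
#' (0.5 rounds up), not banker's rounding.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
reportRound <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Round a confidence bound pair outward
#'
#' @param lo,hi bounds
#' @param digits decimal places
#' @return `c(lo, hi)` with lo floored and hi ceiled at `digits`
#' @export
roundOutward <- function(lo, hi, digits = 0) {
  f <- 10^digits
  c(lo = floor(lo * f) / f, hi = ceiling(hi * f) / f)
}

#' Sum per-gene burden rows into per-region totals
#'
#' Componentwise sums of the (point, lo, hi) burden columns within each
#' region. `mode = "unrounded"` (default) sums the raw values; rounding is
#' applied afterwards by the formatting layer. `mode = "sum_of_rounded"`
#' first rounds each gene row per the reporting conventions (births to 1
#' decimal, carriers to the nearest thousand, patients to integers) and then
#' sums — the convention some printed tables follow, kept as an explicit flag
#' because the two modes can differ by a unit in the last place.
#'
#' @param gene_table data.frame with `region` and the nine burden columns
#' @param mode `"unrounded"` or `"sum_of_rounded"`
#' @return data.frame of per-region totals
#' @export
burdenTotals <- function(gene_table, mode = c("unrounded", "sum_of_rounded")) {
  mode <- match.arg(mode)
  cols <- c("births", "births_lo", "births_hi",
            "carriers", "carriers_lo", "carriers_hi",
            "patients", "patients_lo", "patients_hi")
  cols <- intersect(cols, names(gene_table))
  gt <- gene_table
  if (mode == "sum_of_rounded") {
    for (cl in grep("^births", cols, value = TRUE)) gt[[cl]] <- reportRound(gt[[cl]], 1)
    for (cl in grep("^carriers", cols, value = TRUE)) gt[[cl]] <- reportRound(gt[[cl]] / 1000) * 1000
    for (cl in grep("^patients", cols, value = TRUE)) gt[[cl]] <- reportRound(gt[[cl]])
  }
  out <- aggregate(gt[cols], by = list(region = gt$region), FUN = sum)
  out[order(out$region), , drop = FALSE]
}

#' Combine regional totals into a multi-region estimate
#'
#' Componentwise sums across regions: the combined confidence range is the
#' sum of the regional bounds (valid because the regional estimates derive
#' from independent cohorts and every transform is monotone).
#'
#' Accepts either a list of [BurdenReport-class] objects (whose confidence
#' level and reference year must agree) or a data.frame of per-region totals
#' rows such as [regionTotals()] returns.
#'
#' @param x list of BurdenReports, or a totals data.frame
#' @return one-row data.frame of combined totals
#' @export
combineRegions <- function(x) {
  if (is.data.frame(x)) {
    totals <- x
  } else if (is.list(x) && all(vapply(x, is, logical(1), "BurdenReport"))) {
    meta <- lapply(x, function(r) r@metadata[c("conf_level", "reference_year")])
    if (length(unique(vapply(meta, function(m)
      paste(m$conf_level, m$reference_year), character(1)))) != 1L) {
      stop("cannot combine reports with mismatched confidence level or reference year")
    }
    totals <- do.call(rbind, lapply(x, regionTotals))
  } else {
    stop("x must be a totals data.frame or a list of BurdenReport objects")
  }
  cols <- setdiff(names(totals)[vapply(totals, is.numeric, logical(1))], "region")
  out <- as.data.frame(as.list(colSums(totals[cols])))
  cbind(region = "combined", out, stringsAsFactors = FALSE)
}

#' Format a burden table with the reporting conventions
#'
#' Births to one decimal, carriers to the nearest thousand (reported in
#' thousands), patients to the nearest integer; confidence bounds rounded
#' outward (floor the lower, ceil the upper). Because rows are rounded
#' independently, per-gene bounds may sum to slightly different values than
#' the rounded totals row — an arithmetic artifact of printing, noted here so
#' downstream readers do not chase it.
#'
#' @param tab geneTable or totals data.frame
#' @return data.frame of display values
#' @export
formatBurdenTable <- function(tab) {
  out <- data.frame(region = tab$region, stringsAsFactors = FALSE)
  if (!is.null(tab$gene)) out <- cbind(gene = tab$gene, out, stringsAsFactors = FALSE)
  out$births <- reportRound(tab$births, 1)
  out$births_lo <- floor(tab$births_lo * 10) / 10
  out$births_hi <- ceiling(tab$births_hi * 10) / 10
  out$carriers_thousands <- reportRound(tab$carriers / 1000)
  out$patients <- reportRound(tab$patients)
  out$patients_lo <- floor(tab$patients_lo)
  out$patients_hi <- ceiling(tab$patients_hi)
  out
}

#' Serialize a BurdenReport
#'
#' Writes `burden_report.tsv` (formatted gene rows plus totals),
#' `age_distribution.tsv` (long format: region, age_bin, expected patients),
#' and/or `burden_report.json` (the full unrounded report with metadata and
#' provenance).
#'
#' @param report a [BurdenReport-class]
#' @param out_dir output directory (created if absent)
#' @param format `"both"`, `"tsv"` or `"json"`
#' @return invisibly, the paths written
#' @export
writeBurdenReport <- function(report, out_dir, format = c("both", "tsv", "json")) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (format %in% c("both", "tsv")) {
    gt <- formatBurdenTable(geneTable(report))
    tot <- formatBurdenTable(regionTotals(report))
    tot <- cbind(gene = "TOTAL", tot, stringsAsFactors = FALSE)
    p <- file.path(out_dir, "burden_report.tsv")
    write.table(rbind(gt, tot), p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "age_distribution.tsv")
    write.table(ageDistribution(report), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  if (format %in% c("both", "json")) {
    p <- file.path(out_dir, "burden_report.json")
    jsonlite::write_json(
      list(gene_table = geneTable(report),
           totals = regionTotals(report),
           totals_sum_of_rounded = burdenTotals(geneTable(report), "sum_of_rounded"),
           age_distribution = ageDistribution(report),
           metadata = reportMetadata(report)),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
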