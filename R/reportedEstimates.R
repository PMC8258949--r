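#' Previously reported RCDP burden estimates
#'
#' Per-gene point estimates and 95% confidence ranges for annual affected
#' births, carriers (in thousands) and currently living patients in the US
#' and pooled EU5, as previously reported for the five RCDP genes (PEX5
#' restricted to its PTS2-domain-encoding region). Shipped as a plain-text
#' table so the report-aggregation arithmetic (totals, combined-region
#' ranges) can be exercised against published reference numbers.
#'
#' @param include_totals keep the published TOTAL rows (default) or return
#'   gene rows only
#' @return data.frame `gene, region, births, births_lo, births_hi,
#'   carriers_thousands, patients, patients_lo, patients_hi`
#' @export
reportedBurdenEstimates <- function(include_totals = TRUE) {
  path <- system.file("extdata", "reported_burden_estimates.tsv",
                      package = "recessiveBurden", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", header = TRUE)
  if (!include_totals) df <- df[df$gene != "TOTAL", ]
  rownames(df) <- NULL
  df
}
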