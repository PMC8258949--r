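#' Read a historic birth series
#'
#' TSV with columns `region, year, births` (one row per region-year,
#' non-negative integer births, unique years within region) — the shape of a
#' national-statistics live-birth extract.
#'
#' @param path TSV path
#' @return data.frame `region, year, births`
#' @export
readBirthSeries <- function(path) {
  if (!file.exists(path)) stop(sprintf("birth series file not found: %s", path))
  df <- read.delim(path, sep = "\t", header = TRUE)
  need <- c("region", "year", "births")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[, need]
  df$year <- as.integer(df$year)
  df$births <- as.numeric(df$births)
  if (any(is.na(df$year)) || any(is.na(df$births)) || any(df$births < 0)) {
    stop(sprintf("%s: years must be integers and births non-negative", path))
  }
  dup <- duplicated(df[, c("region", "year")])
  if (any(dup)) {
    stop(sprintf("%s: duplicate year %d for region %s", path,
                 df$year[dup][1], df$region[dup][1]))
  }
  df
}

#' Fill gaps in a single-region birth series
#'
#' Missing years within the requested range take the births of the nearest
#' available year (ties break to the earlier year), so absent early history —
#' common before 1970 in public series — is carried back deterministically.
#' Filled rows are flagged. Old-cohort contributions are negligible under the
#' mortality model, so the fill rule is low-stakes, but it must be explicit.
#'
#' @param births data.frame `year, births` (single region)
#' @param years integer vector of required years
#' @return data.frame `year, births, filled` covering exactly `years`
#' @export
fillBirthSeries <- function(births, years) {
  if (!nrow(births)) stop("cannot gap-fill an empty birth series")
  if (!length(years)) stop("empty year range")
  years <- sort(unique(as.integer(years)))
  idx <- match(years, births$year)
  filled <- is.na(idx)
  vals <- births$births[idx]
  if (any(filled)) {
    for (i in which(filled)) {
      d <- abs(births$year - years[i])
      nearest <- which(d == min(d))
      pick <- nearest[which.min(births$year[nearest])]
      vals[i] <- births$births[pick]
    }
  }
  data.frame(year = years, births = vals, filled = filled)
}

#' Expected affected births per year
#'
#' Applies the genotype prevalence q^2 to each year's live births:
#' I_y = q^2 * B_y, componentwise on (point, lo, hi). Genetic prevalence is
#' held constant over the historic window; births vary by year.
#'
#' @param genotype_prev genotype-prevalence triplet (from [genotypePrevalence()])
#' @param births data.frame `year, births` for one region (pre- or un-filled;
#'   gaps within `years` are filled via [fillBirthSeries()])
#' @param years integer years to cover
#' @return data.frame `year, births, filled, point, lo, hi`
#' @export
annualBirthIncidence <- function(genotype_prev, births, years) {
  gp <- assert_triplet(genotype_prev, "genotype_prev")
  if (!length(years)) stop("empty year range")
  b <- fillBirthSeries(births, years)
  b$point <- gp[["point"]] * b$births
  b$lo <- gp[["lo"]] * b$births
  b$hi <- gp[["hi"]] * b$births
  b
}

#' Birth prevalence per 100,000 births
#'
#' @param incidence expected affected births in a year
#' @param births_that_year live births that year (> 0)
#' @return rate per 100,000 births
#' @export
birthPrevalencePer100k <- function(incidence, births_that_year) {
  if (any(births_that_year <= 0)) stop("births_that_year must be positive")
  1e5 * incidence / births_that_year
}
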