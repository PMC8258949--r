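#' @import methods
NULL

#' MortalityTable: discrete annual-mortality life table
#'
#' Holds the age-specific annual mortality rates m_a (probability of dying
#' during the year of age a, conditional on surviving to a) for integer ages
#' 0..max_age, plus the hard lifespan cap: survival beyond `maxAge` is zero
#' regardless of the rates. Deaths occur at year boundaries — the model is an
#' ordinary discrete-time life table, matching "annual mortality rate per year
#' of life" data.
#'
#' @slot rates numeric vector of length `maxAge + 1`, each in [0, 1]
#' @slot maxAge last attainable age in completed years
#' @export
setClass("MortalityTable",
         representation(rates = "numeric", maxAge = "integer"))

setValidity("MortalityTable", function(object) {
  d <- validateMortalityRates(object@rates, object@maxAge)
  if (length(d)) paste(d, collapse = "; ") else TRUE
})

#' Construct a MortalityTable
#'
#' @param rates annual mortality rates for ages 0..max_age
#' @param max_age last attainable age (default inferred from `rates`)
#' @return a [MortalityTable-class] object
#' @export
MortalityTable <- function(rates, max_age = length(rates) - 1L) {
  new("MortalityTable", rates = as.numeric(rates), maxAge = as.integer(max_age))
}

#' Diagnose a candidate mortality-rate vector
#'
#' Returns human-readable diagnostics instead of throwing, so user-supplied
#' tables can be checked before construction: rate bounds, vector length, and
#' (for completeness) that the implied survival function is non-increasing.
#' An empty character vector means valid.
#'
#' @param rates candidate annual rate vector
#' @param max_age intended maximum age
#' @return character vector of diagnostics (empty when valid)
#' @export
validateMortalityRates <- function(rates, max_age) {
  d <- character()
  if (length(rates) != max_age + 1) {
    d <- c(d, sprintf("rates has length %d; expected max_age + 1 = %d",
                      length(rates), max_age + 1))
  }
  if (anyNA(rates)) {
    d <- c(d, "rates contain missing values")
  } else {
    bad <- which(rates < 0 | rates > 1)
    if (length(bad)) {
      d <- c(d, sprintf("rate out of [0, 1] at age %s",
                        paste(bad - 1, collapse = ", ")))
    } else {
      s <- cumprod(1 - rates)
      if (any(diff(c(1, s)) > 0)) d <- c(d, "survival function is increasing")
    }
  }
  d
}

#' @describeIn validateMortalityRates diagnostics for an existing table
#' @param table a [MortalityTable-class]
#' @export
validateMortalityTable <- function(table) {
  validateMortalityRates(table@rates, table@maxAge)
}

#' Default three-segment disease mortality table
#'
#' The packaged default encodes the published survival observations for RCDP:
#' a natural-history cohort put survival to the fifth birthday at about 75%,
#' mortality was modelled per year of life to age 14, a uniform 8%/yr applied
#' from age 15 onward, and no patient survives past age 34. Ages 0-4 share a
#' constant rate r0 solving (1 - r0)^5 = `survival_to_five`
#' (r0 ~ 0.0559 at the 75% calibration); ages 5-14 use `mid_childhood_rate`,
#' a smooth-decline default standing in for per-age rates the source cohort
#' does not publish; ages 15..`max_age` use `adult_rate`. Every segment is a
#' parameter — the model is data, not code — and a full per-age vector can be
#' supplied instead via [MortalityTable()] or [readMortalityTable()].
#'
#' @param survival_to_five cumulative survival to age 5 (calibration target)
#' @param mid_childhood_rate annual rate for ages 5-14
#' @param adult_rate annual rate from age 15 on
#' @param max_age last attainable age
#' @return a [MortalityTable-class]
#' @export
#' @examples
#' tab <- buildDefaultMortalityTable()
#' survivalToAge(tab, 5)   # 0.75 by construction
buildDefaultMortalityTable <- function(survival_to_five = 0.75,
                                       mid_childhood_rate = 0.02,
                                       adult_rate = 0.08,
                                       max_age = 34L) {
  stopifnot(survival_to_five > 0, survival_to_five <= 1, max_age >= 15)
  r0 <- 1 - survival_to_five^(1 / 5)
  MortalityTable(c(rep(r0, 5), rep(mid_childhood_rate, 10),
                   rep(adult_rate, max_age - 14)),
                 as.integer(max_age))
}

#' Read a mortality table from CSV
#'
#' Columns `age, annual_mortality_rate`; ages must form 0..max_age
#' contiguously.
#'
#' @param path CSV path
#' @return a [MortalityTable-class]
#' @export
readMortalityTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("mortality file not found: %s", path))
  df <- read.csv(path)
  need <- c("age", "annual_mortality_rate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[order(df$age), ]
  if (!identical(as.integer(df$age), seq(0L, nrow(df) - 1L))) {
    stop(sprintf("%s: ages must form a contiguous 0..max_age sequence", path))
  }
  MortalityTable(df$annual_mortality_rate, nrow(df) - 1L)
}

#' Survival function of a life table
#'
#' S(0) = 1; S(a) = prod_{k < a} (1 - m_k) for a <= max_age; the lifespan cap
#' forces S(a) = 0 for a > max_age even when the rates alone would permit
#' survival.
#'
#' @param table a [MortalityTable-class]
#' @param age integer age(s) in completed years, >= 0
#' @return survival probability (vectorized over `age`)
#' @export
setGeneric("survivalToAge", function(table, age) standardGeneric("survivalToAge"))

#' @rdname survivalToAge
setMethod("survivalToAge", "MortalityTable", function(table, age) {
  if (any(age < 0) || any(age != floor(age))) {
    stop("age must be a non-negative integer")
  }
  s <- c(1, cumprod(1 - table@rates))
  out <- ifelse(age > table@maxAge, 0, s[pmin(age, table@maxAge) + 1L])
  unname(out)
})

#' Age-specific mortality rates
#' @param table a [MortalityTable-class]
#' @return numeric vector m_0..m_maxAge
#' @export
setGeneric("mortalityRates", function(table) standardGeneric("mortalityRates"))

#' @rdname mortalityRates
setMethod("mortalityRates", "MortalityTable", function(table) table@rates)

#' Maximum attainable age
#' @param table a [MortalityTable-class]
#' @return integer
#' @export
setGeneric("maxAge", function(table) standardGeneric("maxAge"))

#' @rdname maxAge
setMethod("maxAge", "MortalityTable", function(table) table@maxAge)

setMethod("show", "MortalityTable", function(object) {
  s <- survivalToAge(object, 0:(object@maxAge + 1L))
  cat("MortalityTable: ages 0-", object@maxAge, " (survival capped at max age)\n",
      sep = "")
  cat(sprintf("  S(5) = %.4f, S(15) = %.4f, S(%d) = %.4f, S(%d) = 0\n",
              s[6], s[16], object@maxAge, s[object@maxAge + 1L],
              object@maxAge + 1L))
  cat(sprintf("  expected lifetime (sum of S(a), a = 0..%d): %.2f years\n",
              object@maxAge, sum(s[seq_len(object@maxAge + 1L)])))
})
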