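#' Genotype (affected) prevalence under Hardy-Weinberg equilibrium
#'
#' Squares the aggregate pathogenic allele frequency q componentwise:
#' q^2 is the probability that a conceptus carries a disease genotype. With
#' q the sum of per-variant frequencies in one gene, q^2 counts homozygous
#' and compound-heterozygous pathogenic genotypes alike, since
#' sum(q_i)^2 = sum(q_i^2) + sum_{i != j} q_i q_j under random mating.
#' Squaring is monotone on [0, 1], so the bounds triplet remains valid.
#'
#' @param q allele-frequency triplet from [estTriplet()]
#' @return genotype-prevalence triplet
#' @export
genotypePrevalence <- function(q) {
  q <- assert_triplet(q, "q")
  if (q[["hi"]] > 1) stop("allele frequency cannot exceed 1")
  estTriplet(q[["point"]]^2, q[["lo"]]^2, q[["hi"]]^2, max = 1)
}

#' Carrier frequency under Hardy-Weinberg equilibrium
#'
#' 2 p q = 2 (1 - q) q, componentwise. The transform is only monotone for
#' q <= 0.5, so bounds cannot be propagated componentwise beyond that; the
#' pathogenic alleles modelled here are all rare (q << 0.01) and a triplet
#' with hi > 0.5 is rejected as a domain error.
#'
#' @param q allele-frequency triplet
#' @return carrier-frequency triplet
#' @export
carrierFrequency <- function(q) {
  q <- assert_triplet(q, "q")
  if (q[["hi"]] > 0.5) {
    stop("carrier frequency bounds require q <= 0.5 (2pq is non-monotone beyond)")
  }
  f <- function(x) 2 * (1 - x) * x
  estTriplet(f(q[["point"]]), f(q[["lo"]]), f(q[["hi"]]), max = 1)
}

#' Expected carrier count in a population
#'
#' @param carrier_freq carrier-frequency triplet
#' @param population_size number of individuals (> 0)
#' @return count triplet (unrounded; reporting rounds to the nearest thousand)
#' @export
carriersInPopulation <- function(carrier_freq, population_size) {
  cf <- assert_triplet(carrier_freq, "carrier_freq")
  stopifnot(length(population_size) == 1L, population_size > 0)
  estTriplet(cf[["point"]] * population_size,
             cf[["lo"]] * population_size,
             cf[["hi"]] * population_size)
}
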