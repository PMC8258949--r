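#' Modified Wald (Agresti-Coull) binomial confidence interval
#'
#' Adds z^2/2 pseudo-successes and pseudo-failures before applying the Wald
#' construction: with z the standard-normal quantile at (1 + conf_level)/2,
#' p~ = (x + z^2/2) / (n + z^2) and half-width z * sqrt(p~ (1 - p~) / (n + z^2)).
#' Bounds are clamped to [0, 1] after construction; clamping is flagged in the
#' `clamped` attribute. `z_convention = "plus2"` uses z = 2 (the textbook
#' "add two successes and two failures" statement of the method), available
#' because the method is often cited that way; the exact quantile is the
#' default.
#'
#' @param x successes (non-negative integer, <= n)
#' @param n trials (positive)
#' @param conf_level confidence level in (0, 1)
#' @param z_convention `"exact"` (normal quantile) or `"plus2"` (z = 2)
#' @return named numeric `c(lo, hi)` with attribute `clamped` (logical pair)
#' @export
#' @examples
#' modifiedWaldInterval(5, 10000)
modifiedWaldInterval <- function(x, n, conf_level = 0.95,
                                 z_convention = c("exact", "plus2")) {
  z_convention <- match.arg(z_convention)
  stopifnot(length(x) == 1L, length(n) == 1L, length(conf_level) == 1L)
  if (is.na(x) || is.na(n) || n <= 0 || x < 0 || x > n) {
    stop(sprintf("modified Wald interval needs 0 <= x <= n with n > 0; got x = %s, n = %s",
                 format(x), format(n)))
  }
  if (!(conf_level > 0 && conf_level < 1)) {
    stop("conf_level must lie strictly between 0 and 1")
  }
  z <- if (z_convention == "exact") qnorm((1 + conf_level) / 2) else 2
  n_adj <- n + z^2
  p_adj <- (x + z^2 / 2) / n_adj
  hw <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  raw <- c(lo = p_adj - hw, hi = p_adj + hw)
  out <- c(lo = max(0, raw[["lo"]]), hi = min(1, raw[["hi"]]))
  attr(out, "clamped") <- c(lo = raw[["lo"]] < 0, hi = raw[["hi"]] > 1)
  out
}

#' Pool pathogenic allele counts into a per-gene aggregate frequency
#'
#' The aggregate pathogenic allele frequency is the sum of per-variant allele
#' frequencies over included variants: q_hat = sum(AC_i / AN_i). Because
#' allele numbers differ by site, the confidence interval is built on an
#' effective binomial experiment chosen by `pool_strategy`:
#' \describe{
#'   \item{effective_mean}{x = round(q_hat * n_bar), n = n_bar = mean AN over
#'     included sites. Recovers the single-site interval exactly; the default.}
#'   \item{min_an}{as above with n = min AN — conservative (widest interval).}
#'   \item{per_variant_sum}{sum of per-variant interval bounds, clamped; the
#'     most conservative aggregation, kept to make the pooling ambiguity of
#'     multi-site aggregation explicit rather than silent.}
#' }
#'
#' A gene with no included variants is a valid empty aggregate (q_hat = 0,
#' CI from x = 0 at the best available allele number): genes genuinely absent
#' from a cohort occur in real extracts.
#'
#' @param variants validated variant data.frame
#' @param calls output of [classifyVariants()]
#' @param gene gene symbol
#' @param dataset dataset label
#' @param conf_level confidence level
#' @param pool_strategy see Details
#' @param z_convention passed to [modifiedWaldInterval()]
#' @param fallback_an allele number used for the empty-aggregate interval when
#'   the dataset itself carries no records to take a mean over
#' @return one-row data.frame: `gene, dataset, n_variants, pooled_ac,
#'   pooled_an, q_hat, q_lo, q_hi, clamped_lo, clamped_hi`
#' @export
aggregateGeneFrequency <- function(variants, calls, gene, dataset,
                                   conf_level = 0.95,
                                   pool_strategy = c("effective_mean", "min_an",
                                                     "per_variant_sum"),
                                   z_convention = c("exact", "plus2"),
                                   fallback_an = 250000) {
  pool_strategy <- match.arg(pool_strategy)
  z_convention <- match.arg(z_convention)
  stopifnot(nrow(variants) == nrow(calls))
  sel <- variants$gene == gene & variants$dataset == dataset & calls$included
  v <- variants[sel, ]
  n_var <- nrow(v)
  if (n_var == 0L) {
    an_pool <- variants$AN[variants$gene == gene & variants$dataset == dataset]
    if (!length(an_pool)) an_pool <- variants$AN[variants$dataset == dataset]
    eff_n <- if (length(an_pool)) mean(an_pool) else fallback_an
    ci <- modifiedWaldInterval(0, eff_n, conf_level, z_convention)
    return(data.frame(gene = gene, dataset = dataset, n_variants = 0L,
                      pooled_ac = 0L, pooled_an = eff_n,
                      q_hat = 0, q_lo = ci[["lo"]], q_hi = ci[["hi"]],
                      clamped_lo = attr(ci, "clamped")[["lo"]],
                      clamped_hi = attr(ci, "clamped")[["hi"]],
                      stringsAsFactors = FALSE))
  }
  q_hat <- sum(v$AC / v$AN)
  if (pool_strategy == "per_variant_sum") {
    per <- lapply(seq_len(n_var), function(i)
      modifiedWaldInterval(v$AC[i], v$AN[i], conf_level, z_convention))
    lo <- min(q_hat, sum(vapply(per, `[[`, numeric(1), "lo")))
    hi <- min(1, sum(vapply(per, `[[`, numeric(1), "hi")))
    clamped <- c(lo = FALSE, hi = sum(vapply(per, `[[`, numeric(1), "hi")) > 1)
  } else {
    eff_n <- if (pool_strategy == "effective_mean") mean(v$AN) else min(v$AN)
    x <- round(q_hat * eff_n)
    ci <- modifiedWaldInterval(x, eff_n, conf_level, z_convention)
    lo <- ci[["lo"]]; hi <- ci[["hi"]]
    clamped <- attr(ci, "clamped")
  }
  data.frame(gene = gene, dataset = dataset, n_variants = n_var,
             pooled_ac = sum(v$AC),
             pooled_an = if (pool_strategy == "min_an") min(v$AN) else mean(v$AN),
             q_hat = q_hat, q_lo = min(lo, q_hat), q_hi = max(hi, q_hat),
             clamped_lo = unname(clamped["lo"]), clamped_hi = unname(clamped["hi"]),
             stringsAsFactors = FALSE)
}
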