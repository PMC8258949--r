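#' Point estimate with confidence bounds
#'
#' Confidence ranges are carried through every model stage as an ordered
#' triplet (point, lo, hi). Every downstream transform (squaring, 2pq on
#' [0, 0.5], linear scaling, summation) is monotone, so bounds propagate
#' componentwise: lo with lo, hi with hi.
#'
#' @param point point estimate
#' @param lo lower confidence bound
#' @param hi upper confidence bound
#' @param max upper admissible value (1 for frequencies, Inf for counts)
#' @return named numeric vector `c(point, lo, hi)`
#' @export
#' @examples
#' estTriplet(0.001764, 0.0015, 0.0021)
estTriplet <- function(point, lo, hi, max = Inf) {
  stopifnot(length(point) == 1L, length(lo) == 1L, length(hi) == 1L)
  if (anyNA(c(point, lo, hi))) stop("triplet components must be non-missing")
  if (!(0 <= lo && lo <= point && point <= hi && hi <= max)) {
    stop(sprintf("invalid triplet ordering: need 0 <= lo <= point <= hi <= %s, got (%g, %g, %g)",
                 format(max), point, lo, hi))
  }
  c(point = unname(point), lo = unname(lo), hi = unname(hi))
}

is_triplet <- function(x) {
  is.numeric(x) && length(x) == 3L && !anyNA(x) &&
    x[["lo"]] <= x[["point"]] && x[["point"]] <= x[["hi"]] && x[["lo"]] >= 0
}

assert_triplet <- function(x, what = "value") {
  if (!is.numeric(x) || length(x) != 3L ||
      is.null(names(x)) || !all(c("point", "lo", "hi") %in% names(x))) {
    stop(sprintf("%s must be a named (point, lo, hi) triplet; see estTriplet()", what))
  }
  estTriplet(x[["point"]], x[["lo"]], x[["hi"]])
}
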