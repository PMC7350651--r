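#' Convolve two mass-shift distributions
#'
#' A mass distribution is a plain numeric vector of probabilities indexed by
#' integer mass shift 0..k (index 1 is the monoisotopic peak). Convolution
#' gives the distribution of the sum of two independent mass shifts,
#' truncated at `max_shift`. Truncation never renormalizes: dropped tail
#' mass is recoverable as `1 - sum(result)`, which is what correction-matrix
#' columns require.
#'
#' @param a,b Numeric probability vectors (shift 0..length-1).
#' @param max_shift Highest shift retained (>= 0).
#' @return Numeric vector of length `max_shift + 1`,
#'   `result[k] = sum_i a[i] * b[k - i]`.
#' @export
#' @examples
#' convolve_dist(c(0.5, 0.5), c(0.5, 0.5), 2)  # binomial: 0.25 0.5 0.25
convolve_dist <- function(a, b, max_shift = length(a) + length(b) - 2L) {
  stopifnot(max_shift >= 0L)
  out <- numeric(max_shift + 1L)
  na <- length(a)
  for (i in seq_len(na)) {
    ai <- a[i]
    if (ai == 0) next
    # shifts i-1 (from a) + 0..length(b)-1 (from b)
    jmax <- min(length(b), max_shift + 2L - i)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + ai * b[seq_len(jmax)]
  }
  out
}

#' Theoretical natural-abundance spectrum of a composition
#'
#' Convolves each element's natural isotope pattern, raised to its atom
#' count, into the mass-shift distribution of the whole molecule or
#' fragment, truncated at `max_shift`. The empty composition yields `1`
#' (all mass at the monoisotopic peak).
#'
#' @param comp An [element_composition] (or a formula string, parsed on the
#'   fly).
#' @param max_shift Highest mass shift retained.
#' @return Numeric probability vector of length `max_shift + 1`. Sums to
#'   <= 1; mass beyond `max_shift` is truncated, not redistributed.
#' @export
#' @examples
#' composition_spectrum("C2", 2)
composition_spectrum <- function(comp, max_shift) {
  if (is.character(comp)) comp <- parse_formula(comp)
  stopifnot(inherits(comp, "element_composition"), max_shift >= 0L)
  spec <- 1
  for (sym in names(comp)) {
    dense <- pattern_dense(natural_pattern(sym), max_shift)
    pow <- element_power(dense, comp[[sym]], max_shift)
    spec <- convolve_dist(spec, pow, max_shift)
  }
  if (length(spec) < max_shift + 1L) {
    spec <- c(spec, numeric(max_shift + 1L - length(spec)))
  }
  spec
}

# dense ^ n under truncated convolution, by exponentiation-by-squaring
element_power <- function(dense, n, max_shift) {
  result <- 1
  base <- dense
  while (n > 0L) {
    if (n %% 2L == 1L) result <- convolve_dist(result, base, max_shift)
    n <- n %/% 2L
    if (n > 0L) base <- convolve_dist(base, base, max_shift)
  }
  if (length(result) < max_shift + 1L) {
    result <- c(result, numeric(max_shift + 1L - length(result)))
  }
  result
}
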