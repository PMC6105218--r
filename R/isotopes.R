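# Isotope pattern simulation, aggregated per nominal-mass bin.
#
# For each element the distribution of (nominal shift, exact mass shift)
# contributed by n atoms is built by convolving the single-atom isotope
# distribution n times, truncated at the requested number of bins; the
# per-element distributions are then convolved across elements. Bin k keeps
# the total probability and the probability-weighted mean exact-mass shift,
# so a "M+2" bin dominated by 37Cl reports a different mass shift than one
# dominated by two 13C. Fine structure within a bin is not resolved.

# cache of element^count distributions, keyed by "<element><count>:<bins>"
.ww_iso_cache <- new.env(parent = emptyenv())

# distribution of one atom of `element`: prob + weighted mass per shift bin
.iso_atom_dist <- function(element, n_bins) {
  iso <- .ww_elements[[element]]
  shift <- iso$nominal - iso$nominal[1L]
  p <- numeric(n_bins); w <- numeric(n_bins)
  keep <- shift < n_bins
  p[shift[keep] + 1L] <- iso$abundance[keep]
  w[shift[keep] + 1L] <- iso$abundance[keep] * (iso$mass[keep] - iso$mass[1L])
  list(p = p, w = w)
}

# convolve two (prob, weighted-mass) states, truncating at n_bins
.iso_convolve <- function(a, b, n_bins) {
  p <- numeric(n_bins); w <- numeric(n_bins)
  for (s in seq_len(n_bins)) {
    idx <- seq_len(s)
    p[s] <- sum(a$p[idx] * b$p[s + 1L - idx])
    w[s] <- sum(a$w[idx] * b$p[s + 1L - idx] + a$p[idx] * b$w[s + 1L - idx])
  }
  list(p = p, w = w)
}

.iso_element_dist <- function(element, count, n_bins) {
  key <- paste0(element, count, ":", n_bins)
  hit <- .ww_iso_cache[[key]]
  if (!is.null(hit)) return(hit)
  atom <- .iso_atom_dist(element, n_bins)
  # binary exponentiation keeps deep caches small for large counts
  res <- list(p = c(1, numeric(n_bins - 1L)), w = numeric(n_bins))
  base <- atom; n <- count
  while (n > 0L) {
    if (n %% 2L == 1L) res <- .iso_convolve(res, base, n_bins)
    n <- n %/% 2L
    if (n > 0L) base <- .iso_convolve(base, base, n_bins)
  }
  .ww_iso_cache[[key]] <- res
  res
}

#' Simulate the aggregated isotope pattern of a molecule
#'
#' Returns the relative abundances of the M, M+1, ... M+(n_peaks-1) nominal
#' isotopologue bins, scaled so the monoisotopic peak is 100, together with
#' the abundance-weighted exact mass shift of each bin.
#'
#' @param f Formula of the neutral molecule (the pattern of a protonated or
#'   deprotonated species differs negligibly for the +-H adducts).
#' @param n_peaks Number of bins to report (>= 1), default 3 (M, M+1, M+2).
#' @return A data.frame of class `ww_isotope_pattern` with columns
#'   `shift` (integer nominal shift), `mass_shift` (Da from monoisotopic)
#'   and `abundance` (% of the monoisotopic peak; first row is 100).
#' @examples
#' isotope_pattern("C6H6")
#' isotope_pattern("C12H19Cl3O8")  # chlorinated: prominent M+2
#' @export
isotope_pattern <- function(f, n_peaks = 3L) {
  f <- parse_formula(f)
  n_peaks <- as.integer(n_peaks)
  if (is.na(n_peaks) || n_peaks < 1L) stop("n_peaks must be >= 1")
  if (!length(f)) stop("cannot simulate the isotope pattern of an empty formula")
  state <- list(p = c(1, numeric(n_peaks - 1L)), w = numeric(n_peaks))
  for (e in names(f))
    state <- .iso_convolve(state, .iso_element_dist(e, f[[e]], n_peaks), n_peaks)
  keep <- state$p > 0
  out <- data.frame(
    shift = (seq_len(n_peaks) - 1L)[keep],
    mass_shift = ifelse(state$p[keep] > 0, state$w[keep] / state$p[keep], 0),
    abundance = state$p[keep] / state$p[1L] * 100
  )
  class(out) <- c("ww_isotope_pattern", "data.frame")
  out
}
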