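# Independent oracles used to validate the package's implementations.
# Both deliberately use different algorithms from the package code paths.

# all compositions of n identical atoms over k isotope slots
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n))
  do.call(rbind, lapply(0:n, function(i) {
    cbind(i, .compositions(n - i, k - 1L))
  }))
}

# exhaustive isotopologue enumeration: every isotope assignment per element
# via multinomial compositions, probabilities multiplied across elements,
# binned by nominal mass shift -- no truncation until the final head()
oracle_isotope_pattern <- function(formula, n_peaks = 3L) {
  f <- parse_formula(formula)
  et <- element_table()
  per_el <- lapply(names(f), function(e) {
    iso <- et[[e]]
    parts <- .compositions(f[[e]], nrow(iso))
    data.frame(
      shift = as.vector(parts %*% (iso$nominal - iso$nominal[1L])),
      prob = apply(parts, 1L, function(v) stats::dmultinom(v, prob = iso$abundance))
    )
  })
  agg <- Reduce(function(a, b) {
    g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    stats::aggregate(
      prob ~ shift,
      data.frame(shift = a$shift[g$i] + b$shift[g$j],
                 prob = a$prob[g$i] * b$prob[g$j]),
      sum)
  }, per_el)
  agg <- agg[order(agg$shift), ]
  utils::head(
    data.frame(shift = agg$shift,
               abundance = agg$prob / agg$prob[1L] * 100),
    n_peaks)
}

# naive grid-search formula enumeration over CHNO bounds
oracle_enumerate <- function(mass, tol_ppm, bounds) {
  et <- element_table()
  grid <- expand.grid(lapply(bounds, function(b) 0:b))
  m <- as.matrix(grid) %*%
    vapply(names(bounds), function(e) et[[e]]$mass[1L], numeric(1))
  keep <- abs((mass - m) / mass * 1e6) <= tol_ppm & m > 0
  apply(grid[keep, , drop = FALSE], 1L, function(v) {
    format_formula(stats::setNames(as.integer(v), names(bounds))[v > 0])
  })
}

# small jitter-free campaign configuration shared by several tests
tiny_preset <- function(seed = 1L, n_background = 30, ...) {
  wwtp_preset(seed = seed, n_background = n_background, ...)
}
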