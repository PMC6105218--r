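# Sample-level summaries: matrix effects, stage-wise removal statistics,
# and mass / retention-time distributions of the detected chemical species.

#' Matrix effect percentage
#'
#' `ME% = (A_matrix / A_solvent - 1) * 100`. Negative values indicate ion
#' suppression by co-extracted matrix, positive values signal enhancement.
#' `a_matrix` is expected to be background-subtracted by the caller (the
#' analyte signal already present in the unspiked extract removed).
#'
#' @param a_matrix Peak area of the analyte spiked into matrix extract.
#' @param a_solvent Peak area of the analyte in pure solvent (> 0).
#' @return ME in percent (vectorized).
#' @examples
#' matrix_effect(80730, 100000)   # -19.27 (suppression)
#' matrix_effect(112470, 100000)  # +12.47 (enhancement)
#' @export
matrix_effect <- function(a_matrix, a_solvent) {
  if (any(a_solvent <= 0)) stop("solvent peak area must be positive")
  (a_matrix / a_solvent - 1) * 100
}

#' Matrix-effect table from replicated area pairs
#'
#' Replicate areas are averaged per compound before the ME formula is
#' applied; the per-replicate ME standard deviation is reported alongside.
#'
#' @param pairs data.frame with columns `compound`, `a_matrix`, `a_solvent`
#'   (one row per replicate), e.g. from [generate_matrix_effect_set()].
#' @return data.frame: `compound`, `a_matrix`, `a_solvent` (means), `me`,
#'   `me_sd`, `n`.
#' @export
matrix_effect_table <- function(pairs) {
  stopifnot(all(c("compound", "a_matrix", "a_solvent") %in% names(pairs)))
  res <- lapply(split(pairs, pairs$compound), function(g) {
    data.frame(compound = g$compound[1L],
               a_matrix = mean(g$a_matrix), a_solvent = mean(g$a_solvent),
               me = matrix_effect(mean(g$a_matrix), mean(g$a_solvent)),
               me_sd = stats::sd(matrix_effect(g$a_matrix, g$a_solvent)),
               n = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$compound), ]
}

#' Stage-wise removal summary
#'
#' Removal between consecutive treatment stages computed from feature
#' counts: `100 * (1 - count_after / count_before)`, plus the cumulative
#' removal relative to the first (raw) stage. A zero count in the reference
#' stage makes the percentage undefined (NA).
#'
#' @param counts Named numeric vector of feature counts, in treatment
#'   order (>= 2 stages), or a named list of feature tables whose row
#'   counts are used.
#' @return data.frame: `stage`, `count`, `removal_pct` (vs previous stage),
#'   `cumulative_removal_pct` (vs first stage).
#' @examples
#' removal_rates(c(hall_of_separators = 1000, secondary_settlement = 200,
#'                 effluent = 160))
#' @export
removal_rates <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts))
    counts <- vapply(counts, nrow, numeric(1))
  if (length(counts) < 2L) stop("at least two stages are required")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- length(counts)
  prev <- c(NA, counts[-n])
  data.frame(
    stage = if (is.null(names(counts))) paste0("stage", seq_len(n))
            else names(counts),
    count = as.numeric(counts),
    removal_pct = ifelse(is.na(prev) | prev == 0, NA,
                         100 * (1 - counts / prev)),
    cumulative_removal_pct = if (counts[1L] == 0) NA
      else c(NA, 100 * (1 - counts[-1L] / counts[1L])),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Mass and retention-time profile of a feature set
#'
#' Bins features on a 2-D neutral-mass x retention-time grid and into the
#' three conventional molecular-weight classes: low (100-500 Da), medium
#' (500-1000 Da) and high (>= 1000 Da); bins are half-open `[lo, hi)`.
#'
#' @param features Feature table with `neutral_mass` and `rt` columns (an
#'   empty table yields all-zero histograms).
#' @param mass_breaks,rt_breaks Grid breakpoints for the 2-D histogram.
#' @return List with `mass_class` (named counts for the three classes;
#'   masses below 100 Da are not classed) and `grid` (matrix of counts,
#'   mass bins x RT bins).
#' @examples
#' mass_rt_profile(data.frame(neutral_mass = c(300, 499.9, 500), rt = 1:3))
#' @export
mass_rt_profile <- function(features,
                            mass_breaks = seq(100, 1700, by = 100),
                            rt_breaks = seq(0, 25, by = 1)) {
  mass <- features$neutral_mass
  rt <- features$rt
  cls <- c(`low_100_500` = sum(mass >= 100 & mass < 500),
           `medium_500_1000` = sum(mass >= 500 & mass < 1000),
           `high_1000_plus` = sum(mass >= 1000))
  mi <- findInterval(mass, mass_breaks)
  ri <- findInterval(rt, rt_breaks)
  grid <- matrix(0L, nrow = length(mass_breaks) - 1L,
                 ncol = length(rt_breaks) - 1L,
                 dimnames = list(
                   paste0("m", mass_breaks[-length(mass_breaks)]),
                   paste0("rt", rt_breaks[-length(rt_breaks)])))
  inside <- mi >= 1 & mi < length(mass_breaks) & ri >= 1 & ri < length(rt_breaks)
  if (any(inside)) {
    tab <- table(factor(mi[inside], levels = seq_len(nrow(grid))),
                 factor(ri[inside], levels = seq_len(ncol(grid))))
    grid <- grid + as.matrix(tab)
    dimnames(grid) <- list(paste0("m", mass_breaks[-length(mass_breaks)]),
                           paste0("rt", rt_breaks[-length(rt_breaks)]))
  }
  list(mass_class = cls, grid = grid)
}
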