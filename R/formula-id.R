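# Candidate molecular-formula generation and the identification gates:
# Seven Golden Rules filtering, the 2 ppm mass-accuracy window, the 5%
# absolute isotope-ratio deviation gate, and a composite score gate.

#' Identification criteria
#'
#' Thresholds of the three conjunctive identification gates plus the
#' golden-rules parameters. Defaults: 2 ppm mass accuracy, 5% absolute
#' isotope-ratio deviation, score > 98%, H/C within 0.2-3.1 and the
#' standard heteroatom/carbon caps.
#'
#' @param max_ppm Maximum absolute mass error (ppm).
#' @param max_iso_dev Maximum absolute isotope-ratio deviation (percentage
#'   points).
#' @param min_score Minimum composite score (%), exclusive.
#' @param hc_range H/C ratio bounds.
#' @param ratio_caps Named caps on heteroatom/C ratios.
#' @param element_bounds Optional named max-count vector overriding the
#'   mass-windowed rule-1 defaults (see [golden_rule_bounds()]).
#' @param n_iso_peaks Isotope bins compared by the isotope gate.
#' @return A list of class `ww_id_criteria`.
#' @export
id_criteria <- function(max_ppm = 2, max_iso_dev = 5, min_score = 98,
                        hc_range = c(0.2, 3.1),
                        ratio_caps = c(N = 1.3, O = 1.2, P = 0.3,
                                       S = 0.8, Cl = 0.8),
                        element_bounds = NULL, n_iso_peaks = 3L) {
  stopifnot(max_ppm > 0, max_iso_dev > 0, min_score > 0, min_score <= 100,
            length(hc_range) == 2L, all(hc_range > 0), all(ratio_caps > 0))
  structure(list(max_ppm = max_ppm, max_iso_dev = max_iso_dev,
                 min_score = min_score, hc_range = hc_range,
                 ratio_caps = ratio_caps, element_bounds = element_bounds,
                 n_iso_peaks = as.integer(n_iso_peaks)),
            class = "ww_id_criteria")
}

#' Element-count bounds by neutral-mass window
#'
#' The rule-1 maximum element counts, widening with mass: below 500 Da,
#' 500-1000 Da, and above.
#'
#' @param mass Neutral mass (Da).
#' @return Named integer vector of maximum counts.
#' @export
golden_rule_bounds <- function(mass) {
  w <- findInterval(mass, c(0, 500, 1000))
  rbind(c(C = 29, H = 72, N = 10, O = 18, P = 4, S = 3, Cl = 8),
        c(C = 66, H = 126, N = 25, O = 27, P = 6, S = 8, Cl = 11),
        c(C = 115, H = 236, N = 32, O = 63, P = 6, S = 14, Cl = 12))[w, ]
}

#' Enumerate candidate formulas within a mass window
#'
#' Exhaustive search over the bounded element lattice: every formula whose
#' monoisotopic mass lies within `tol_ppm` of `mass` and whose element
#' counts respect `bounds` is returned. Depth-first over elements ordered
#' by decreasing mass with running-mass pruning; hydrogen is solved in
#' closed form at the bottom, so the search cost is independent of the
#' hydrogen bound.
#'
#' @param mass Target neutral monoisotopic mass (Da, > 0).
#' @param tol_ppm Window half-width (ppm, > 0).
#' @param bounds Named vector of maximum element counts (elements absent
#'   from `bounds` are not used). Defaults to [golden_rule_bounds()].
#' @return data.frame (`formula`, `mass`, `ppm`) sorted by absolute ppm
#'   error; zero rows when nothing fits.
#' @examples
#' enumerate_formulas(236.09496, 2, c(C = 20, H = 30, N = 5, O = 5))
#' @export
enumerate_formulas <- function(mass, tol_ppm, bounds = golden_rule_bounds(mass)) {
  if (tol_ppm <= 0) stop("tolerance must be positive")
  if (mass <= 0) stop("mass must be positive")
  delta <- mass * tol_ppm * 1e-6
  lo <- mass - delta; hi <- mass + delta
  bounds <- bounds[bounds > 0]
  max_h <- if ("H" %in% names(bounds)) as.integer(bounds[["H"]]) else 0L
  els <- setdiff(names(bounds), "H")
  unknown <- setdiff(els, names(.ww_elements))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  emass <- vapply(els, function(e) .ww_elements[[e]]$mass[1L], numeric(1))
  ord <- order(-emass)
  els <- els[ord]; emass <- emass[ord]
  m_h <- .ww_elements$H$mass[1L]
  # max additional mass attainable from elements i..end (plus all hydrogens)
  suffix <- rev(cumsum(rev(emass * bounds[els]))) + max_h * m_h
  suffix <- c(suffix, max_h * m_h)

  counts <- integer(length(els))
  acc <- vector("list", 256L); n_found <- 0L
  rec <- function(i, running) {
    if (running + suffix[i] < lo) return()
    if (i > length(els)) {
      h_lo <- max(0, ceiling((lo - running) / m_h - 1e-9))
      h_hi <- min(max_h, floor((hi - running) / m_h + 1e-9))
      if (h_lo > h_hi) return()
      for (h in h_lo:h_hi) {
        total <- running + h * m_h
        if (total < lo || total > hi || total == 0) next
        v <- c(counts, H = h)
        names(v) <- c(els, "H")
        n_found <<- n_found + 1L
        acc[[n_found]] <<- list(v = v[v > 0], mass = total)
      }
      return()
    }
    n_max <- min(bounds[[els[i]]], floor((hi - running) / emass[i] + 1e-9))
    for (k in 0:n_max) {
      counts[i] <<- k
      rec(i + 1L, running + k * emass[i])
    }
    counts[i] <<- 0L
  }
  rec(1L, 0)
  if (n_found == 0L)
    return(data.frame(formula = character(), mass = numeric(),
                      ppm = numeric(), stringsAsFactors = FALSE))
  acc <- acc[seq_len(n_found)]
  out <- data.frame(
    formula = vapply(acc, function(a) format_formula(a$v), character(1)),
    mass = vapply(acc, function(a) a$mass, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$ppm <- ppm_error(out$mass, mass)
  out[order(abs(out$ppm)), , drop = FALSE]
}

# per-formula golden-rules verdict; returns all failing rules ("" if none)
.golden_rules_one <- function(f, criteria) {
  f <- parse_formula(f)
  cnt <- function(e) if (e %in% names(f)) f[[e]] else 0L
  fails <- character(0)
  mass <- monoisotopic_mass(f)
  b <- if (is.null(criteria$element_bounds)) golden_rule_bounds(mass)
       else criteria$element_bounds
  bb <- b[names(f)]
  if (any(f > bb, na.rm = TRUE)) fails <- c(fails, "rule1_element_counts")
  r <- rdbe(f)
  if (r < 0 || abs(r - round(r)) > 1e-9) fails <- c(fails, "rule2_rdbe")
  C <- cnt("C")
  if (C > 0) {
    hc <- cnt("H") / C
    if (hc < criteria$hc_range[1] || hc > criteria$hc_range[2])
      fails <- c(fails, "rule4_hc_ratio")
    for (e in names(criteria$ratio_caps)) {
      if (cnt(e) / C > criteria$ratio_caps[[e]]) {
        fails <- c(fails, "rule5_heteroatom_ratio")
        break
      }
    }
  }
  N <- cnt("N"); O <- cnt("O"); P <- cnt("P"); S <- cnt("S")
  if ((N > 1 && O > 1 && P > 1 && S > 1 &&
         (N >= 10 || O >= 20 || P >= 4 || S >= 3)) ||
      (N > 3 && O > 3 && P > 3 && (N >= 11 || O >= 22 || P >= 6)) ||
      (O > 1 && P > 1 && S > 1 && (O >= 14 || P >= 3 || S >= 3)) ||
      (P > 1 && S > 1 && N > 1 && (P >= 3 || S >= 3 || N >= 4)))
    fails <- c(fails, "rule6_nops")
  paste(fails, collapse = ",")
}

#' Apply the Seven Golden Rules filters to candidate formulas
#'
#' Applies the non-spectral rules: element-count bounds by mass window
#' (rule 1), non-negative integral RDBE for even-electron neutrals
#' (rule 2), H/C ratio bounds (rule 4), heteroatom/C ratio caps (rule 5)
#' and the joint NOPS multi-element caps (rule 6). The isotope-pattern
#' filter (rule 3) is a separate gate ([isotope_fit()]); the
#' trimethylsilyl rule (rule 7) is GC-specific and not applied.
#'
#' @param candidates A data.frame with a `formula` column (e.g. from
#'   [enumerate_formulas()]) or a character vector of formulas.
#' @param criteria [id_criteria()].
#' @return The candidates with added columns `failed_rule` (empty string
#'   when all rules pass) and `rules_passed` (logical).
#' @examples
#' golden_rules(c("C15H12N2O", "CH30"))
#' @export
golden_rules <- function(candidates, criteria = id_criteria()) {
  if (is.character(candidates))
    candidates <- data.frame(formula = candidates, stringsAsFactors = FALSE)
  candidates$failed_rule <- vapply(candidates$formula, .golden_rules_one,
                                   character(1), criteria = criteria,
                                   USE.NAMES = FALSE)
  candidates$rules_passed <- candidates$failed_rule == ""
  candidates
}

#' Isotope-ratio deviation between a candidate and an observed pattern
#'
#' Simulates the candidate's aggregated isotope pattern and returns the
#' maximum absolute difference (percentage points, relative to the
#' monoisotopic peak) over the compared M+1, M+2, ... bins. A bin missing
#' from the observed pattern is compared as 0 whenever the simulated
#' abundance exceeds 1%.
#'
#' @param candidate Formula of the candidate neutral molecule.
#' @param observed Observed pattern: data.frame with columns `shift`
#'   (integer bin) and `abundance` (% of monoisotopic), e.g. from
#'   [isotope_pattern()] or a feature's `observed_pattern`.
#' @param n_peaks Bins compared (M included).
#' @return Deviation in absolute percentage points.
#' @examples
#' isotope_fit("C15H12N2O", isotope_pattern("C15H12N2O"))  # 0
#' @export
isotope_fit <- function(candidate, observed, n_peaks = 3L) {
  if (is.null(observed) || nrow(observed) < 1L)
    stop("observed pattern must contain at least one peak")
  sim <- isotope_pattern(candidate, n_peaks)
  dev <- 0
  for (k in seq_len(n_peaks - 1L)) {
    s <- sim$abundance[match(k, sim$shift)]
    o <- observed$abundance[match(k, observed$shift)]
    if (is.na(s)) s <- 0
    if (is.na(o)) {
      if (s <= 1) next    # below-noise bins are not evidence against
      o <- 0
    }
    dev <- max(dev, abs(o - s))
  }
  dev
}

#' Composite identification score
#'
#' `100 * (0.4 * exp(-(ppm/2)^2) + 0.4 * exp(-(dev/5)^2) +
#' 0.2 * exp(-(spacing/0.005)^2))`: a weighted product-of-Gaussians style
#' score that is 100 at a perfect tri-criteria match and decreases
#' monotonically in each error. The exponential form is this package's own
#' definition (vendor scores are proprietary); it is isolated here so it
#' can be swapped.
#'
#' @param ppm Absolute mass error (ppm).
#' @param iso_dev Absolute isotope-ratio deviation (percentage points).
#' @param spacing_err Absolute isotope-spacing error (Da).
#' @return Score in \\[0, 100\\].
#' @examples
#' identification_score(0, 0, 0)        # 100
#' identification_score(2, 5, 0.005)    # ~36.8
#' @export
identification_score <- function(ppm, iso_dev = 0, spacing_err = 0) {
  stopifnot(all(is.finite(ppm)), all(is.finite(iso_dev)),
            all(is.finite(spacing_err)))
  100 * (0.4 * exp(-(ppm / 2)^2) +
           0.4 * exp(-(iso_dev / 5)^2) +
           0.2 * exp(-(spacing_err / 0.005)^2))
}

#' Identify the molecular formula of one feature
#'
#' Runs the full identification cascade on a feature's neutral mass:
#' candidate enumeration within the ppm window, golden-rules filtering,
#' the mass-accuracy gate, the isotope-ratio gate against the feature's
#' observed cluster, and the composite-score gate — cheapest first; the
#' gates are conjunctive so the order does not change the accepted set.
#'
#' @param feature One row of an [extract_features()] table (needs
#'   `neutral_mass`, `iso_shifts`, `iso_abundances`), or a list with a
#'   `neutral_mass` and optionally an `observed` pattern.
#' @param criteria [id_criteria()].
#' @param bounds Optional element bounds for enumeration.
#' @return data.frame of all surviving-enumeration candidates with columns
#'   `formula`, `ppm`, `rdbe`, `iso_dev`, `spacing_err`, `score`,
#'   `failed_rule`, `accepted`, ordered by descending score (ties by
#'   absolute ppm) with accepted candidates first.
#' @export
identify_feature <- function(feature, criteria = id_criteria(),
                             bounds = NULL) {
  nm <- feature$neutral_mass
  if (is.null(nm) || is.na(nm)) stop("feature must have a neutral mass")
  if (is.null(bounds)) bounds <- golden_rule_bounds(nm)
  cand <- enumerate_formulas(nm, criteria$max_ppm, bounds)
  empty <- data.frame(formula = character(), ppm = numeric(),
                      rdbe = numeric(), iso_dev = numeric(),
                      spacing_err = numeric(), score = numeric(),
                      failed_rule = character(), accepted = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  cand <- golden_rules(cand, criteria)
  obs <- if (!is.null(feature$observed)) feature$observed
         else if (!is.null(feature$iso_shifts)) observed_pattern(feature)
         else data.frame(shift = 0L, mass_shift = 0, abundance = 100)
  cand$rdbe <- vapply(cand$formula, rdbe, numeric(1), USE.NAMES = FALSE)
  cand$iso_dev <- NA_real_
  cand$spacing_err <- NA_real_
  cand$score <- NA_real_
  gate_mass <- abs(cand$ppm) <= criteria$max_ppm  # enumeration already windows
  todo <- which(cand$rules_passed & gate_mass)
  for (i in todo) {
    cand$iso_dev[i] <- isotope_fit(cand$formula[i], obs, criteria$n_iso_peaks)
    sim <- isotope_pattern(cand$formula[i], criteria$n_iso_peaks)
    common <- intersect(obs$shift[obs$shift > 0], sim$shift)
    cand$spacing_err[i] <- if (length(common) && !is.null(obs$mass_shift)) {
      max(abs(obs$mass_shift[match(common, obs$shift)] -
                sim$mass_shift[match(common, sim$shift)]))
    } else 0
    cand$score[i] <- identification_score(abs(cand$ppm[i]), cand$iso_dev[i],
                                          cand$spacing_err[i])
  }
  cand$accepted <- cand$rules_passed & gate_mass &
    !is.na(cand$iso_dev) & cand$iso_dev <= criteria$max_iso_dev &
    !is.na(cand$score) & cand$score > criteria$min_score
  ord <- order(!cand$accepted, -ifelse(is.na(cand$score), -Inf, cand$score),
               abs(cand$ppm))
  cand <- cand[ord, c("formula", "ppm", "rdbe", "iso_dev", "spacing_err",
                      "score", "failed_rule", "accepted")]
  rownames(cand) <- NULL
  cand
}

#' Identify formulas for a whole feature table
#'
#' @param features An [extract_features()] table.
#' @param criteria [id_criteria()].
#' @param top_only Keep only the best candidate per feature.
#' @return Long data.frame of candidates with a `feature_id` column.
#' @export
identify_features <- function(features, criteria = id_criteria(),
                              top_only = TRUE) {
  res <- lapply(seq_len(nrow(features)), function(i) {
    out <- identify_feature(features[i, ], criteria)
    if (nrow(out) == 0L) return(NULL)
    if (top_only) out <- out[1L, , drop = FALSE]
    out$feature_id <- features$feature_id[i]
    out
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(formula = character(), ppm = numeric(),
                      rdbe = numeric(), iso_dev = numeric(),
                      spacing_err = numeric(), score = numeric(),
                      failed_rule = character(), accepted = logical(),
                      feature_id = character(), stringsAsFactors = FALSE)
  out[, c("feature_id", setdiff(names(out), "feature_id"))]
}
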