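# Synthetic LC-HRMS campaign generator.
#
# Emulates a wastewater treatment plant sampling campaign: three treatment
# stages x three SPE protocols x two ESI polarities. Each run is a list of
# centroided scans on a regular retention-time grid. Planted compounds
# appear as Gaussian chromatographic peaks carrying their simulated isotope
# cluster; anonymous background features survive stage transitions with
# configurable Bernoulli probabilities; sub-noise-floor peaks are sprinkled
# in so that feature extraction has something to reject.

.ww_stages <- c("hall_of_separators", "secondary_settlement", "effluent")
.ww_protocols <- c("A", "B", "C")
.ww_polarities <- c("positive", "negative")

# deterministic sub-seed from a base seed and integer tags, always < 2^31
seed_mix <- function(seed, ...) {
  acc <- as.double(seed) %% 2147483629
  for (x in c(...)) acc <- (acc * 7919 + as.double(x) + 1) %% 2147483629
  as.integer(acc)
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Assembles and validates the knobs of the synthetic-campaign generator.
#' All randomness flows from `seed`; two runs generated from the same
#' configuration are identical.
#'
#' @param seed Mandatory integer seed.
#' @param stages,protocols,polarities Sample-label sets.
#' @param n_background Background features per polarity: a single number or
#'   a vector named by polarity.
#' @param survival Per-polarity numeric vector of length 2: background
#'   survival probability across the raw -> secondary and the
#'   secondary -> effluent transitions.
#' @param mass_jitter_ppm Gaussian sd of per-peak m/z jitter (ppm).
#' @param rt_jitter_min Gaussian sd of per-compound retention-time jitter (min).
#' @param intensity_range Apex-intensity range for background features
#'   (counts, log-uniform).
#' @param noise_floor Intensity (counts) below which planted noise peaks lie;
#'   mirrors the extraction noise threshold.
#' @param noise_peaks_per_scan Mean number of sub-noise-floor peaks per scan.
#' @param mass_range Instrument acquisition m/z range (Da).
#' @param rt_range Chromatographic run range (min).
#' @param scan_spacing Scan-to-scan spacing (min).
#' @param peak_width_sd Gaussian chromatographic peak sd (min); with 0.05-min
#'   scan spacing the default 0.15 spans well over 5 scans.
#' @param n_isotope_peaks Isotope-cluster bins planted per compound.
#' @param suspects Optional suspect plan (as built by [wwtp_preset()]):
#'   a data.frame with columns `name`, `formula`, `polarity`, `rt_min`,
#'   `theor_mz`, `base_intensity`, `me_factor`.
#' @param presence Optional long data.frame (`compound`, `stage`,
#'   `protocol`, `present`) saying which suspect is planted where.
#' @param me_noise_cv Multiplicative log-normal noise CV applied to matrix
#'   areas in [generate_matrix_effect_set()]; 0 (default) is deterministic.
#' @return A list of class `ww_sim_config`.
#' @export
sim_config <- function(seed,
                       stages = .ww_stages,
                       protocols = .ww_protocols,
                       polarities = .ww_polarities,
                       n_background = c(positive = 150, negative = 150),
                       survival = list(positive = c(0.2, 0.825),
                                       negative = c(0.1, 0.825)),
                       mass_jitter_ppm = 0,
                       rt_jitter_min = 0,
                       intensity_range = c(5e3, 5e5),
                       noise_floor = 1300,
                       noise_peaks_per_scan = 20,
                       mass_range = c(100, 1700),
                       rt_range = c(0, 25),
                       scan_spacing = 0.05,
                       peak_width_sd = 0.15,
                       n_isotope_peaks = 3L,
                       suspects = NULL,
                       presence = NULL,
                       me_noise_cv = 0) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory: silent nondeterminism is not allowed")
  stopifnot(all(stages %in% .ww_stages), all(protocols %in% .ww_protocols),
            all(polarities %in% .ww_polarities))
  if (length(n_background) == 1L && is.null(names(n_background)))
    n_background <- stats::setNames(rep(n_background, length(polarities)), polarities)
  for (p in polarities) {
    s <- survival[[p]]
    if (is.null(s) || length(s) != 2L || any(s < 0) || any(s > 1))
      stop("survival[['", p, "']] must be two probabilities in [0, 1]")
  }
  stopifnot(mass_jitter_ppm >= 0, rt_jitter_min >= 0,
            length(mass_range) == 2L, mass_range[1] < mass_range[2],
            length(rt_range) == 2L, rt_range[1] < rt_range[2],
            scan_spacing > 0, peak_width_sd > 0, noise_floor > 0)
  structure(list(
    seed = as.integer(seed), stages = stages, protocols = protocols,
    polarities = polarities, n_background = n_background, survival = survival,
    mass_jitter_ppm = mass_jitter_ppm, rt_jitter_min = rt_jitter_min,
    intensity_range = intensity_range, noise_floor = noise_floor,
    noise_peaks_per_scan = noise_peaks_per_scan, mass_range = mass_range,
    rt_range = rt_range, scan_spacing = scan_spacing,
    peak_width_sd = peak_width_sd, n_isotope_peaks = as.integer(n_isotope_peaks),
    suspects = suspects, presence = presence, me_noise_cv = me_noise_cv
  ), class = "ww_sim_config")
}

#' The packaged wastewater-treatment-plant campaign preset
#'
#' Configuration whose planted ground truth reproduces the packaged
#' reference campaign: the 12 suspects of [suspect_list()] planted according
#' to [reference_detections()], background survival 0.2 (positive mode) and
#' 0.1 (negative mode) across the raw -> secondary transition and 0.825
#' across secondary -> effluent, and the packaged matrix-effect area ratios.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()] (e.g. `n_background`,
#'   `mass_jitter_ppm`).
#' @return A `ww_sim_config`.
#' @examples
#' cfg <- wwtp_preset(seed = 1)
#' @export
wwtp_preset <- function(seed = 1L, ...) {
  susp <- suspect_list()
  plan <- data.frame(
    name = susp$name, formula = susp$formula, polarity = susp$polarity,
    rt_min = susp$rt_min, theor_mz = susp$theor_mz,
    base_intensity = 2e5, me_factor = susp$me_factor,
    product_mz = susp$product_mz,
    stringsAsFactors = FALSE
  )
  dm <- reference_detections()
  long <- expand.grid(compound = rownames(dm),
                      cell = colnames(dm), stringsAsFactors = FALSE)
  parts <- strsplit(long$cell, ".", fixed = TRUE)
  presence <- data.frame(
    compound = long$compound,
    stage = vapply(parts, `[`, "", 1L),
    protocol = vapply(parts, `[`, "", 2L),
    present = dm[cbind(long$compound, long$cell)],
    stringsAsFactors = FALSE
  )
  sim_config(seed = seed, suspects = plan, presence = presence, ...)
}

#' Ground truth of the background features of one polarity
#'
#' Draws the anonymous background population deterministically from the
#' configuration seed: random plausible CHNOS(Cl) formulas with integral
#' non-negative RDBE, uniform retention times, log-uniform apex intensities,
#' and per-stage Bernoulli survival flags (a feature absent from the
#' secondary stage never reappears in the effluent).
#'
#' @param config A `ww_sim_config`.
#' @param polarity `"positive"` or `"negative"`.
#' @return data.frame with columns `id`, `formula`, `mz` (ion m/z), `rt`,
#'   `base_intensity` and logical presence flags `hall_of_separators`,
#'   `secondary_settlement`, `effluent`.
#' @export
ground_truth <- function(config, polarity) {
  stopifnot(inherits(config, "ww_sim_config"), polarity %in% config$polarities)
  n <- unname(config$n_background[[polarity]])
  if (n == 0L) {
    return(data.frame(id = character(), formula = character(), mz = numeric(),
                      rt = numeric(), base_intensity = numeric(),
                      hall_of_separators = logical(),
                      secondary_settlement = logical(), effluent = logical()))
  }
  key <- paste(config$seed, polarity, n,
               paste(config$survival[[polarity]], collapse = ","),
               paste(config$mass_range, collapse = ","),
               paste(config$rt_range, collapse = ","),
               paste(config$intensity_range, collapse = ","), sep = "|")
  hit <- .ww_truth_cache[[key]]
  if (!is.null(hit)) return(hit)
  pol_i <- match(polarity, .ww_polarities)
  out <- with_seed(seed_mix(config$seed, 11L, pol_i), {
    fml <- character(0); mz <- numeric(0)
    adduct <- if (polarity == "positive") "M+H" else "M-H"
    dm_ion <- if (polarity == "positive") .ww_proton else -.ww_proton
    me <- vapply(c("C", "H", "N", "O", "S", "Cl"),
                 function(e) .ww_elements[[e]]$mass[1L], numeric(1))
    # rule-1 element-count windows (< 500 / < 1000 / >= 1000 Da)
    b_C <- c(29, 66, 115); b_H <- c(72, 126, 236)
    b_N <- c(10, 25, 32); b_O <- c(18, 27, 63); b_S <- c(3, 8, 14)
    b_Cl <- c(8, 11, 12)
    while (length(fml) < n) {
      k <- max(2L * (n - length(fml)), 64L)
      C <- sample(5:80, k, replace = TRUE)
      N <- sample(0:3, k, replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
      O <- sample(0:10, k, replace = TRUE)
      S <- stats::rbinom(k, 1L, 0.15)
      Cl <- sample(0:2, k, replace = TRUE, prob = c(0.85, 0.1, 0.05))
      H <- round(C * stats::runif(k, 0.7, 1.9))
      H <- pmin(H, 2L + 2L * C + N - Cl)          # RDBE >= 0
      H <- H - ((H + Cl + N) %% 2L)               # integral RDBE
      m <- C * me[["C"]] + H * me[["H"]] + N * me[["N"]] + O * me[["O"]] +
        S * me[["S"]] + Cl * me[["Cl"]] + dm_ion
      w <- findInterval(m, c(0, 500, 1000))
      ok <- m > config$mass_range[1] + 2 & m < config$mass_range[2] - 5 &
        H >= 1L & (H + Cl + N) %% 2L == 0L &
        C <= b_C[w] & H <= b_H[w] & N <= b_N[w] & O <= b_O[w] &
        S <= b_S[w] & Cl <= b_Cl[w] &
        H / C >= 0.2 & H / C <= 3.1 &
        N / C <= 1.3 & O / C <= 1.2 & S / C <= 0.8 & Cl / C <= 0.8
      cand <- sprintf("C%dH%d%s%s%s%s", C[ok], H[ok],
                      ifelse(Cl[ok] > 0, paste0("Cl", Cl[ok]), ""),
                      ifelse(N[ok] > 0, paste0("N", N[ok]), ""),
                      ifelse(O[ok] > 0, paste0("O", O[ok]), ""),
                      ifelse(S[ok] > 0, paste0("S", S[ok]), ""))
      fml <- c(fml, cand); mz <- c(mz, m[ok])
    }
    fml <- fml[seq_len(n)]; mz <- mz[seq_len(n)]
    surv <- config$survival[[polarity]]
    s2 <- stats::runif(n) < surv[1]
    s3 <- s2 & stats::runif(n) < surv[2]
    data.frame(
      id = sprintf("bg_%s_%04d", substr(polarity, 1, 3), seq_len(n)),
      formula = fml, mz = mz,
      rt = stats::runif(n, config$rt_range[1] + 1, config$rt_range[2] - 1),
      base_intensity = 10^stats::runif(n, log10(config$intensity_range[1]),
                                       log10(config$intensity_range[2])),
      hall_of_separators = TRUE, secondary_settlement = s2, effluent = s3,
      stringsAsFactors = FALSE
    )
  })
  .ww_truth_cache[[key]] <- out
  out
}

.ww_truth_cache <- new.env(parent = emptyenv())

#' Generate one synthetic LC-HRMS run
#'
#' Produces the centroided peak list of one sample (stage x protocol x
#' polarity): every planted compound present in that sample appears as a
#' Gaussian chromatographic peak whose isotope cluster follows
#' [isotope_pattern()], with optional Gaussian ppm jitter on each centroid
#' m/z and per-compound retention-time jitter; sub-noise-floor peaks are
#' added on top. Reproducible: the same configuration always yields the
#' same run.
#'
#' @param config A `ww_sim_config`.
#' @param stage,protocol,polarity Sample label; must belong to the
#'   configured sets.
#' @return A list of class `ww_run` with elements `label`, `peaks` (a
#'   data.frame `scan_id`, `rt_min`, `mz`, `intensity`, `polarity`, ordered
#'   by scan then m/z) and `truth` (the planted compounds of this sample).
#' @examples
#' run <- generate_run(wwtp_preset(seed = 1, n_background = 5),
#'                     "effluent", "C", "negative")
#' nrow(run$peaks)
#' @export
generate_run <- function(config, stage, protocol, polarity) {
  stopifnot(inherits(config, "ww_sim_config"))
  if (!stage %in% config$stages) stop("unknown stage: ", stage)
  if (!protocol %in% config$protocols) stop("unknown protocol: ", protocol)
  if (!polarity %in% config$polarities) stop("unknown polarity: ", polarity)

  bg <- ground_truth(config, polarity)
  planted <- data.frame(
    id = bg$id, name = bg$id, formula = bg$formula, mz = bg$mz, rt = bg$rt,
    base_intensity = bg$base_intensity,
    is_suspect = rep(FALSE, nrow(bg)),
    stringsAsFactors = FALSE
  )[bg[[stage]], , drop = FALSE]

  if (!is.null(config$suspects)) {
    pres <- config$presence
    here <- pres$present & pres$stage == stage & pres$protocol == protocol
    sus <- config$suspects
    sus <- sus[sus$polarity == polarity & sus$name %in% pres$compound[here], ,
               drop = FALSE]
    if (nrow(sus)) {
      planted <- rbind(planted, data.frame(
        id = sus$name, name = sus$name, formula = sus$formula,
        mz = sus$theor_mz, rt = sus$rt_min,
        base_intensity = sus$base_intensity, is_suspect = TRUE,
        stringsAsFactors = FALSE
      ))
    }
  }

  scan_rt <- seq(config$rt_range[1], config$rt_range[2],
                 by = config$scan_spacing)
  n_scans <- length(scan_rt)
  run_seed <- seed_mix(config$seed, 23L, match(stage, .ww_stages),
                       match(protocol, .ww_protocols),
                       match(polarity, .ww_polarities))

  peaks <- with_seed(run_seed, {
    parts <- list()
    if (nrow(planted)) {
      rt0 <- planted$rt +
        if (config$rt_jitter_min > 0)
          stats::rnorm(nrow(planted), 0, config$rt_jitter_min) else 0
      pat <- lapply(planted$formula, isotope_pattern,
                    n_peaks = config$n_isotope_peaks)
      sdw <- config$peak_width_sd
      half <- ceiling(4 * sdw / config$scan_spacing)
      comp <- lapply(seq_len(nrow(planted)), function(i) {
        centre <- findInterval(rt0[i], scan_rt)
        idx <- max(1L, centre - half):min(n_scans, centre + half + 1L)
        p <- pat[[i]]
        prof <- planted$base_intensity[i] *
          exp(-(scan_rt[idx] - rt0[i])^2 / (2 * sdw^2))
        data.table::data.table(
          scan_id = rep(idx, times = nrow(p)),
          rt_min = rep(scan_rt[idx], times = nrow(p)),
          mz = rep(planted$mz[i] + p$mass_shift, each = length(idx)),
          intensity = as.vector(outer(prof, p$abundance / 100))
        )
      })
      parts$comp <- data.table::rbindlist(comp)
      parts$comp <- parts$comp[parts$comp$intensity >= 10, ]
      if (config$mass_jitter_ppm > 0) {
        parts$comp$mz <- parts$comp$mz *
          (1 + stats::rnorm(nrow(parts$comp), 0, config$mass_jitter_ppm * 1e-6))
      }
    }
    n_noise <- stats::rpois(n_scans, config$noise_peaks_per_scan)
    if (sum(n_noise) > 0) {
      parts$noise <- data.table::data.table(
        scan_id = rep(seq_len(n_scans), n_noise),
        rt_min = rep(scan_rt, n_noise),
        mz = stats::runif(sum(n_noise), config$mass_range[1],
                          config$mass_range[2]),
        intensity = stats::runif(sum(n_noise), 0.05 * config$noise_floor,
                                 0.99 * config$noise_floor)
      )
    }
    all <- data.table::rbindlist(parts)
    if (nrow(all) == 0L) {
      all <- data.table::data.table(scan_id = integer(), rt_min = numeric(),
                                    mz = numeric(), intensity = numeric())
    }
    data.table::setorderv(all, c("scan_id", "mz"))
    all$polarity <- rep(polarity, nrow(all))
    as.data.frame(all)
  })

  structure(list(
    label = list(stage = stage, protocol = protocol, polarity = polarity),
    peaks = peaks, truth = planted,
    scan_spacing = config$scan_spacing, rt_range = config$rt_range
  ), class = "ww_run")
}

#' @export
print.ww_run <- function(x, ...) {
  cat(sprintf("<ww_run> %s / %s / %s: %d peaks in %d scans, %d planted compounds\n",
              x$label$stage, x$label$protocol, x$label$polarity,
              nrow(x$peaks), length(unique(x$peaks$scan_id)), nrow(x$truth)))
  invisible(x)
}

#' Generate a paired matrix/solvent calibration set
#'
#' Emulates the matrix-effect experiment: for every suspect with a
#' configured area ratio, produces `n_replicates` paired peak areas with
#' `A_matrix = me_factor * A_solvent`, optionally perturbed by
#' multiplicative log-normal noise (`me_noise_cv`).
#'
#' @param config A `ww_sim_config` whose suspect plan carries `me_factor`.
#' @param n_replicates Pairs per compound (default 3, triplicate).
#' @param a_solvent Baseline solvent peak area (counts).
#' @return data.frame with columns `compound`, `replicate`, `a_matrix`,
#'   `a_solvent`.
#' @export
generate_matrix_effect_set <- function(config, n_replicates = 3L,
                                       a_solvent = 1e5) {
  stopifnot(inherits(config, "ww_sim_config"))
  sus <- config$suspects
  if (is.null(sus) || is.null(sus$me_factor))
    stop("no matrix-effect area ratios configured")
  n <- nrow(sus) * n_replicates
  with_seed(seed_mix(config$seed, 37L), {
    noise <- if (config$me_noise_cv > 0)
      exp(stats::rnorm(n, 0, sqrt(log(1 + config$me_noise_cv^2)))) else 1
    data.frame(
      compound = rep(sus$name, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = nrow(sus)),
      a_matrix = rep(sus$me_factor, each = n_replicates) * a_solvent * noise,
      a_solvent = a_solvent,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a targeted MS/MS spectrum of a suspect
#'
#' Builds a small product-ion spectrum for a suspect entry: the surviving
#' precursor, the monitored product ion, and a few minor uninformative
#' fragments. Used to exercise MS/MS confirmation end to end.
#'
#' @param entry One row of [suspect_list()] (needs `theor_mz`, `product_mz`).
#' @param product_rel Relative intensity (%) of the product ion.
#' @param seed Seed for the minor fragments.
#' @return data.frame with columns `mz`, `intensity`.
#' @export
simulate_msms <- function(entry, product_rel = 60, seed = 1L) {
  stopifnot(nrow(entry) == 1L)
  with_seed(seed_mix(seed, 53L), {
    minor <- stats::runif(3, 50, max(60, entry$product_mz - 10))
    data.frame(
      mz = c(entry$theor_mz, entry$product_mz, minor),
      intensity = c(35, product_rel, stats::runif(3, 1, 4)) * 1000
    )
  })
}
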