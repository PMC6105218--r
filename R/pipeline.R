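# The end-to-end chain: simulate (or load) every sample of a campaign,
# extract features, screen suspects, confirm MS/MS, and summarize
# detections, removal and matrix effects.

#' Run the full screening pipeline on a synthetic campaign
#'
#' For every configured stage x protocol x polarity sample: generate the
#' run, extract features and screen them against the suspect list; then
#' assemble the detection matrix, select effluent-persistent markers,
#' compute per-polarity stage-wise removal of extracted features, the
#' matrix-effect table, the raw-wastewater mass/RT profile, and (optionally)
#' formula identification plus simulated MS/MS confirmation for every
#' detected suspect.
#'
#' @param config A `ww_sim_config`, e.g. [wwtp_preset()].
#' @param params [extraction_params()].
#' @param criteria [id_criteria()] used when `identify = TRUE`.
#' @param mz_tol_ppm,rt_tol_min Screening tolerances.
#' @param identify Run formula identification on the suspect-matched
#'   features (confirmatory; enumeration over the full background is left
#'   to explicit [identify_features()] calls).
#' @param msms Simulate and evaluate the MS/MS confirmation transition for
#'   each detected suspect.
#' @param out_dir Optional directory; when given, all result tables and the
#'   effective configuration are written there.
#' @param quiet Suppress progress messages.
#' @return List of class `ww_pipeline_result`: `detections`, `matrix`
#'   (a [detection_matrix()]), `markers`, `removal` (per polarity),
#'   `me_table`, `mass_profile` (per polarity, raw stage), `identifications`
#'   (NULL unless `identify`), `feature_counts`, `config`.
#' @export
run_pipeline <- function(config,
                         params = extraction_params(),
                         criteria = id_criteria(),
                         mz_tol_ppm = 2, rt_tol_min = 0.5,
                         identify = TRUE, msms = TRUE,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "ww_sim_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  say("pipeline: noise=%g counts, link=%g ppm, screen=%g ppm / %g min, gates: %g ppm, %g%% iso, score > %g%%",
      params$noise_threshold, params$mz_tol_ppm, mz_tol_ppm, rt_tol_min,
      criteria$max_ppm, criteria$max_iso_dev, criteria$min_score)

  suspects <- if (!is.null(config$suspects)) {
    s <- suspect_list()
    s[s$name %in% config$suspects$name, ]
  } else suspect_list()

  detections <- list()
  counts <- list()
  features_by_sample <- list()
  id_pool <- list()
  for (stage in config$stages) {
    for (protocol in config$protocols) {
      feats <- list()
      for (polarity in config$polarities) {
        run <- generate_run(config, stage, protocol, polarity)
        f <- extract_features(run, params)
        # keep feature ids unique across the pooled polarities of a sample
        f$feature_id <- paste0(substr(polarity, 1L, 3L), "_", f$feature_id)
        feats[[polarity]] <- f
        if (protocol == config$protocols[1L])
          counts[[polarity]][[stage]] <- nrow(f)
      }
      fs <- do.call(rbind, feats)
      features_by_sample[[paste(stage, protocol, sep = ".")]] <- fs
      det <- screen_suspects(fs, suspects, mz_tol_ppm, rt_tol_min)
      if (nrow(det)) {
        id_pool[[length(id_pool) + 1L]] <-
          fs[fs$feature_id %in% det$feature_id, , drop = FALSE]
        det$stage <- stage; det$protocol <- protocol
        detections[[length(detections) + 1L]] <- det
      }
      say("  %s / %s: %d features, %d suspect hits", stage, protocol,
          nrow(fs), nrow(det))
    }
  }
  detections <- if (length(detections)) do.call(rbind, detections) else
    data.frame(suspect = character(), feature_id = character(),
               ppm = numeric(), rt_diff = numeric(),
               msms_confirmed = logical(), stage = character(),
               protocol = character(), stringsAsFactors = FALSE)

  if (msms && nrow(detections)) {
    for (i in seq_len(nrow(detections))) {
      entry <- suspects[suspects$name == detections$suspect[i], ]
      sp <- simulate_msms(entry, seed = config$seed)
      detections$msms_confirmed[i] <- confirm_msms(sp, entry)
    }
  }

  dm <- detection_matrix(detections, compounds = suspects$name,
                         stages = config$stages,
                         protocols = config$protocols)
  markers <- if ("effluent" %in% config$stages) select_markers(dm) else character()

  removal <- lapply(config$polarities, function(p)
    removal_rates(unlist(counts[[p]])))
  names(removal) <- config$polarities

  me_table <- if (!is.null(config$suspects) &&
                  !is.null(config$suspects$me_factor))
    matrix_effect_table(generate_matrix_effect_set(config)) else NULL

  raw_key <- paste(config$stages[1L], config$protocols[1L], sep = ".")
  mass_profile <- lapply(config$polarities, function(p) {
    f <- features_by_sample[[raw_key]]
    mass_rt_profile(f[f$polarity == p, , drop = FALSE])
  })
  names(mass_profile) <- config$polarities

  identifications <- NULL
  if (identify && length(id_pool)) {
    pool <- do.call(rbind, id_pool)
    # one identification per distinct ion species, not per sample
    pool <- pool[!duplicated(round(pool$mz, 4)), , drop = FALSE]
    identifications <- identify_features(pool, criteria)
  }

  res <- structure(list(
    detections = detections, matrix = dm, markers = markers,
    removal = removal, me_table = me_table, mass_profile = mass_profile,
    identifications = identifications,
    feature_counts = counts, config = config
  ), class = "ww_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Write all pipeline result tables to a directory
#'
#' @param res A `ww_pipeline_result`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_detection_matrix(res$matrix, p("detection_matrix.csv"))
  utils::write.csv(data.frame(marker = res$markers), p("markers.csv"),
                   row.names = FALSE, quote = FALSE)
  for (pol in names(res$removal))
    utils::write.csv(res$removal[[pol]], p(paste0("removal_", pol, ".csv")),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(res$me_table))
    utils::write.csv(res$me_table, p("matrix_effects.csv"),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(res$detections, p("detections.csv"), row.names = FALSE)
  if (!is.null(res$identifications))
    utils::write.csv(res$identifications, p("identifications.csv"),
                     row.names = FALSE)
  cls <- do.call(rbind, lapply(names(res$mass_profile), function(pol)
    data.frame(polarity = pol, class = names(res$mass_profile[[pol]]$mass_class),
               count = as.integer(res$mass_profile[[pol]]$mass_class))))
  utils::write.csv(cls, p("mass_classes.csv"), row.names = FALSE, quote = FALSE)
  cfg <- res$config
  simple <- vapply(cfg, function(x) is.atomic(x) && length(x) <= 6, logical(1))
  lines <- c(
    vapply(names(cfg)[simple], function(k)
      paste0(k, ": ", paste(cfg[[k]], collapse = ", ")), character(1)),
    paste0("survival: ", paste(vapply(names(cfg$survival), function(p)
      paste0(p, "=", paste(cfg$survival[[p]], collapse = "/")),
      character(1)), collapse = "; "))
  )
  writeLines(lines, p("config_echo.txt"))
  invisible(out_dir)
}

#' @export
print.ww_pipeline_result <- function(x, ...) {
  cat("<ww_pipeline_result>\n")
  cat("  detections:", nrow(x$detections), "suspect hits\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  for (pol in names(x$removal)) {
    r <- x$removal[[pol]]
    cat(sprintf("  removal (%s): %s\n", pol,
                paste(sprintf("%s=%d", r$stage, as.integer(r$count)),
                      collapse = " -> ")))
  }
  invisible(x)
}
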