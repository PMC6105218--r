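# Suspect screening: MS1 matching of extracted features against the suspect
# list (m/z + retention time + polarity), MS/MS transition confirmation
# recorded separately, and assembly of presence/absence detection matrices.

#' Screen features against a suspect list
#'
#' A suspect is detected when some feature matches its ESI polarity, its
#' theoretical ion m/z within `mz_tol_ppm`, and its retention time within
#' `rt_tol_min`. Every (suspect, matching feature) pair is reported; the
#' MS/MS confirmation flag is a separate record filled by [confirm_msms()].
#'
#' @param features An [extract_features()] table.
#' @param suspects A [suspect_list()]-shaped data.frame (needs `name`,
#'   `polarity`, `rt_min` and `theor_mz`).
#' @param mz_tol_ppm Mass tolerance (ppm, default 2).
#' @param rt_tol_min Retention-time tolerance (min, default 0.5).
#' @return data.frame of detections: `suspect`, `feature_id`, `ppm`,
#'   `rt_diff`, `msms_confirmed` (NA until confirmed).
#' @examples
#' run <- generate_run(wwtp_preset(seed = 1, n_background = 0),
#'                     "effluent", "C", "negative")
#' screen_suspects(extract_features(run), suspect_list())
#' @export
screen_suspects <- function(features, suspects = suspect_list(),
                            mz_tol_ppm = 2, rt_tol_min = 0.5) {
  stopifnot(mz_tol_ppm > 0, rt_tol_min > 0)
  out <- list()
  for (i in seq_len(nrow(suspects))) {
    s <- suspects[i, ]
    if (nrow(features) == 0L) break
    ppm <- ppm_error(s$theor_mz, features$mz)
    hit <- features$polarity == s$polarity & abs(ppm) <= mz_tol_ppm &
      abs(features$rt - s$rt_min) <= rt_tol_min
    if (!any(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      suspect = s$name, feature_id = features$feature_id[hit],
      ppm = ppm[hit], rt_diff = features$rt[hit] - s$rt_min,
      msms_confirmed = NA, stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(suspect = character(), feature_id = character(),
                      ppm = numeric(), rt_diff = numeric(),
                      msms_confirmed = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Confirm a suspect by its MS/MS transition
#'
#' TRUE when the acquired product-ion spectrum contains a peak within
#' `tol_da` of the entry's monitored product m/z at or above the relative
#' intensity floor. Product masses are printed at two decimals in
#' monitoring lists, so the tolerance is absolute (Da), not ppm.
#'
#' @param spectrum data.frame with columns `mz`, `intensity`.
#' @param entry One suspect row (needs `product_mz`).
#' @param tol_da Absolute matching tolerance (Da, default 0.01).
#' @param min_rel_intensity Relative-intensity floor (% of base peak).
#' @return Logical flag.
#' @examples
#' sp <- data.frame(mz = c(237.10, 194.10), intensity = c(40, 100))
#' confirm_msms(sp, suspect_list()[suspect_list()$name == "carbamazepine", ])
#' @export
confirm_msms <- function(spectrum, entry, tol_da = 0.01,
                         min_rel_intensity = 5) {
  stopifnot(nrow(entry) == 1L)
  if (is.null(spectrum) || nrow(spectrum) == 0L) return(FALSE)
  rel <- spectrum$intensity / max(spectrum$intensity) * 100
  any(abs(spectrum$mz - entry$product_mz) <= tol_da &
        rel >= min_rel_intensity)
}

#' Assemble a detection matrix
#'
#' Builds the compound x (stage, protocol) presence matrix: a cell is
#' detected iff at least one detection exists for that compound in that
#' sample (duplicates collapse to a single "+").
#'
#' @param detections data.frame with columns `suspect`, `stage`, `protocol`
#'   (e.g. the pooled output of per-sample [screen_suspects()] calls with
#'   sample labels attached).
#' @param compounds Row universe (detections outside it are dropped).
#' @param stages,protocols Column universe.
#' @return A logical matrix of class `ww_detection_matrix` with
#'   `stage.protocol` column names.
#' @export
detection_matrix <- function(detections,
                             compounds = suspect_list()$name,
                             stages = .ww_stages,
                             protocols = .ww_protocols) {
  cells <- as.vector(t(outer(stages, protocols, paste, sep = ".")))
  m <- matrix(FALSE, nrow = length(compounds), ncol = length(cells),
              dimnames = list(sort(compounds), cells))
  if (nrow(detections)) {
    key <- paste(detections$stage, detections$protocol, sep = ".")
    keep <- detections$suspect %in% rownames(m) & key %in% colnames(m)
    m[cbind(detections$suspect[keep], key[keep])] <- TRUE
  }
  class(m) <- c("ww_detection_matrix", class(m))
  m
}

#' @export
print.ww_detection_matrix <- function(x, ...) {
  disp <- ifelse(unclass(x), "+", "-")
  print(as.data.frame(disp), ...)
  invisible(x)
}

#' Pollution-marker selection
#'
#' Markers of anthropogenic pollution are the compounds that persist
#' through treatment: detected in the effluent stage under at least one
#' extraction protocol.
#'
#' @param dm A [detection_matrix()].
#' @param effluent_stage Name of the effluent stage.
#' @return Character vector of marker compounds (possibly empty).
#' @examples
#' select_markers(reference_detections())
#' @export
select_markers <- function(dm, effluent_stage = "effluent") {
  cols <- grep(paste0("^", effluent_stage, "\\."), colnames(dm))
  if (!length(cols)) stop("no effluent-stage columns in the detection matrix")
  sort(rownames(dm)[rowSums(dm[, cols, drop = FALSE]) > 0])
}
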