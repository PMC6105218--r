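#' The packaged emerging-contaminant suspect list
#'
#' Twelve emerging contaminants (artificial sweeteners, pharmaceuticals and
#' parabens) routinely monitored in municipal wastewater, with their
#' molecular formula, ESI polarity, retention time on the methanol/water
#' reversed-phase method (minutes), monitored precursor ion m/z, the MS/MS
#' confirmation transition (product ion m/z and collision energy) and the
#' matrix-effect area ratio (`me_factor` = A_matrix / A_solvent) used by the
#' synthetic calibration-set generator.
#'
#' The `mz_convention` column records whether the listed `precursor_mz`
#' follows proton-mass or hydrogen-atom-mass arithmetic (see [ion_mz()]);
#' the monitoring source mixes the two, and the printed value is only
#' reproduced under the row's stated convention. The `theor_mz` column
#' always carries the physically correct proton-convention ion m/z, which
#' is what screening matches against (it agrees with `precursor_mz` within
#' 5 ppm for every row). `experimental_mz` and `reported_ppm` retain the
#' originally reported measured values for regression checks.
#'
#' @return A data.frame with one row per suspect.
#' @examples
#' suspect_list()[, c("name", "formula", "polarity", "rt_min")]
#' @export
suspect_list <- function() {
  path <- system.file("extdata", "suspects.tsv", package = "wwscreen",
                      mustWork = TRUE)
  s <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  s$adduct <- ifelse(s$polarity == "positive", "M+H", "M-H")
  # full-precision proton-convention ion m/z: the physically consistent
  # monitor mass used for planting and screening
  s$theor_mz <- mapply(function(f, a) ion_mz(f, a, "proton"),
                       s$formula, s$adduct)
  s
}

#' Reference detection matrix of the packaged monitoring campaign
#'
#' Presence/absence of the 12 packaged suspects across the three treatment
#' stages (hall of separators, secondary settlement tank, effluent quality
#' control station) and three solid-phase extraction protocols (A: pH ~ 2,
#' B: pH ~ 6, C: pH ~ 8). This is the ground truth the `wwtp` simulation
#' preset plants, and the matrix a noise-free end-to-end pipeline run must
#' recover.
#'
#' @return A `ww_detection_matrix`: logical matrix, compounds as rows,
#'   `stage.protocol` as columns.
#' @examples
#' reference_detections()["carbamazepine", ]
#' @export
reference_detections <- function() {
  path <- system.file("extdata", "detection_truth.csv", package = "wwscreen",
                      mustWork = TRUE)
  read_detection_matrix(path)
}
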