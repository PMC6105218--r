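#' Monoisotopic mass of a neutral molecule
#'
#' Sum over elements of count times the exact mass of the lightest isotope.
#'
#' @param f Formula (string or named count vector).
#' @return Mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C15H12N2O")  # carbamazepine, 236.09496
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(f) {
  f <- parse_formula(f)
  if (!length(f)) return(0)
  light <- vapply(names(f), function(e) .ww_elements[[e]]$mass[1L], numeric(1))
  sum(light * f)
}

#' m/z of a singly charged (de)protonated ion
#'
#' Computes the ion m/z for the `[M+H]+` or `[M-H]-` species. Under the
#' physically correct `proton` convention the mass of a proton
#' (1.00727646 Da) is added or removed, i.e. the electron is accounted for;
#' the `hydrogen` convention uses the mass of a neutral hydrogen atom
#' (1.00782503 Da), an approximation some instrument software applies. The
#' two differ by one electron mass (~0.00055 Da), which is resolvable at
#' sub-2-ppm accuracy, so the convention is explicit.
#'
#' @param f Formula of the neutral molecule.
#' @param adduct `"M+H"` (positive mode) or `"M-H"` (negative mode).
#' @param convention `"proton"` (default) or `"hydrogen"`.
#' @return Ion m/z in Da.
#' @examples
#' ion_mz("C15H12N2O", "M+H")              # 237.1022
#' ion_mz("C8H8O3", "M-H")                 # 151.0401
#' ion_mz("C4H5NO4S", "M-H", "hydrogen")   # 161.9861
#' @export
ion_mz <- function(f, adduct = c("M+H", "M-H"), convention = c("proton", "hydrogen")) {
  adduct <- match.arg(adduct)
  convention <- match.arg(convention)
  m <- monoisotopic_mass(f)
  dm <- if (convention == "proton") .ww_proton else .ww_hydrogen
  if (adduct == "M+H") m + dm else m - dm
}

#' Signed mass error in parts per million
#'
#' Uses the convention `(theoretical - experimental) / theoretical * 1e6`:
#' a positive error means the measured m/z is below the theoretical value.
#'
#' @param theoretical Theoretical m/z (Da, > 0).
#' @param experimental Measured m/z (Da).
#' @return Signed error in ppm (vectorized).
#' @examples
#' ppm_error(178.0538, 178.0535)  # +1.68
#' ppm_error(237.1022, 237.1023)  # -0.42
#' @export
ppm_error <- function(theoretical, experimental) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  (theoretical - experimental) / theoretical * 1e6
}

#' Ring plus double-bond equivalents
#'
#' RDBE = 1 + sum(count_i * (valence_i - 2) / 2) with standard valences
#' (C=4, N=3, P=3, O=S=2, H and halogens 1). Even-electron neutral molecules
#' have a non-negative integer RDBE; half-integer or negative values signal
#' an impossible composition.
#'
#' @param f Formula.
#' @return RDBE as a double.
#' @examples
#' rdbe("CH4")        # 0
#' rdbe("C15H12N2O")  # 11
#' @export
rdbe <- function(f) {
  f <- parse_formula(f)
  if (!length(f)) return(1)
  val <- .ww_valences[names(f)]
  if (anyNA(val))
    stop("no configured valence for element(s): ",
         paste(names(f)[is.na(val)], collapse = ", "))
  1 + sum(f * (val - 2) / 2)
}
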