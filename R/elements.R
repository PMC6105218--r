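#' Isotope table of the supported elements
#'
#' Exact masses and natural abundances (IUPAC 2013 standard values) for the
#' elements handled by the formula machinery. Each element maps to a
#' data.frame with one row per stable isotope, ordered by nominal mass.
#'
#' @return A named list; each entry is a data.frame with columns
#'   `nominal` (integer mass number), `mass` (exact mass, Da) and
#'   `abundance` (mole fraction, sums to 1 per element).
#' @examples
#' element_table()$Cl
#' @export
element_table <- function() .ww_elements

.ww_elements <- list(
  C = data.frame(
    nominal = c(12L, 13L),
    mass = c(12, 13.00335483507),
    abundance = c(0.9893, 0.0107)
  ),
  H = data.frame(
    nominal = c(1L, 2L),
    mass = c(1.00782503207, 2.01410177785),
    abundance = c(0.999885, 0.000115)
  ),
  N = data.frame(
    nominal = c(14L, 15L),
    mass = c(14.00307400443, 15.00010889888),
    abundance = c(0.99636, 0.00364)
  ),
  O = data.frame(
    nominal = c(16L, 17L, 18L),
    mass = c(15.99491461957, 16.99913175650, 17.99915961286),
    abundance = c(0.99757, 0.00038, 0.00205)
  ),
  P = data.frame(
    nominal = 31L,
    mass = 30.97376199842,
    abundance = 1
  ),
  S = data.frame(
    nominal = c(32L, 33L, 34L, 36L),
    mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
    abundance = c(0.9499, 0.0075, 0.0425, 0.0001)
  ),
  Cl = data.frame(
    nominal = c(35L, 37L),
    mass = c(34.968852682, 36.965902602),
    abundance = c(0.7576, 0.2424)
  ),
  Na = data.frame(
    nominal = 23L,
    mass = 22.9897692820,
    abundance = 1
  ),
  K = data.frame(
    nominal = c(39L, 40L, 41L),
    mass = c(38.9637064864, 39.963998166, 40.9618252579),
    abundance = c(0.932581, 0.000117, 0.067302)
  )
)

# standard valences used by the RDBE statistic (even-electron neutrals)
.ww_valences <- c(C = 4, H = 1, N = 3, O = 2, P = 3, S = 2,
                  Cl = 1, Na = 1, K = 1)

# mass of a proton and of a hydrogen atom; the difference (one electron)
# matters at the 2 ppm level for small ions
.ww_proton <- 1.007276466879
.ww_hydrogen <- 1.00782503207

# nominal spacing of an isotope cluster at charge 1 (13C - 12C)
.ww_iso_spacing <- 1.00335483507
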