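# Channel registry and batch-design vocabulary.

#' Default monitored isotope channels
#'
#' The 43 isotope channels quantified in the wine-profiling batch together
#' with the collision/reaction-cell acquisition mode used for each: lithium,
#' molybdenum and tellurium are measured without cell gas, arsenic and
#' selenium in high-energy helium mode, and every other analyte with helium
#' in the cell.
#'
#' @return A data frame with columns `element` (chemical symbol), `mass`
#'   (integer mass number) and `mode` (one of `"no-gas"`, `"helium"`,
#'   `"high-energy-helium"`). Rows are ordered by increasing mass and the
#'   (element, mass) pairs are unique.
#' @examples
#' ch <- default_channels()
#' nrow(ch)            # 43
#' subset(ch, element == "Cu")
#' @export
default_channels <- function() {
  channels <- data.frame(
    element = c("Li", "Al", "Ti", "V", "Cr", "Mn", "Co", "Ni", "Cu", "Cu",
                "Zn", "Ga", "As", "Se", "Rb", "Sr", "Nb", "Mo", "Ru", "Rh",
                "Ag", "Cd", "Sb", "Te", "Cs", "Ba", "Ce", "Pr", "Nd", "Sm",
                "Eu", "Gd", "Dy", "Ho", "Er", "Tm", "Yb", "Ta", "W", "Tl",
                "Pb", "Pb", "U"),
    mass = c(7L, 27L, 47L, 51L, 52L, 55L, 59L, 60L, 63L, 65L,
             66L, 71L, 75L, 78L, 85L, 88L, 93L, 98L, 101L, 103L,
             107L, 111L, 123L, 125L, 133L, 137L, 140L, 141L, 146L, 147L,
             153L, 157L, 163L, 165L, 166L, 169L, 172L, 181L, 182L, 205L,
             206L, 208L, 238L),
    stringsAsFactors = FALSE
  )
  channels$mode <- channel_mode(channels$element)
  channels
}

#' Cell-gas acquisition mode for an element
#'
#' @param element character vector of chemical symbols.
#' @return character vector of modes.
#' @keywords internal
channel_mode <- function(element) {
  ifelse(element %in% c("Li", "Mo", "Te"), "no-gas",
         ifelse(element %in% c("As", "Se"), "high-energy-helium", "helium"))
}

#' Internal-standard channels
#'
#' The seven internal-standard isotopes fed continuously into the sample
#' stream (1 ug/L mix): 6Li, 45Sc, 72Ge, 89Y, 115In, 159Tb, 209Bi.
#'
#' @return data frame with columns `element`, `mass`.
#' @export
internal_standard_channels <- function() {
  data.frame(
    element = c("Li", "Sc", "Ge", "Y", "In", "Tb", "Bi"),
    mass = c(6L, 45L, 72L, 89L, 115L, 159L, 209L),
    stringsAsFactors = FALSE
  )
}

#' Assign an internal standard to each analyte channel
#'
#' Pairs every analyte channel with the internal-standard isotope closest in
#' mass (ties broken toward the lighter isotope). The pairing is a
#' convention, not an instrument constraint, and can be overridden in the
#' run configuration.
#'
#' @param channels analyte channel registry, as from [default_channels()].
#' @param is_channels internal-standard registry, as from
#'   [internal_standard_channels()].
#' @return `channels` with added columns `is_element`, `is_mass`.
#' @export
assign_internal_standard <- function(channels = default_channels(),
                                     is_channels = internal_standard_channels()) {
  idx <- vapply(channels$mass, function(m) {
    d <- abs(is_channels$mass - m)
    which(d == min(d))[1L]
  }, integer(1))
  channels$is_element <- is_channels$element[idx]
  channels$is_mass <- is_channels$mass[idx]
  channels
}

#' Sample-preparation method codes
#'
#' DD: direct dilution; FA: filtration then acidification; AF: acidification
#' then filtration; MW: closed-vessel microwave-assisted acid digestion.
#'
#' @return character vector of the four method codes.
#' @export
prep_methods <- function() c("DD", "FA", "AF", "MW")

#' Overall dilution factor of a preparation method
#'
#' Direct methods dilute the wine 1:3 with 5% nitric acid (one part sample
#' in three parts total, mapping 12--15% ethanol wine onto the 4% ethanol
#' matrix-matched calibration standards). Microwave digestion combines 2 mL
#' sample with 2 mL concentrated acid and then dilutes the digest 1:5 with
#' ultrapure water, an overall factor of 10.
#'
#' @param method character vector of method codes.
#' @param factors named numeric vector of factors, overridable for users who
#'   read "1:3" as 1 + 3.
#' @return numeric vector of dilution factors.
#' @examples
#' dilution_factor("DD")  # 3
#' dilution_factor("MW")  # 10
#' @export
dilution_factor <- function(method,
                            factors = c(DD = 3, FA = 3, AF = 3, MW = 10)) {
  bad <- setdiff(unique(method), names(factors))
  if (length(bad) > 0) {
    stop("invalid preparation method: ", paste(bad, collapse = ", "))
  }
  unname(factors[method])
}

#' Matrix group of a batch row
#'
#' Calibration standards, continuing calibration blanks and QC standards are
#' shared between the three direct methods (4% ethanol / 5% nitric acid
#' matrix) while microwave digests are quantified against their own 5% nitric
#' acid matrix series.
#'
#' @param method method code or matrix label.
#' @return `"direct"` or `"MW"`.
#' @keywords internal
matrix_group <- function(method) {
  ifelse(method %in% c("MW"), "MW", "direct")
}
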