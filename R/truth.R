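# Ground-truth elemental composition of the simulated wines.

#' Default concentration ranges of wine elements
#'
#' Plausible ranges (ug/L in the undiluted wine) for the monitored elements,
#' spanning roughly three nanograms per litre for the scarcest rare-earth
#' elements up to a few milligrams per litre for manganese and rubidium.
#' Per-wine true values are drawn log-uniformly within these ranges so the
#' four wines carry distinct, separable elemental profiles.
#'
#' @return data frame with columns `element`, `min`, `max` (ug/L).
#' @export
default_truth_ranges <- function() {
  r <- function(element, min, max) data.frame(element = element, min = min,
                                              max = max,
                                              stringsAsFactors = FALSE)
  rbind(
    r("Li", 5, 40),       r("Al", 300, 1500),  r("Ti", 10, 80),
    r("V", 3, 30),        r("Cr", 5, 25),      r("Mn", 1200, 3000),
    r("Co", 2, 8),        r("Ni", 15, 60),     r("Cu", 100, 600),
    r("Zn", 300, 1200),   r("Ga", 0.5, 5),     r("As", 2, 20),
    r("Se", 1, 10),       r("Rb", 1100, 2600), r("Sr", 300, 1200),
    r("Nb", 0.02, 0.2),   r("Mo", 2, 15),      r("Ru", 0.005, 0.03),
    r("Rh", 0.005, 0.03), r("Ag", 0.01, 0.1),  r("Cd", 0.1, 1),
    r("Sb", 0.2, 2),      r("Te", 0.01, 0.08), r("Cs", 2, 20),
    r("Ba", 80, 300),     r("Ce", 0.1, 1.5),   r("Pr", 0.02, 0.2),
    r("Nd", 0.05, 0.8),   r("Sm", 0.01, 0.1),  r("Eu", 0.005, 0.05),
    r("Gd", 0.01, 0.12),  r("Dy", 0.008, 0.1), r("Ho", 0.003, 0.02),
    r("Er", 0.005, 0.05), r("Tm", 0.003, 0.015), r("Yb", 0.005, 0.05),
    r("Ta", 0.005, 0.05), r("W", 0.05, 0.5),   r("Tl", 0.1, 1),
    r("Pb", 5, 60),       r("U", 0.05, 1)
  )
}

#' Generate a ground-truth concentration table
#'
#' Draws one true concentration per (wine, element) pair, log-uniformly
#' within the supplied ranges. Degenerate ranges (`min == max`) yield that
#' exact value. The draw is fully reproducible under a fixed seed.
#'
#' @param seed integer seed (mandatory; the simulation contract is
#'   reproducibility).
#' @param wines character vector of wine codes.
#' @param ranges range specification, as from [default_truth_ranges()].
#' @return data frame with columns `wine`, `element`, `truth` (ug/L in the
#'   undiluted wine).
#' @examples
#' tt <- generate_truth(seed = 1)
#' subset(tt, element == "Mn")  # all above 1000 ug/L
#' @export
generate_truth <- function(seed, wines = c("C", "PN", "S", "T"),
                           ranges = default_truth_ranges()) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (nrow(ranges) == 0) stop("empty element list")
  if (any(ranges$min <= 0 | ranges$max < ranges$min)) {
    stop("ranges must be positive with max >= min")
  }
  set.seed(seed)
  grid <- expand.grid(wine = wines, element = ranges$element,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rmin <- ranges$min[match(grid$element, ranges$element)]
  rmax <- ranges$max[match(grid$element, ranges$element)]
  grid$truth <- exp(stats::runif(nrow(grid), log(rmin), log(rmax)))
  grid$truth[rmin == rmax] <- rmin[rmin == rmax]   # exact, not exp(log(x))
  grid[order(match(grid$element, ranges$element), match(grid$wine, wines)), ,
       drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid
}

#' Look up a truth value
#' @keywords internal
truth_value <- function(truth, wine, element) {
  i <- truth$wine == wine & truth$element == element
  if (!any(i)) return(0)
  truth$truth[i][1L]
}
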