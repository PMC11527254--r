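#' Polygon area by the shoelace formula
#'
#' `area = |0.5 * sum(x_i * y_{i+1} - x_{i+1} * y_i)|` with cyclic closure;
#' the absolute value makes the result independent of vertex orientation.
#' Used for traced region contours on stained sections.
#'
#' @param vertices n x 2 matrix (or data.frame) of ordered (x, y) in um,
#'   n >= 3.
#' @return area in um^2.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("polygon needs at least 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Count-weighted mean section thickness
#'
#' `t_bar_Q = sum(t_i * Q_i) / sum(Q_i)`: the mean measured thickness
#' weighted by the particles counted at each site, so sites contributing no
#' counts contribute no thickness.
#'
#' @param thickness_um thickness t_i at each counting site (um, > 0).
#' @param counts particles Q_i counted at each site (sum > 0).
#' @return weighted mean thickness in um.
#' @export
mean_section_thickness <- function(thickness_um, counts) {
  stopifnot(length(thickness_um) == length(counts))
  if (any(thickness_um <= 0)) stop("thicknesses must be > 0")
  if (sum(counts) <= 0) stop("undefined thickness: no particles counted")
  sum(thickness_um * counts) / sum(counts)
}

#' Optical-fractionator total-number estimate
#'
#' `N_hat = sum_Q * (1/ssf) * (1/asf) * (1/tsf)` where ssf is the section
#' sampling fraction (e.g. 1/6 for every sixth section), asf the area
#' sampling fraction (e.g. 0.20 for a grid covering 20% of the region), and
#' tsf the thickness sampling fraction (disector height / mean measured
#' thickness; defaults to 1 when the full thickness is counted).
#'
#' @param sum_Q total particles counted (>= 0).
#' @param ssf,asf,tsf sampling fractions in (0, 1].
#' @return estimated total number of cells.
#' @export
fractionator_estimate <- function(sum_Q, ssf = 1 / 6, asf = 0.20, tsf = 1) {
  if (sum_Q < 0) stop("sum_Q must be >= 0")
  for (f in c(ssf, asf, tsf))
    if (!(f > 0 && f <= 1)) stop("sampling fractions must be in (0, 1]")
  sum_Q / (ssf * asf * tsf)
}

#' Systematic section sampling
#'
#' Selects every `period`-th section, optionally with a uniformly random
#' start offset in `[0, period)` (the design-based sampling assumption that
#' makes the fractionator unbiased). With ~50 sections and period 6 this
#' yields 8-9 sections per brain.
#'
#' @param n_sections total sections available.
#' @param period sampling period (default 6).
#' @param random_start draw the start offset at random? Default FALSE
#'   (start at section 0).
#' @param seed RNG seed when `random_start`.
#' @return 0-based selected section indices.
#' @export
section_sampling <- function(n_sections, period = 6L, random_start = FALSE,
                             seed = 1L) {
  period <- as.integer(period)
  if (period < 1L) stop("period must be >= 1")
  s <- 0L
  if (random_start) {
    set.seed(seed)
    s <- sample.int(period, 1L) - 1L
  }
  if (s >= n_sections) return(integer(0))
  seq.int(s, n_sections - 1L, by = period)
}

#' Mean-fluorescence ipsi/contra ratio
#'
#' `100 * mean_ipsi / mean_contra`: the ipsilateral region's mean
#' fluorescence intensity as a percentage of the contralateral region's.
#'
#' @param mean_ipsi,mean_contra mean intensities; `mean_contra > 0`.
#' @return percent.
#' @export
mfi_ratio <- function(mean_ipsi, mean_contra) {
  if (mean_contra <= 0) stop("undefined ratio: contralateral mean must be > 0")
  100 * mean_ipsi / mean_contra
}

#' Per-animal fractionator report from section traces
#'
#' Combines polygon traces and counting-site tables into the quantities of
#' the fractionator design: total counted particles, count-weighted mean
#' thickness, and the extrapolated total.
#'
#' @param traces data.frame with columns `section_index`, `x_um`, `y_um`
#'   (ordered vertices per section).
#' @param sites data.frame with columns `section_index`, `thickness_um`,
#'   `count`.
#' @param ssf,asf section/area sampling fractions.
#' @param disector_height_um disector height h; tsf = h / t_bar_Q. Default
#'   NULL counts the full thickness (tsf = 1).
#' @return list: `sum_Q`, `t_bar_Q`, `total_area_um2`, `ssf`, `asf`, `tsf`,
#'   `N_hat`.
#' @export
fractionator_report <- function(traces, sites, ssf = 1 / 6, asf = 0.20,
                                disector_height_um = NULL) {
  areas <- vapply(split(traces, traces$section_index),
                  function(tr) polygon_area(cbind(tr$x_um, tr$y_um)), 1)
  sum_Q <- sum(sites$count)
  t_bar <- mean_section_thickness(sites$thickness_um, sites$count)
  tsf <- if (is.null(disector_height_um)) 1 else disector_height_um / t_bar
  list(sum_Q = sum_Q, t_bar_Q = t_bar, total_area_um2 = sum(areas),
       ssf = ssf, asf = asf, tsf = tsf,
       N_hat = fractionator_estimate(sum_Q, ssf, asf, tsf))
}
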