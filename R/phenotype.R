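# Canalization / variability statistics and spectrophotometric pigment
# quantification.

#' Scaled absolute deviation from the median
#'
#' Per-observation relative variability statistic
#' \eqn{|x_i - \mathrm{median}(x)| / \mathrm{median}(x)}, a robust,
#' CV-comparable measure of phenotype stability (canalization) suited to
#' small or unbalanced designs. The sample coefficient of variation
#' (sd/mean) is included for comparison.
#'
#' @param values Numeric vector of positive observations, length >= 2.
#' @param scale_to `"median"` (default) or `"mean"`: the location used both
#'   as center and as scale.
#' @return List of class `canalization_stats` with `center`, `scaled_ad`
#'   (one entry per observation) and `cv`.
#' @examples
#' scaled_abs_dev_median(c(1, 2, 3))$scaled_ad  # 0.5 0 0.5
#' @export
scaled_abs_dev_median <- function(values, scale_to = c("median", "mean")) {
  scale_to <- match.arg(scale_to)
  if (length(values) < 2L) stop("need at least 2 observations")
  if (anyNA(values)) stop("missing values not allowed")
  center <- switch(scale_to, median = stats::median(values),
                   mean = mean(values))
  if (center <= 0) stop("center must be positive for a scaled deviation")
  structure(
    list(
      center = center,
      scaled_ad = abs(values - center) / center,
      cv = stats::sd(values) / mean(values)
    ),
    class = "canalization_stats"
  )
}

# Pure-methanol chlorophyll/carotenoid equations (standard spectrophotometric
# coefficients; recorded here and in every result for auditability).
pigment_coefficients <- function() {
  list(
    chl_a = c(a665 = 16.72, a652 = -9.16),
    chl_b = c(a652 = 34.09, a665 = -15.28),
    car = c(a470 = 1000, chl_a = -1.63, chl_b = -104.96, denom = 221)
  )
}

#' Pigment concentrations from microplate absorbances
#'
#' Chlorophyll a, chlorophyll b and total carotenoid concentrations
#' (micrograms per ml) from absorbances at 470, 652 and 665 nm of a pure
#' methanolic extract read in a 96-well plate. Because the well's optical
#' path is shorter than the 1 cm cuvette the equations assume, measured
#' absorbances are first divided by the `pathlength` correction (default
#' 0.51). Results scale linearly with the `dilution` factor (default
#' 10-fold dilution in methanol).
#'
#' @param a470,a652,a665 Non-negative absorbances (vectorized).
#' @param pathlength Optical path correction, > 0; default 0.51.
#' @param dilution Dilution factor applied multiplicatively; default 10.
#' @return Data.frame with columns `chl_a`, `chl_b`, `carotenoids`
#'   (micrograms/ml), `pathlength`, `dilution` and a logical `warn_negative`
#'   flag (negative concentrations are reported as computed). The
#'   coefficient set used is attached as attribute `coefficients`.
#' @examples
#' pigment_concentrations(0, 0.051, 0.051, dilution = 1)
#' @export
pigment_concentrations <- function(a470, a652, a665,
                                   pathlength = 0.51, dilution = 10) {
  if (pathlength <= 0) stop("pathlength must be positive")
  if (any(c(a470, a652, a665) < 0)) stop("absorbances must be non-negative")
  k <- pigment_coefficients()
  A470 <- a470 / pathlength
  A652 <- a652 / pathlength
  A665 <- a665 / pathlength
  chl_a <- k$chl_a[["a665"]] * A665 + k$chl_a[["a652"]] * A652
  chl_b <- k$chl_b[["a652"]] * A652 + k$chl_b[["a665"]] * A665
  car <- (k$car[["a470"]] * A470 + k$car[["chl_a"]] * chl_a +
            k$car[["chl_b"]] * chl_b) / k$car[["denom"]]
  out <- data.frame(
    chl_a = chl_a * dilution,
    chl_b = chl_b * dilution,
    carotenoids = car * dilution,
    pathlength = pathlength,
    dilution = dilution
  )
  out$warn_negative <- out$chl_a < 0 | out$chl_b < 0 | out$carotenoids < 0
  if (any(out$warn_negative))
    warning("negative pigment concentration(s) computed; check blanks")
  attr(out, "coefficients") <- k
  out
}
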