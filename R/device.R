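#' LDM301-class device characteristics
#'
#' Nominal characteristics of the 100 Hz laser rangefinder class this
#' package targets, used as defaults by the simulator: output rate 100 Hz
#' (internal measurement at 2 kHz), precision about +/-20 mm, and a beam
#' spot that widens with range (1.7 x 0.08 mrad transmitter divergence,
#' 2.9 mrad circular receiver divergence).
#'
#' @return A named list: `rate_hz`, `precision_m`, `beam_divergence_mrad`
#'   (length 2), `receiver_divergence_mrad`, `spot_area_mm2` (named numeric,
#'   spot area at 10 m and at 100 m).
#' @examples
#' ldm_device_specs()$precision_m  # 0.02
#' @export
ldm_device_specs <- function() {
  list(
    rate_hz = 100,
    internal_rate_hz = 2000,
    precision_m = 0.020,
    beam_divergence_mrad = c(1.7, 0.08),
    receiver_divergence_mrad = 2.9,
    spot_area_mm2 = c(`10m` = 1548, `100m` = 19900)
  )
}

#' Beam spot growth factor between two ranges
#'
#' The laser spot area grows with distance; the ratio of the far-range to
#' the near-range spot area quantifies how much the reflected signal is
#' diluted over the course of a run.  For the default device the spot grows
#' from 1548 mm^2 at 10 m to 19,900 mm^2 at 100 m, a factor of 12.9.
#'
#' @param area_near_mm2,area_far_mm2 Spot areas in mm^2 (defaults: the
#'   device's 10 m and 100 m values).
#' @param digits Rounding applied to the ratio (default 1).
#' @return The ratio `area_far / area_near`, rounded.
#' @export
beam_spread_factor <- function(area_near_mm2 = ldm_device_specs()$spot_area_mm2[["10m"]],
                               area_far_mm2 = ldm_device_specs()$spot_area_mm2[["100m"]],
                               digits = 1) {
  check_scalar_number(area_near_mm2, "area_near_mm2", lower = 1e-12)
  check_scalar_number(area_far_mm2, "area_far_mm2", lower = 0)
  round(area_far_mm2 / area_near_mm2, digits)
}
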