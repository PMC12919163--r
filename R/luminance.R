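#' Convert perimetric stimulus attenuation (dB) to luminance
#'
#' Microperimetry devices express stimulus intensity as decibels of attenuation
#' from the instrument maximum. On the scale implemented here the brightest
#' stimulus (0 dB) is 127 cd/m^2 and each 10 dB attenuates luminance tenfold,
#' so `L = 127 * 10^(-dB/10)`. The 20 dB floor (1.27 cd/m^2) equals the
#' background luminance, i.e. a 20 dB stimulus is invisible by construction.
#'
#' @param db Numeric vector of attenuation values in dB; must be `>= 0`.
#' @return Luminance in cd/m^2, same length as `db`. Strictly decreasing in
#'   `db`.
#' @examples
#' db_to_luminance(c(0, 4, 16, 20))  # 127, 50.6..., 3.2..., 1.27
#' @export
db_to_luminance <- function(db) {
  if (!is.numeric(db) || anyNA(db))
    stop("`db` must be numeric with no missing values", call. = FALSE)
  if (any(db < 0))
    stop("`db` must be non-negative: attenuation below the device maximum",
         call. = FALSE)
  127 * 10^(-db / 10)
}

#' Relative evoked-response amplitude for a stimulus intensity
#'
#' Cortical response amplitude compresses with luminance; here it is modeled
#' as a power law of luminance relative to the 0 dB device maximum,
#' `(L(db)/L(0))^exponent`, so the map is 1 at 0 dB and strictly decreasing
#' in dB.
#'
#' @param db Attenuation in dB (`>= 0`).
#' @param exponent Compression exponent; 0.3 by default.
#' @return Dimensionless scale factor in `(0, 1]`.
#' @export
amplitude_scale <- function(db, exponent = 0.3) {
  (db_to_luminance(db) / db_to_luminance(0))^exponent
}
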