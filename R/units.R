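#' Unit conversions for the internal unit system
#'
#' All computations in sdspike use a single internal unit system chosen so
#' that Ohm's law and the membrane time constant close without numerical
#' factors: length in micrometres, time in milliseconds, voltage in
#' millivolts, current in nanoamperes, resistance in megaohms and
#' capacitance in nanofarads (mV = nA * MOhm, ms = MOhm * nF).  Published
#' electrophysiological constants are quoted in mixed cgs-style units;
#' `sds_units()` returns the multiplicative factors that convert those
#' published units into the internal system.
#'
#' @return Named numeric vector of conversion factors. Multiplying a value in
#'   the published unit by the factor gives the value in internal units;
#'   dividing converts back.
#' @examples
#' u <- sds_units()
#' 130 * u[["MOhm_cm"]]   # membrane resistance coefficient in MOhm*um
#' @export
sds_units <- function() {
  c(
    pF_per_cm   = 1e-7,  # -> nF/um   (1 pF = 1e-3 nF, 1 cm = 1e4 um)
    MOhm_cm     = 1e4,   # -> MOhm*um
    Ohm_cm      = 1e-2,  # -> MOhm*um
    Ohm_cm2     = 1e2,   # -> MOhm*um^2
    uF_per_cm2  = 1e-5,  # -> nF/um^2
    pA_per_um2  = 1e-3,  # -> nA/um^2
    us          = 1e-3,  # -> ms
    um_per_ms   = 1e-3   # -> m/s
  )
}

# internal shorthands
.u <- function(name) sds_units()[[name]]
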