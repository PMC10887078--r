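#' Exchange-pool parameters
#'
#' Describes one proton pool in the Bloch-McConnell model: its resonance
#' position relative to water, the exchange rate with the water pool, its
#' equilibrium size relative to water, and its own relaxation times.
#'
#' @param chemical_shift Resonance offset from water, ppm (glutamate amine
#'   protons sit near +3.0 ppm downfield).
#' @param exchange_rate Solute-to-water proton exchange rate, 1/s.
#' @param proton_fraction Equilibrium magnetization of the pool relative to
#'   water (dimensionless, in (0, 0.1]; 0 is allowed and removes the pool's
#'   saturation-transfer effect).
#' @param t1 Longitudinal relaxation time of the pool, seconds.
#' @param t2 Transverse relaxation time of the pool, seconds.
#' @return An object of class `pool_parameters`.
#' @examples
#' glu_pool(proton_fraction = 0.001)
#' @export
pool_parameters <- function(chemical_shift, exchange_rate, proton_fraction,
                            t1, t2) {
  stopifnot(is.numeric(chemical_shift), length(chemical_shift) == 1L)
  if (!all(is.finite(c(chemical_shift, exchange_rate, proton_fraction, t1, t2))))
    stop("pool parameters must be finite")
  if (exchange_rate < 0) stop("exchange_rate must be >= 0")
  if (proton_fraction < 0 || proton_fraction > 0.1)
    stop("proton_fraction must lie in [0, 0.1]")
  if (t1 <= 0 || t2 <= 0) stop("pool T1 and T2 must be positive")
  structure(list(chemical_shift = chemical_shift,
                 exchange_rate = exchange_rate,
                 proton_fraction = proton_fraction,
                 t1 = t1, t2 = t2),
            class = "pool_parameters")
}

#' @param t1,t2 Water relaxation times in seconds; defaults are typical for
#'   rat brain parenchyma at 7 T.
#' @rdname pool_parameters
#' @export
water_pool <- function(t1 = 1.9, t2 = 0.05) {
  if (t1 <= 0 || t2 <= 0) stop("water T1 and T2 must be positive")
  structure(list(chemical_shift = 0, exchange_rate = 0, proton_fraction = 1,
                 t1 = t1, t2 = t2),
            class = "pool_parameters")
}

#' @param exchange_rate,proton_fraction See above; the amine exchange rate
#'   default is a literature-typical value for glutamate at physiological
#'   pH and temperature. Forward/inverse calibration makes downstream
#'   quantities insensitive to its exact value.
#' @rdname pool_parameters
#' @export
glu_pool <- function(proton_fraction = 0.001, exchange_rate = 2000,
                     t1 = 1.0, t2 = 0.008) {
  pool_parameters(chemical_shift = 3.0, exchange_rate = exchange_rate,
                  proton_fraction = proton_fraction, t1 = t1, t2 = t2)
}

#' Acquisition schedule
#'
#' Collects every axis the simulated (or loaded) protocol uses. The defaults
#' reproduce the full 7 T rodent protocol: 25 CEST offsets from +6 to -6 ppm
#' in 0.5 ppm steps with 3.6 uT / 1000 ms continuous-wave saturation; 33
#' WASSR offsets over +/-0.8 ppm in 0.05 ppm steps at 0.05 uT; a 30/60
#' degree double-angle B1 pair; six repetition times for variable-TR T1
#' mapping; fifteen echo times for multi-echo T2; seven b-values for ADC;
#' and sixteen inversion times for FAIR perfusion.
#'
#' @param cest_offsets Saturation offsets, ppm.
#' @param wassr_offsets WASSR offsets, ppm.
#' @param sat_power Saturation amplitude for the CEST series, microtesla.
#' @param sat_duration Saturation duration, ms.
#' @param wassr_power Saturation amplitude for the WASSR series, microtesla.
#' @param b1_angles Nominal flip angles of the double-angle B1 pair, degrees.
#' @param tr_list Repetition times for T1 mapping, ms.
#' @param te_list Echo times for T2 mapping, ms.
#' @param b_values Diffusion weightings, s/mm^2.
#' @param ti_list Inversion times for FAIR, ms.
#' @param field_hz_per_ppm Water frequency in Hz per ppm (300 at 7 T).
#' @return An object of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(cest_offsets = seq(6, -6, by = -0.5),
                                 wassr_offsets = seq(0.8, -0.8, by = -0.05),
                                 sat_power = 3.6,
                                 sat_duration = 1000,
                                 wassr_power = 0.05,
                                 b1_angles = c(30, 60),
                                 tr_list = c(600, 900, 1500, 2500, 4000, 7000),
                                 te_list = seq(10, 150, by = 10),
                                 b_values = c(0, 166.7, 333.3, 500, 666.7,
                                              833.3, 1000),
                                 ti_list = c(35, seq(100, 1400, by = 100), 1600),
                                 field_hz_per_ppm = 300) {
  stopifnot(sat_power >= 0, wassr_power >= 0, sat_duration > 0,
            field_hz_per_ppm > 0, length(b1_angles) == 2L)
  structure(list(cest_offsets = cest_offsets, wassr_offsets = wassr_offsets,
                 sat_power = sat_power, sat_duration = sat_duration,
                 wassr_power = wassr_power, b1_angles = b1_angles,
                 tr_list = tr_list, te_list = te_list, b_values = b_values,
                 ti_list = ti_list, field_hz_per_ppm = field_hz_per_ppm),
            class = "acquisition_schedule")
}

as_pool_matrix <- function(pools) {
  if (inherits(pools, "pool_parameters")) pools <- list(pools)
  do.call(rbind, lapply(pools, function(p) {
    stopifnot(inherits(p, "pool_parameters"))
    c(p$chemical_shift, p$exchange_rate, p$proton_fraction, 1 / p$t1, 1 / p$t2)
  }))
}
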