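# Active system: error signals, vasomotion, sweating (with dehydration
# modification), shivering, and the high-temperature extensions.

#' Mean skin temperature of a segment
#'
#' Arithmetic mean of the four angular sector temperatures.
#'
#' @param t_sk numeric vector of length 4 (or an n x 4 matrix), degrees C.
#' @return scalar (or length-n vector) mean skin temperature, degrees C.
#' @export
mean_skin_temperature <- function(t_sk) {
  if (is.matrix(t_sk)) rowMeans(t_sk) else mean(t_sk)
}

#' Metabolic multiplier in hot environments
#'
#' Above 39 degrees C ambient, metabolic rate rises by 13% per degree of
#' core temperature above 39 degrees C; below that ambient threshold the
#' multiplier is 1. The hot-branch value is floored at 1 so a hot ambient
#' with a cool core never suppresses metabolism.
#'
#' @param t_cr core temperature, degrees C (vectorised).
#' @param t_a ambient air temperature of the current stage, degrees C.
#' @return dimensionless multiplier >= 1.
#' @export
metabolic_multiplier <- function(t_cr, t_a) {
  if (t_a < 39) rep(1, length(t_cr)) else pmax(1, 1 + 0.13 * (t_cr - 39))
}

#' Cumulative dehydration percentage
#'
#' Cumulative sweat mass expressed as a percentage of the reference body
#' mass (74.30 kg by default).
#'
#' @param sweat_cumulative cumulative sweat mass, kg.
#' @param body_mass_ref reference body mass, kg.
#' @return dehydration D, percent.
#' @export
dehydration_percent <- function(sweat_cumulative, body_mass_ref = 74.30) {
  100 * sweat_cumulative / body_mass_ref
}

#' Dehydration-driven heart-rate increment
#'
#' @param d cumulative dehydration, percent of body mass.
#' @return heart-rate increase, beats/min.
#' @export
heart_rate_increase <- function(d) 4.75 * d

#' Dehydration-modified sweating controller
#'
#' Whole-body sweat production rate driven by the head core temperature
#' error and the integrated warm/cold skin signals. Each 1% of cumulative
#' dehydration raises the onset threshold by 0.06 degrees C and lowers the
#' sensitivity by 0.068 kg/(h C). The sensitivity is floored at zero
#' (reached near D = 4.26%), and the returned rate is non-negative.
#'
#' @param t_head head core temperature, degrees C.
#' @param wrms integrated warm skin signal, K.
#' @param clds integrated cold skin signal, K.
#' @param d cumulative dehydration, percent.
#' @param t_head_set sweating set point, degrees C.
#' @return sweat production rate, kg/h.
#' @export
sweating_rate <- function(t_head, wrms = 0, clds = 0, d = 0, t_head_set = 37) {
  sens <- pmax(0.2898 - 0.068 * d, 0)
  pmax(sens * (t_head - t_head_set - 0.06 * d) + 0.03364 * wrms - clds, 0)
}

#' Sweating-onset head temperature
#'
#' The lowest head core temperature at which the sweating controller
#' produces a positive rate, located by bisection on the onset boundary
#' (the controller is zero at and below onset). With zero skin signals the
#' onset is the dehydration-shifted threshold.
#'
#' @param d cumulative dehydration, percent.
#' @param wrms,clds integrated skin signals, K.
#' @param lower,upper bracketing head temperatures, degrees C.
#' @param tol bisection tolerance, degrees C.
#' @return onset head temperature, degrees C.
#' @export
sweating_onset <- function(d = 0, wrms = 0, clds = 0,
                           lower = 30, upper = 45, tol = 1e-12) {
  f <- function(t) sweating_rate(t, wrms, clds, d) > 0
  if (f(lower)) return(lower)
  if (!f(upper)) stop("no sweating onset in [lower, upper]")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Vasomotor skin blood flow
#'
#' Stolwijk-form control of per-segment skin perfusion: a warm drive
#' (head-core and integrated skin warm signals) dilates, a cold drive
#' constricts, each weighted by the segment's skin sensitivity
#' `alpha_sk`, and the result is clamped to the segment's physiological
#' flow range.
#'
#' @param wrm_cr,cld_cr head-core warm / cold error, K (non-negative).
#' @param wrms,clds integrated skin signals, K.
#' @param body a `bioheat_body`.
#' @return per-segment skin perfusion, cm^3/h (length 15).
#' @export
vasomotor_skin_flow <- function(wrm_cr, cld_cr, wrms, clds, body) {
  g <- body$thermo$gains
  a <- body$thermo$alpha_sk
  dl <- g$dil_cr * wrm_cr + g$dil_sk * wrms
  st <- g$con_cr * cld_cr + g$con_sk * clds
  m <- (body$segments$m_sk_basal + dl * a) / (1 + st * a)
  pmin(pmax(m, body$segments$m_sk_min), body$segments$m_sk_max)
}

#' Shivering heat production
#'
#' Total shivering power proportional to the product of the head-core
#' cold error and the integrated cold skin signal, distributed to segment
#' cores by the shivering coefficients `alpha_sh`.
#'
#' @inheritParams vasomotor_skin_flow
#' @return per-segment shivering power, W (length 15).
#' @export
shivering_heat <- function(cld_cr, clds, body) {
  total <- body$thermo$gains$sh * cld_cr * clds
  body$thermo$alpha_sh * total
}

#' Control signals and regulatory outputs for a body state
#'
#' Computes the full active-system response at one instant: per-segment
#' error signals, integrated warm/cold skin signals, vasomotor skin
#' perfusion, total sweat rate, shivering power, the hot-environment
#' metabolic multiplier, dehydration percentage and heart-rate increment.
#'
#' @param state a `bioheat_state` (see [body_state()]).
#' @param body a `bioheat_body`.
#' @param t_air_mean sector-mean ambient air temperature of the current
#'   stage, degrees C (drives the metabolic-multiplier branch).
#' @return list with elements `err`, `wrm`, `cld`, `wrms`, `clds`,
#'   `wrm_cr`, `cld_cr`, `m_sk_perfusion` (cm^3/h), `sweat_total` (kg/h),
#'   `shiver` (W per segment), `mult` (per segment), `D` (%), `dHR`
#'   (beats/min).
#' @export
control_signals <- function(state, body, t_air_mean = 29) {
  th <- body$thermo
  tskm <- rowMeans(state$T_sk)
  err <- tskm - th$T_sk0
  wrm <- pmax(err, 0); cld <- pmax(-err, 0)
  wrms <- sum(th$alpha_sk * wrm)
  clds <- sum(th$alpha_sk * cld)
  t_head <- state$T_cr[1]
  wrm_cr <- max(t_head - th$T_cr_set, 0)
  cld_cr <- max(th$T_cr_set - t_head, 0)
  d <- dehydration_percent(state$sweat_cumulative, th$body_mass_ref)
  list(
    err = err, wrm = wrm, cld = cld, wrms = wrms, clds = clds,
    wrm_cr = wrm_cr, cld_cr = cld_cr,
    m_sk_perfusion = vasomotor_skin_flow(wrm_cr, cld_cr, wrms, clds, body),
    sweat_total = sweating_rate(t_head, wrms, clds, d, th$T_head_set_sweat),
    shiver = shivering_heat(cld_cr, clds, body),
    mult = metabolic_multiplier(state$T_cr, t_air_mean),
    D = d,
    dHR = heart_rate_increase(d)
  )
}
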