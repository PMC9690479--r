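# Per-sector boundary exchange: convection, evaporation, two-part
# radiation with analytic view factors, and the serial-resistance
# clothing layer.

.sigma_sb <- 5.670374419e-8  # Stefan-Boltzmann constant, W/(m^2 K^4)

#' Saturation vapor pressure of water
#'
#' Antoine correlation (valid 1-100 degrees C), returned in kPa.
#'
#' @param t temperature, degrees C (vectorised).
#' @return saturation vapor pressure, kPa.
#' @export
p_sat_kpa <- function(t) {
  0.133322 * 10^(8.07131 - 1730.63 / (233.426 + t))
}

#' Convective heat loss of a skin sector
#'
#' @param t_sk sector skin temperature, degrees C.
#' @param t_air sector air temperature, degrees C.
#' @param a_sector sector area, m^2 (one quarter of the segment area).
#' @param h_c convective coefficient, W/(m^2 K).
#' @return heat loss, W (negative when the air is hotter: heat gain).
#' @export
convective_loss <- function(t_sk, t_air, a_sector, h_c) {
  a_sector * h_c * (t_sk - t_air)
}

#' Evaporative heat loss of a skin sector
#'
#' Skin vapor pressure is the wettedness-weighted saturation pressure at
#' skin temperature; the loss is floored at zero when the ambient vapor
#' pressure exceeds the skin vapor pressure (no condensation gain is
#' modelled).
#'
#' @param t_sk sector skin temperature, degrees C.
#' @param p_air ambient vapor pressure, kPa.
#' @param wettedness skin wettedness in `[0, 1]` (insensible minimum 0.06
#'   is applied by the caller that derives wettedness from sweat demand).
#' @param a_sector sector area, m^2.
#' @param h_e evaporative coefficient, W/(m^2 kPa).
#' @return heat loss, W (non-negative).
#' @export
evaporative_loss <- function(t_sk, p_air, wettedness, a_sector, h_e) {
  if (any(wettedness < 0 | wettedness > 1))
    stop("wettedness must lie in [0, 1]")
  pmax(a_sector * h_e * (wettedness * p_sat_kpa(t_sk) - p_air), 0)
}

#' Radiative heat loss of a skin sector
#'
#' Two-part radiation: a linearised exchange with the mean radiant
#' temperature plus, for each planar radiant source seen by the sector, a
#' fourth-power exchange weighted by the source view factor.
#'
#' @param t_sk sector skin temperature, degrees C.
#' @param t_mrt mean radiant temperature, degrees C.
#' @param panels list of panels, each a list with `t_r` (source
#'   temperature, degrees C) and `f_vf` (view factor from this sector).
#' @param a_sector sector area, m^2.
#' @param h_r radiative coefficient, W/(m^2 K).
#' @param epsilon emissivity factor of the skin/source pair.
#' @return heat loss, W (negative = radiant gain).
#' @export
radiative_loss <- function(t_sk, t_mrt, panels = list(), a_sector, h_r,
                           epsilon = 0.95) {
  rad <- a_sector * h_r * (t_sk - t_mrt)
  tk4 <- (t_sk + 273.15)^4
  for (p in panels) {
    rad <- rad + a_sector * .sigma_sb * epsilon * p$f_vf *
      (tk4 - (p$t_r + 273.15)^4)
  }
  rad
}

# view factor from a differential patch to a corner-aligned rectangle
# (patch parallel to the rectangle, normal through the corner); a, b are
# the rectangle half-plane extents normalised by the distance.
.vf_corner <- function(a, b) {
  x <- sqrt(1 + a^2)
  y <- sqrt(1 + b^2)
  (a / x * atan(b / x) + b / y * atan(a / y)) / (2 * pi)
}

#' View factor from a differential patch to a parallel rectangle
#'
#' The patch sits at the origin with its normal perpendicular to the
#' rectangle plane at distance `d`; the rectangle spans `[x1, x2]` by
#' `[z1, z2]` in that plane, coordinates measured from the foot of the
#' patch normal. Computed exactly by signed additivity of the classical
#' corner formula, so subdividing the rectangle and summing reproduces
#' the whole-rectangle value to machine precision.
#'
#' @param x1,x2,z1,z2 rectangle extents in its plane, m.
#' @param d perpendicular distance from patch to plane, m (> 0).
#' @return view factor in `[0, 1]`; 0 for a degenerate rectangle.
#' @export
view_factor_rect <- function(x1, x2, z1, z2, d) {
  if (d <= 0) stop("panel distance must be positive")
  if (x2 <= x1 || z2 <= z1) return(0)
  f <- function(x, z) sign(x) * sign(z) * .vf_corner(abs(x) / d, abs(z) / d)
  val <- f(x2, z2) - f(x1, z2) - f(x2, z1) + f(x1, z1)
  min(max(val, 0), 1)
}

#' Clothing adjustment of boundary fluxes
#'
#' Simplified serial-resistance clothing layer: the dry (convective plus
#' radiative) flux is scaled by the ratio of the clothed to the bare dry
#' conductance, `1 / (1 + I_cl (h_c + h_r))`, and the evaporative flux
#' analogously by `1 / (1 + R_ecl h_e)`. Bare segments (zero resistances)
#' pass through unchanged.
#'
#' @param fluxes list with `dry` and `evap` components, W.
#' @param i_cl intrinsic clothing insulation, m^2 K/W.
#' @param r_ecl clothing evaporative resistance, m^2 kPa/W.
#' @param h_c,h_r,h_e bare transfer coefficients.
#' @return list with scaled `dry` and `evap` fluxes.
#' @export
apply_clothing <- function(fluxes, i_cl, r_ecl, h_c, h_r, h_e) {
  if (i_cl < 0 || r_ecl < 0) stop("clothing resistances must be >= 0")
  list(dry = fluxes$dry * clothing_dry_factor(i_cl, h_c, h_r),
       evap = fluxes$evap * clothing_evap_factor(r_ecl, h_e))
}

#' @rdname apply_clothing
#' @export
clothing_dry_factor <- function(i_cl, h_c, h_r) 1 / (1 + i_cl * (h_c + h_r))

#' @rdname apply_clothing
#' @export
clothing_evap_factor <- function(r_ecl, h_e) 1 / (1 + r_ecl * h_e)

#' Planar radiant source
#'
#' A vertical rectangular panel parallel to the body axis: `width` by
#' `height` (m), lower edge at height `z0`, lateral centre offset
#' `x_offset`, at perpendicular `distance` from the body surface. The
#' panel irradiates the sectors listed in `targets` (a data.frame with
#' `segment` and `sector` columns), or, via the `side` shortcut, the
#' laterally outward (`exterior`) sectors of that side's limbs and of the
#' head/trunk.
#'
#' @param t_r source temperature, degrees C.
#' @param width,height panel dimensions, m.
#' @param distance perpendicular distance to the body, m (> 0).
#' @param z0 height of the panel's lower edge, m.
#' @param x_offset lateral offset of the panel centre, m.
#' @param side optional shortcut: `"left"` or `"right"`.
#' @param targets optional data.frame (`segment`, `sector`).
#' @return list of class `bioheat_panel`.
#' @export
radiant_panel <- function(t_r, width, height, distance, z0 = 0,
                          x_offset = 0, side = NULL, targets = NULL) {
  if (distance <= 0) stop("panel distance must be positive")
  if (is.null(targets)) {
    if (is.null(side)) stop("give either targets or a side shortcut")
    side <- match.arg(side, c("left", "right"))
    suf <- if (side == "left") "_l" else "_r"
    segs <- c("head", "chest", "abdomen",
              grep(paste0(suf, "$"), segment_names(), value = TRUE))
    targets <- data.frame(segment = segs, sector = "exterior",
                          stringsAsFactors = FALSE)
  }
  structure(list(t_r = t_r, width = width, height = height,
                 distance = distance, z0 = z0, x_offset = x_offset,
                 targets = targets),
            class = "bioheat_panel")
}

#' One stage of a time-staged environment
#'
#' @param duration stage duration, s (> 0).
#' @param t_air air temperature, degrees C; scalar or one value per sector
#'   (anterior, exterior, posterior, inferior).
#' @param rh relative humidity (0-1), used to derive the vapor pressure
#'   when `p_air` is not given.
#' @param p_air ambient vapor pressure, kPa; scalar or per sector.
#' @param t_mrt mean radiant temperature, degrees C (defaults to the
#'   sector-mean air temperature).
#' @param h_c convective coefficient, W/(m^2 K).
#' @param h_r radiative coefficient, W/(m^2 K).
#' @param h_e evaporative coefficient, W/(m^2 kPa); defaults to the Lewis
#'   relation `16.5 * h_c`.
#' @param panels list of [radiant_panel()] sources.
#' @return list of class `bioheat_stage`.
#' @export
environment_stage <- function(duration, t_air, rh = NULL, p_air = NULL,
                              t_mrt = NULL, h_c = 3.0, h_r = 4.7,
                              h_e = 16.5 * h_c, panels = list()) {
  if (duration <= 0) stop("stage duration must be positive")
  if (any(c(h_c, h_r, h_e) <= 0)) stop("transfer coefficients must be positive")
  t_air <- rep_len(t_air, 4)
  if (is.null(p_air)) {
    if (is.null(rh)) stop("give rh or p_air")
    p_air <- rh * p_sat_kpa(t_air)
  }
  p_air <- rep_len(p_air, 4)
  if (is.null(t_mrt)) t_mrt <- mean(t_air)
  structure(list(duration = duration, t_air = t_air, p_air = p_air,
                 t_mrt = t_mrt, h_c = h_c, h_r = h_r, h_e = h_e,
                 panels = panels),
            class = "bioheat_stage")
}
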