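# 105-node passive system: state vector layout, per-node energy
# balances, and the vectorised right-hand side of the coupled ODE
# system (cores, arteries, veins, four skin sectors per segment, plus
# cumulative sweat mass as an auxiliary state).

#' Body thermal state
#'
#' @param T_cr,T_bl_a,T_bl_v core / artery / vein temperatures, degrees C
#'   (length n segments).
#' @param T_sk skin sector temperatures, n x 4 matrix, degrees C (columns:
#'   anterior, exterior, posterior, inferior).
#' @param sweat_cumulative cumulative sweat mass, kg.
#' @param t elapsed time, s.
#' @return object of class `bioheat_state`. Dehydration `D` (%) and the
#'   heart-rate increment `dHR` (beats/min) are derived quantities,
#'   available via [control_signals()] or [run_simulation()] output.
#' @export
body_state <- function(T_cr, T_bl_a, T_bl_v, T_sk, sweat_cumulative = 0,
                       t = 0) {
  n <- length(T_cr)
  T_sk <- matrix(T_sk, n, 4)
  stopifnot(length(T_bl_a) == n, length(T_bl_v) == n)
  structure(list(T_cr = T_cr, T_bl_a = T_bl_a, T_bl_v = T_bl_v,
                 T_sk = T_sk, sweat_cumulative = sweat_cumulative, t = t),
            class = "bioheat_state")
}

#' Uniform body state
#'
#' Convenience constructor: every node at one temperature.
#'
#' @param temp temperature, degrees C.
#' @param n number of segments.
#' @inheritParams body_state
#' @export
uniform_state <- function(temp, n = 15, sweat_cumulative = 0, t = 0) {
  body_state(rep(temp, n), rep(temp, n), rep(temp, n),
             matrix(temp, n, 4), sweat_cumulative, t)
}

#' @rdname body_state
#' @param state a `bioheat_state`.
#' @export
pack_state <- function(state) {
  c(state$T_cr, state$T_bl_a, state$T_bl_v, as.vector(state$T_sk),
    state$sweat_cumulative)
}

#' @rdname body_state
#' @param y packed numeric state vector.
#' @param ctx a `bioheat_context`.
#' @export
unpack_state <- function(y, ctx, t = 0) {
  n <- ctx$n
  body_state(y[ctx$i_cr], y[ctx$i_a], y[ctx$i_v],
             matrix(y[ctx$i_sk], n, 4), y[ctx$i_sw], t)
}

#' Check state sanity bounds
#'
#' All node temperatures must lie in `[0, 60]` degrees C and be finite;
#' cumulative sweat must be non-negative.
#'
#' @param y packed state vector.
#' @param ctx a `bioheat_context`.
#' @param t time stamp used in the diagnostic, s.
#' @return invisibly `TRUE`; aborts with the offending node identified.
#' @export
check_state <- function(y, ctx, t = NA) {
  temps <- y[seq_len(7 * ctx$n)]
  bad <- which(!is.finite(temps) | temps < 0 | temps > 60)
  if (length(bad)) {
    stop(sprintf(
      "state invariant violated at t = %s s: node %d (%s) = %g C",
      format(t), bad[1], .node_label(bad[1], ctx), temps[bad[1]]))
  }
  if (!is.finite(y[ctx$i_sw]) || y[ctx$i_sw] < 0)
    stop("cumulative sweat must be finite and >= 0")
  invisible(TRUE)
}

.node_label <- function(i, ctx) {
  n <- ctx$n
  if (i <= n) return(paste0(ctx$names[i], "/core"))
  if (i <= 2 * n) return(paste0(ctx$names[i - n], "/artery"))
  if (i <= 3 * n) return(paste0(ctx$names[i - 2 * n], "/vein"))
  k <- i - 3 * n
  seg <- (k - 1) %% n + 1
  sec <- (k - 1) %/% n + 1
  paste0(ctx$names[seg], "/skin-", sector_names()[sec])
}

#' Respiratory heat loss
#'
#' Convective-plus-evaporative respiratory loss attributed to the chest
#' core, `RES = 0.0014 M (34 - T_air) + 0.0173 M (5.87 - P_air)`. May be
#' negative in hot, humid air (respiratory heat gain), which is physical.
#'
#' @param m_cr chest core metabolic rate, W.
#' @param t_air ambient air temperature, degrees C.
#' @param p_air ambient vapor pressure, kPa.
#' @return respiratory heat loss, W.
#' @export
respiratory_heat_loss <- function(m_cr, t_air, p_air) {
  0.0014 * m_cr * (34 - t_air) + 0.0173 * m_cr * (5.87 - p_air)
}

#' Redistribute segment skin perfusion over sectors
#'
#' Hotter sectors receive proportionally more of the segment's skin blood
#' flow: each sector gets a quarter share modulated by its temperature
#' excess over the sector mean, `(m/4) (1 + delta_i / sum(max(0, delta)))`,
#' which conserves the segment total because the deltas sum to zero.
#' Isothermal sectors split the flow equally. Any negative share (cannot
#' arise for a 4-sector ring, but guarded) is clipped to zero with the
#' deficit removed proportionally from the positive sectors.
#'
#' @param t_sk four sector temperatures, degrees C.
#' @param m_total total segment skin perfusion (>= 0), any flow unit.
#' @return per-sector flows summing to `m_total`.
#' @export
perfusion_redistribution <- function(t_sk, m_total) {
  stopifnot(length(t_sk) == 4, m_total >= 0)
  delta <- t_sk - mean(t_sk)
  possum <- sum(pmax(delta, 0))
  if (possum == 0) return(rep(m_total / 4, 4))
  share <- 0.25 * (1 + delta / possum)
  if (any(share < 0)) {
    deficit <- -sum(share[share < 0])
    share[share < 0] <- 0
    share[share > 0] <- share[share > 0] * (1 - deficit / sum(share[share > 0]))
  }
  m_total * share
}

#' Core node energy balance
#'
#' Scalar form of the core balance: metabolic heat minus mechanical work,
#' conduction and perfusion to the four skin sectors, arterial perfusion
#' gain, convective exchange with the artery and vein, perfusion to the
#' vein, and (chest only) respiratory loss, divided by the core
#' capacitance.
#'
#' @param C_cr core heat capacitance, J/K.
#' @param M_cr metabolic heat, W. @param W_cr mechanical work, W.
#' @param q_cr_sk,q_perf_cr_sk conduction / perfusion losses to the four
#'   sectors, W (length 4).
#' @param q_perf_a_cr arterial perfusion gain, W.
#' @param q_cr_a,q_cr_v convective losses to artery / vein, W.
#' @param q_perf_cr_v perfusion loss to the vein, W.
#' @param res respiratory loss, W (chest only).
#' @return dT_cr/dt, K/s.
#' @export
core_rhs <- function(C_cr, M_cr = 0, W_cr = 0, q_cr_sk = numeric(4),
                     q_perf_cr_sk = numeric(4), q_perf_a_cr = 0,
                     q_cr_a = 0, q_cr_v = 0, q_perf_cr_v = 0, res = 0) {
  ((M_cr - W_cr) - sum(q_cr_sk) - sum(q_perf_cr_sk) + q_perf_a_cr -
     q_cr_a - q_cr_v - q_perf_cr_v - res) / C_cr
}

#' Angular conduction around the sector ring
#'
#' Periodic central second difference of the four sector temperatures
#' with angular step pi/2, scaled by the tangential conduction
#' coefficient `K_sk L_n th_sk / r^2`. The four terms sum to zero
#' (conservation on the ring).
#'
#' @param t_sk four sector temperatures, degrees C.
#' @param g_ang conduction coefficient `K_sk L_n th_sk / r^2`, W/K.
#' @return per-sector conduction gain, W (length 4).
#' @export
angular_conduction <- function(t_sk, g_ang) {
  g_ang / (pi / 2)^2 * (t_sk[c(2, 3, 4, 1)] + t_sk[c(4, 1, 2, 3)] - 2 * t_sk)
}

#' Skin sector energy balance
#'
#' @param C_sk_sector sector heat capacitance (segment skin capacitance
#'   divided by 4), J/K.
#' @param ang angular conduction gain, W.
#' @param m_sk_sector sector metabolic heat (segment skin metabolism
#'   divided by 4), W.
#' @param q_cr_sk,q_perf_cr_sk conduction / perfusion gains from the
#'   core, W.
#' @param con,eva,rad boundary losses, W.
#' @return dT_sk/dt, K/s.
#' @export
skin_sector_rhs <- function(C_sk_sector, ang = 0, m_sk_sector = 0,
                            q_cr_sk = 0, q_perf_cr_sk = 0,
                            con = 0, eva = 0, rad = 0) {
  (ang + m_sk_sector + q_cr_sk + q_perf_cr_sk - con - eva - rad) / C_sk_sector
}

#' Vessel node energy balances
#'
#' Artery: convective exchange with the core plus advection of upstream
#' arterial blood. Vein: convective exchange with the core, core
#' perfusion return, plus advection of the flow-weighted mixture of
#' distal venous returns and local skin-perfusion returns.
#'
#' @param t_cr,t_a,t_v core / artery / vein temperatures, degrees C.
#' @param t_a_up upstream artery temperature, degrees C.
#' @param t_v_in flow-weighted venous inflow mixture temperature, degrees C.
#' @param h_a,h_v core-vessel convective conductances, W/K.
#' @param w_a arterial advective conductance (mass flow times blood
#'   specific heat), W/K.
#' @param w_cr core perfusion conductance, W/K.
#' @param w_v venous advective conductance, W/K.
#' @param C_a,C_v vessel heat capacitances, J/K.
#' @return list with `dT_a` and `dT_v`, K/s.
#' @export
vessel_rhs <- function(t_cr, t_a, t_v, t_a_up, t_v_in, h_a, h_v,
                       w_a, w_cr, w_v, C_a, C_v) {
  list(dT_a = (h_a * (t_cr - t_a) + w_a * (t_a_up - t_a)) / C_a,
       dT_v = (h_v * (t_cr - t_v) + w_cr * (t_cr - t_v) +
                 w_v * (t_v_in - t_v)) / C_v)
}

#' Simulation context
#'
#' Precomputes every per-segment constant needed by the right-hand side:
#' capacitances, conductances, flow conversions, controller gains, the
#' blood-network traversal and clothing resistances. Flags allow the
#' boundary exchange, metabolic heat or the active controller to be
#' switched off for conservation and equilibrium analyses.
#'
#' @param body a `bioheat_body`.
#' @param network a `bioheat_network` (default topology when `NULL`).
#' @param clothing optional clothing specification from [clothing_spec()].
#' @param flags list with logical `boundary`, `metabolism`, `active`.
#' @return object of class `bioheat_context`.
#' @export
build_context <- function(body, network = NULL, clothing = NULL,
                          flags = list()) {
  validate_body(body)
  if (is.null(network)) network <- blood_network(body)
  if (is.null(clothing)) clothing <- clothing_spec()
  fl <- list(boundary = TRUE, metabolism = TRUE, active = TRUE)
  fl[names(flags)] <- flags
  seg <- body$segments
  th <- body$thermo
  n <- nrow(seg)
  parent_safe <- network$parent
  parent_safe[network$root] <- network$root
  i_cl <- r_ecl <- numeric(n)
  idx <- match(clothing$segment, seg$name)
  if (anyNA(idx)) stop("unknown segment in clothing spec")
  i_cl[idx] <- clothing$i_cl
  r_ecl[idx] <- clothing$r_ecl
  structure(list(
    n = n, names = seg$name,
    i_cr = seq_len(n), i_a = n + seq_len(n), i_v = 2 * n + seq_len(n),
    i_sk = 3 * n + seq_len(4 * n), i_sw = 7 * n + 1L,
    A4 = seg$A / 4, M_cr = seg$M_cr, M_sk = seg$M_sk, W_cr = seg$W_cr,
    C_cr = seg$C_cr, C_a = seg$C_bl_a, C_v = seg$C_bl_v,
    C_sk4 = seg$C_sk / 4, K4 = seg$K_cr_sk / 4,
    g_ang = seg$K_sk * seg$L_n * seg$th_sk / seg$r^2 / (pi / 2)^2,
    eps = seg$epsilon, z_c = seg$z_c,
    m_basal = seg$m_sk_basal, m_min = seg$m_sk_min, m_max = seg$m_sk_max,
    cm3h_W = 1e-6 / 3600 * th$rho_bl * th$c_bl,
    w_cr_basal = core_perfusion(body) * 1e-6 / 3600 * th$rho_bl * th$c_bl,
    t_sk0 = th$T_sk0, alpha_sk = th$alpha_sk, alpha_sh = th$alpha_sh,
    alpha_sw = th$alpha_sw,
    t_cr_set = th$T_cr_set, t_head_set = th$T_head_set_sweat,
    body_mass_ref = th$body_mass_ref, lambda = th$lambda_sweat,
    g_dil_cr = th$gains$dil_cr, g_dil_sk = th$gains$dil_sk,
    g_con_cr = th$gains$con_cr, g_con_sk = th$gains$con_sk,
    g_sh = th$gains$sh,
    parent = network$parent, parent_safe = parent_safe,
    order = network$order, root = network$root,
    h_a = network$h_a, h_v = network$h_v,
    ref = match("head", seg$name, nomatch = 1L),
    chest = match("chest", seg$name, nomatch = network$root),
    i_cl = i_cl, r_ecl = r_ecl,
    flags = fl
  ), class = "bioheat_context")
}

#' Clothing specification
#'
#' @param segment character vector of clothed segment names.
#' @param i_cl intrinsic insulation, m^2 K/W (recycled).
#' @param r_ecl evaporative resistance, m^2 kPa/W (recycled).
#' @return data.frame used by [build_context()]; zero rows = nude body.
#' @export
clothing_spec <- function(segment = character(), i_cl = numeric(),
                          r_ecl = numeric()) {
  if (length(segment)) {
    i_cl <- rep_len(i_cl, length(segment))
    r_ecl <- rep_len(r_ecl, length(segment))
    if (any(i_cl < 0) || any(r_ecl < 0))
      stop("clothing resistances must be >= 0")
  }
  data.frame(segment = as.character(segment), i_cl = as.numeric(i_cl),
             r_ecl = as.numeric(r_ecl), stringsAsFactors = FALSE)
}

# fast elementwise max(x, 0) / clamp without pmax dispatch overhead
.relu <- function(x) (x + abs(x)) * 0.5
.clamp <- function(x, lo, hi) {
  x <- lo + .relu(x - lo)
  hi - .relu(hi - x)
}

# Vectorised right-hand side over the packed state. `st` is a compiled
# stage (see .compile_stage). Returns the derivative vector, or, with
# details = TRUE, a list exposing every heat flow for inspection.
.rhs_raw <- function(y, st, ctx, details = FALSE) {
  n <- ctx$n
  Tcr <- y[ctx$i_cr]; Ta <- y[ctx$i_a]; Tv <- y[ctx$i_v]
  Tsk <- y[ctx$i_sk]; dim(Tsk) <- c(n, 4L)
  sweat <- y[ctx$i_sw]
  t_head <- Tcr[ctx$ref]
  D <- 100 * sweat / ctx$body_mass_ref

  tskm <- .rowMeans(Tsk, n, 4L)
  if (ctx$flags$active) {
    err <- tskm - ctx$t_sk0
    wrm <- .relu(err); cld <- .relu(-err)
    wrms <- sum(ctx$alpha_sk * wrm); clds <- sum(ctx$alpha_sk * cld)
    wrm_cr <- max(t_head - ctx$t_cr_set, 0)
    cld_cr <- max(ctx$t_cr_set - t_head, 0)
    dl <- ctx$g_dil_cr * wrm_cr + ctx$g_dil_sk * wrms
    stq <- ctx$g_con_cr * cld_cr + ctx$g_con_sk * clds
    m_sk <- .clamp((ctx$m_basal + dl * ctx$alpha_sk) /
                     (1 + stq * ctx$alpha_sk), ctx$m_min, ctx$m_max)
    sweat_rate <- max(max(0.2898 - 0.068 * D, 0) *
                        (t_head - ctx$t_head_set - 0.06 * D) +
                        0.03364 * wrms - clds, 0)
    shiver_tot <- ctx$g_sh * cld_cr * clds
  } else {
    wrms <- clds <- 0
    m_sk <- ctx$m_basal
    sweat_rate <- 0
    shiver_tot <- 0
  }

  if (ctx$flags$metabolism) {
    mult <- if (st$t_air_mean >= 39) 1 + 0.13 * .relu(Tcr - 39) else 1
    Mcr <- mult * ctx$M_cr + ctx$alpha_sh * shiver_tot
    Wcr <- ctx$W_cr
    Msk4 <- mult * ctx$M_sk * 0.25
  } else {
    Mcr <- numeric(n); Wcr <- 0; Msk4 <- 0
  }

  # sector split of skin perfusion (conserves the segment total; a
  # sector's deficit cannot exceed the positive-delta sum, so shares
  # are non-negative)
  delta <- Tsk - tskm
  possum <- .rowSums(.relu(delta), n, 4L)
  possum[possum == 0] <- Inf
  share <- 0.25 * (1 + delta / possum)
  w_sk <- ctx$cm3h_W * m_sk
  w_sk_sec <- w_sk * share
  w_cr <- ctx$w_cr_basal

  # conservative tree flows (advective conductances, W/K)
  w_a <- w_cr + w_sk
  for (k in ctx$order) w_a[ctx$parent[k]] <- w_a[ctx$parent[k]] + w_a[k]
  heat_in <- .rowSums(w_sk_sec * Tsk, n, 4L)
  w_v <- w_sk
  for (k in ctx$order) {
    p <- ctx$parent[k]
    heat_in[p] <- heat_in[p] + w_a[k] * Tv[k]
    w_v[p] <- w_v[p] + w_a[k]
  }
  T_up <- Ta[ctx$parent_safe]
  T_up[ctx$root] <- Tv[ctx$root]  # heart: central venous return re-enters

  if (ctx$flags$boundary) {
    hc <- st$h_c; hr <- st$h_r; he <- st$h_e
    f_dry <- 1 / (1 + ctx$i_cl * (hc + hr))
    f_evap <- 1 / (1 + ctx$r_ecl * he)
    CON <- ctx$A4 * hc * f_dry * (Tsk - st$t_air_mat)
    # panels displace their solid angle from the enclosure exchange:
    # the mean-radiant term acts on the residual view factor 1 - sum(F)
    RAD1 <- ctx$A4 * hr * f_dry * (Tsk - st$t_mrt) * st$f_bg
    RAD2 <- 0
    if (length(st$panel_f)) {
      tk4 <- (Tsk + 273.15)^4
      RAD2 <- matrix(0, n, 4)
      for (p in st$panel_f)
        RAD2 <- RAD2 + (ctx$A4 * .sigma_sb * ctx$eps * f_dry) * p$f *
          (tk4 - (p$t_r + 273.15)^4)
    }
    psat <- p_sat_kpa(Tsk)
    e_dem <- sweat_rate * ctx$alpha_sw * (ctx$lambda / 14400)
    emax <- ctx$A4 * he * f_evap * (psat - st$p_air_mat)
    wett <- .clamp(e_dem / (.relu(emax) + 1e-300), 0.06, 1)
    EVA <- .relu(ctx$A4 * he * f_evap * (wett * psat - st$p_air_mat))
    res <- 0.0014 * Mcr[ctx$chest] * (34 - st$t_air_mean) +
      0.0173 * Mcr[ctx$chest] * (5.87 - st$p_air_mean)
  } else {
    CON <- EVA <- RAD1 <- RAD2 <- 0
    res <- 0
  }

  cond <- ctx$K4 * (Tcr - Tsk)
  perf <- w_sk_sec * (Tcr - Tsk)
  q_a_cr <- (w_cr + w_sk) * (Ta - Tcr)
  q_cr_a <- ctx$h_a * (Tcr - Ta)
  q_cr_v <- ctx$h_v * (Tcr - Tv)
  q_cr_vp <- w_cr * (Tcr - Tv)
  resv <- numeric(n); resv[ctx$chest] <- res

  # Perfusing blood enters the core at T_bl_a and leaves it at T_cr;
  # q_a_cr therefore carries the whole through-flow (core + skin
  # demand). The skin-bound share deposits w_sec (T_cr - T_sk) in the
  # skin and returns to the vein at skin temperature; the core-bound
  # share returns at T_cr (a vein gain, q_cr_vp). Neither return leg
  # may be subtracted from the core again - its loss is already
  # embodied in the through-flow discharge, and double-counting it
  # breaks energy conservation.
  dcr <- (Mcr - Wcr - .rowSums(cond, n, 4L) + q_a_cr -
            q_cr_a - q_cr_v - resv) / ctx$C_cr
  da <- (q_cr_a + w_a * (T_up - Ta)) / ctx$C_a
  dv <- (q_cr_v + q_cr_vp + heat_in - w_v * Tv) / ctx$C_v
  ang <- ctx$g_ang * (Tsk[, c(2L, 3L, 4L, 1L)] + Tsk[, c(4L, 1L, 2L, 3L)] -
                        2 * Tsk)
  dsk <- (ang + Msk4 + cond + perf - CON - EVA - RAD1 - RAD2) / ctx$C_sk4
  deriv <- c(dcr, da, dv, dsk, sweat_rate / 3600)

  if (!details) return(deriv)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, n, 4)
  CON <- as_mat(CON); EVA <- as_mat(EVA)
  RAD1 <- as_mat(RAD1); RAD2 <- as_mat(RAD2)
  list(deriv = deriv,
       flows = list(Q_cr_sk = cond, Q_perf_cr_sk = perf,
                    Q_perf_a_cr = q_a_cr, Q_cr_a = q_cr_a, Q_cr_v = q_cr_v,
                    Q_perf_cr_v = q_cr_vp, Q_adj_a = w_a * (T_up - Ta),
                    Q_adj_v = heat_in - w_v * Tv, RES = resv,
                    CON = CON, EVA = EVA, RAD1 = RAD1, RAD2 = RAD2,
                    ANG = ang),
       controls = list(m_sk_perfusion = m_sk, w_sk_sec = w_sk_sec,
                       sweat_total = sweat_rate, shiver = ctx$alpha_sh *
                         shiver_tot, wrms = wrms, clds = clds, D = D,
                       dHR = 4.75 * D,
                       mult = if (ctx$flags$metabolism &&
                                    st$t_air_mean >= 39)
                         pmax(1, 1 + 0.13 * (Tcr - 39)) else rep(1, n)),
       network = list(w_a = w_a, w_v = w_v, w_cr = w_cr, w_sk = w_sk))
}

#' Assembled right-hand side of the 105-node system
#'
#' Resolves the active-system outputs from the current state, builds the
#' conservative blood-flow network, evaluates every internal and boundary
#' heat flow and returns the full derivative vector (105 node
#' temperatures plus the cumulative-sweat rate).
#'
#' @param state a `bioheat_state`.
#' @param stage a `bioheat_stage` (boundary conditions).
#' @param ctx a `bioheat_context`.
#' @param details if `TRUE`, also return every heat flow and control
#'   output.
#' @return derivative vector (K/s and kg/s), or a list when
#'   `details = TRUE`.
#' @export
assemble_rhs <- function(state, stage, ctx, details = FALSE) {
  st <- .compile_stage(stage, ctx)
  out <- .rhs_raw(pack_state(state), st, ctx, details = details)
  d <- if (details) out$deriv else out
  if (anyNA(d) || any(!is.finite(d))) {
    bad <- which(!is.finite(d))[1]
    stop("non-finite derivative at node ", bad, " (",
         if (bad <= 7 * ctx$n) .node_label(bad, ctx) else "sweat", ")")
  }
  out
}

# Precompute the stage fields the RHS needs against a context: per-sector
# boundary matrices, panel view-factor matrices, and means.
.compile_stage <- function(stage, ctx) {
  if (isTRUE(stage$compiled)) return(stage)
  n <- ctx$n
  stage$t_air_mat <- matrix(stage$t_air, n, 4, byrow = TRUE)
  stage$p_air_mat <- matrix(stage$p_air, n, 4, byrow = TRUE)
  stage$t_air_mean <- mean(stage$t_air)
  stage$p_air_mean <- mean(stage$p_air)
  stage$panel_f <- lapply(stage$panels, function(p) {
    f <- matrix(0, n, 4)
    for (k in seq_len(nrow(p$targets))) {
      i <- match(p$targets$segment[k], ctx$names)
      j <- match(p$targets$sector[k], sector_names())
      if (is.na(i) || is.na(j))
        stop("unknown panel target: ", p$targets$segment[k], "/",
             p$targets$sector[k])
      zc <- ctx$z_c[i]
      f[i, j] <- view_factor_rect(p$x_offset - p$width / 2,
                                  p$x_offset + p$width / 2,
                                  p$z0 - zc, p$z0 + p$height - zc,
                                  p$distance)
    }
    list(f = f, t_r = p$t_r)
  })
  f_bg <- 1
  if (length(stage$panel_f)) {
    f_bg <- matrix(1, n, 4)
    for (p in stage$panel_f) f_bg <- f_bg - p$f
    f_bg[f_bg < 0] <- 0
  }
  stage$f_bg <- f_bg
  stage$compiled <- TRUE
  stage
}
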