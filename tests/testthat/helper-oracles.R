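# Independent oracles used only by the test suite: a 2-segment toy body
# with a scalar, loop-based re-implementation of the node energy
# balances; a brute-force quadrature view-factor oracle; and a
# reproducible random-state generator. None of these share code paths
# with the package internals they check.

toy_body <- function() {
  seg <- data.frame(
    name = c("chest", "limb"),
    A = c(0.2, 0.1), M_cr = c(10, 2), M_sk = c(0.5, 0.2),
    C_cr = c(20000, 5000), C_bl_a = c(1000, 50), C_bl_v = c(3000, 150),
    C_sk = c(8000, 2000), K_cr_sk = c(4, 1.5),
    m_sk_basal = c(2000, 1000), m_sk_min = c(0, 100),
    m_sk_max = c(20000, 8000),
    L_n = c(0.3, 0.3), z_c = c(1.2, 0.8), stringsAsFactors = FALSE)
  seg$r <- seg$A / (2 * pi * seg$L_n)
  seg$th_sk <- 0.001; seg$K_sk <- 0.47; seg$epsilon <- 0.95; seg$W_cr <- 0
  th <- default_body()$thermo
  th$T_sk0 <- c(34, 34)
  th$alpha_sk <- c(0.6, 0.4)
  th$alpha_sh <- c(0.7, 0.3)
  th$alpha_sw <- c(0.5, 0.5)
  th$co_core <- 50000
  structure(list(segments = seg, thermo = th), class = "bioheat_body")
}

toy_network <- function(body = toy_body()) {
  blood_network(body, parent = c(chest = NA, limb = "chest"))
}

toy_context <- function(body = toy_body(), ...) {
  build_context(body, toy_network(body), ...)
}

toy_env <- function(t_air = 29, rh = 0.5, ...) {
  environment_stage(600, t_air = t_air, rh = rh, ...)
}

# Scalar oracle for the toy body's derivative vector: plain loops, every
# term written out from the segment balances. State layout matches
# pack_state: (T_cr[2], T_a[2], T_v[2], T_sk[2x4 col-major], sweat).
scalar_rhs_oracle <- function(y, env, body = toy_body()) {
  seg <- body$segments; th <- body$thermo
  sigma <- 5.670374419e-8
  n <- 2
  Tcr <- y[1:2]; Ta <- y[3:4]; Tv <- y[5:6]
  Tsk <- matrix(y[7:14], 2, 4)
  sweat <- y[15]
  D <- 100 * sweat / th$body_mass_ref
  t_air <- rep_len(env$t_air, 4); p_air <- rep_len(env$p_air, 4)
  t_air_mean <- mean(t_air); p_air_mean <- mean(p_air)

  # --- controller (reference segment = first, chest-like) ---
  wrms <- 0; clds <- 0
  for (i in 1:n) {
    e <- mean(Tsk[i, ]) - th$T_sk0[i]
    wrms <- wrms + th$alpha_sk[i] * max(e, 0)
    clds <- clds + th$alpha_sk[i] * max(-e, 0)
  }
  wrm_cr <- max(Tcr[1] - th$T_cr_set, 0)
  cld_cr <- max(th$T_cr_set - Tcr[1], 0)
  g <- th$gains
  dl <- g$dil_cr * wrm_cr + g$dil_sk * wrms
  stq <- g$con_cr * cld_cr + g$con_sk * clds
  m_sk <- numeric(n)
  for (i in 1:n)
    m_sk[i] <- min(max((seg$m_sk_basal[i] + dl * th$alpha_sk[i]) /
                         (1 + stq * th$alpha_sk[i]),
                       seg$m_sk_min[i]), seg$m_sk_max[i])
  sweat_rate <- max(max(0.2898 - 0.068 * D, 0) *
                      (Tcr[1] - th$T_head_set_sweat - 0.06 * D) +
                      0.03364 * wrms - clds, 0)
  shiver_tot <- g$sh * cld_cr * clds
  mult <- numeric(n)
  for (i in 1:n)
    mult[i] <- if (t_air_mean >= 39) 1 + 0.13 * max(Tcr[i] - 39, 0) else 1
  Mcr <- mult * seg$M_cr + th$alpha_sh * shiver_tot

  # --- flows ---
  to_wk <- 1e-6 / 3600 * th$rho_bl * th$c_bl
  w_cr <- th$co_core * seg$M_cr / sum(seg$M_cr) * to_wk
  w_sk <- m_sk * to_wk
  w_sec <- matrix(0, n, 4)
  for (i in 1:n) {
    dbar <- Tsk[i, ] - mean(Tsk[i, ])
    pos <- sum(pmax(dbar, 0))
    for (j in 1:4)
      w_sec[i, j] <- w_sk[i] *
        (if (pos > 0) 0.25 * (1 + dbar[j] / pos) else 0.25)
  }
  demand <- w_cr + w_sk
  w_a <- c(demand[1] + demand[2], demand[2])  # limb feeds from chest
  h_a <- th$kappa_vessel * seg$C_bl_a
  h_v <- th$kappa_vessel * seg$C_bl_v

  # --- boundary ---
  lam <- th$lambda_sweat
  CON <- EVA <- RAD <- matrix(0, n, 4)
  for (i in 1:n) {
    a4 <- seg$A[i] / 4
    for (j in 1:4) {
      CON[i, j] <- a4 * env$h_c * (Tsk[i, j] - t_air[j])
      RAD[i, j] <- a4 * env$h_r * (Tsk[i, j] - env$t_mrt)
      psat <- 0.133322 * 10^(8.07131 - 1730.63 / (233.426 + Tsk[i, j]))
      e_dem <- sweat_rate * th$alpha_sw[i] * lam / 3600 / 4
      emax <- a4 * env$h_e * (psat - p_air[j])
      w <- if (emax > 0) min(max(e_dem / emax, 0.06), 1) else
        if (e_dem > 0) 1 else 0.06
      EVA[i, j] <- max(a4 * env$h_e * (w * psat - p_air[j]), 0)
    }
  }
  res <- 0.0014 * Mcr[1] * (34 - t_air_mean) +
    0.0173 * Mcr[1] * (5.87 - p_air_mean)

  # --- node balances ---
  dcr <- da <- dv <- numeric(n)
  dsk <- matrix(0, n, 4)
  for (i in 1:n) {
    cond_i <- sum(seg$K_cr_sk[i] / 4 * (Tcr[i] - Tsk[i, ]))
    q_a_cr <- (w_cr[i] + w_sk[i]) * (Ta[i] - Tcr[i])
    q_cr_a <- h_a[i] * (Tcr[i] - Ta[i])
    q_cr_v <- h_v[i] * (Tcr[i] - Tv[i])
    dcr[i] <- (Mcr[i] - seg$W_cr[i] - cond_i + q_a_cr - q_cr_a - q_cr_v -
                 (if (i == 1) res else 0)) / seg$C_cr[i]
    t_up <- if (i == 1) Tv[1] else Ta[1]
    da[i] <- (q_cr_a + w_a[i] * (t_up - Ta[i])) / seg$C_bl_a[i]
    # venous mixture: local skin returns, plus (chest) the limb return
    hin <- sum(w_sec[i, ] * Tsk[i, ])
    wv <- w_sk[i]
    if (i == 1) { hin <- hin + w_a[2] * Tv[2]; wv <- wv + w_a[2] }
    dv[i] <- (q_cr_v + w_cr[i] * (Tcr[i] - Tv[i]) + hin - wv * Tv[i]) /
      seg$C_bl_v[i]
    gang <- seg$K_sk[i] * seg$L_n[i] * seg$th_sk[i] / seg$r[i]^2 / (pi / 2)^2
    for (j in 1:4) {
      jp <- if (j == 4) 1 else j + 1
      jm <- if (j == 1) 4 else j - 1
      ang <- gang * (Tsk[i, jp] + Tsk[i, jm] - 2 * Tsk[i, j])
      dsk[i, j] <- (ang + mult[i] * seg$M_sk[i] / 4 +
                      seg$K_cr_sk[i] / 4 * (Tcr[i] - Tsk[i, j]) +
                      w_sec[i, j] * (Tcr[i] - Tsk[i, j]) -
                      CON[i, j] - EVA[i, j] - RAD[i, j]) / (seg$C_sk[i] / 4)
    }
  }
  c(dcr, da, dv, as.vector(dsk), sweat_rate / 3600)
}

# Brute-force view factor between two parallel rectangles by midpoint
# quadrature of cos t1 cos t2 / (pi S^2) over both surfaces. rect = list
# (x1, x2, z1, z2); the second rectangle lies in a plane at distance d.
quadrature_view_factor <- function(r1, r2, d, res = 64) {
  gx1 <- seq(r1$x1, r1$x2, length.out = res + 1); gx1 <- (gx1[-1] + gx1[-(res + 1)]) / 2
  gz1 <- seq(r1$z1, r1$z2, length.out = res + 1); gz1 <- (gz1[-1] + gz1[-(res + 1)]) / 2
  gx2 <- seq(r2$x1, r2$x2, length.out = res + 1); gx2 <- (gx2[-1] + gx2[-(res + 1)]) / 2
  gz2 <- seq(r2$z1, r2$z2, length.out = res + 1); gz2 <- (gz2[-1] + gz2[-(res + 1)]) / 2
  a1 <- (r1$x2 - r1$x1) * (r1$z2 - r1$z1)
  dA1 <- a1 / res^2
  dA2 <- (r2$x2 - r2$x1) * (r2$z2 - r2$z1) / res^2
  p1 <- expand.grid(x = gx1, z = gz1)
  p2 <- expand.grid(x = gx2, z = gz2)
  total <- 0
  for (k in seq_len(nrow(p1))) {
    dx <- p2$x - p1$x[k]
    dz <- p2$z - p1$z[k]
    s2 <- dx^2 + dz^2 + d^2
    total <- total + sum(d^2 / (pi * s2^2)) * dA2 * dA1
  }
  total / a1
}

# Reproducible physiological-range random states (temperatures within
# 30-41 C, dehydration within 0-3 % of body mass).
random_body_state <- function(seed, n = 15) {
  set.seed(seed)
  body_state(runif(n, 36, 40), runif(n, 34, 39), runif(n, 33, 39),
             matrix(runif(4 * n, 30, 41), n, 4),
             sweat_cumulative = runif(1, 0, 0.03) * 74.30)
}
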