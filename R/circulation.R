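# Artery/vein blood network: a directed tree rooted at the chest
# (heart). Arterial flow is accumulated leaf-to-root so that every
# branch point conserves mass; venous flows mirror the arterial side,
# with skin perfusion returning to the local vein.

#' Blood network topology
#'
#' Builds the conservative flow tree over the body's segments. The chest
#' is the root (heart); the default chains are chest-head,
#' chest-abdomen-thigh-calf-foot per side, and
#' chest-upper arm-forearm-hand per side. Core-vessel convective
#' conductances default to `kappa_vessel` times the vessel heat
#' capacitance of each segment.
#'
#' @param body a `bioheat_body`.
#' @param parent optional named character vector overriding the topology:
#'   `parent["segment"] = "parent segment"`, with the root mapped to `NA`.
#' @return list of class `bioheat_network` with `parent` (index vector, 0
#'   at the root), `order` (child-before-parent traversal of non-root
#'   segments), `root`, and conductances `h_a`, `h_v` (W/K).
#' @export
blood_network <- function(body, parent = NULL) {
  nm <- body$segments$name
  if (is.null(parent)) {
    parent <- c(head = "chest", chest = NA, abdomen = "chest",
                upper_arm_l = "chest", upper_arm_r = "chest",
                forearm_l = "upper_arm_l", forearm_r = "upper_arm_r",
                hand_l = "forearm_l", hand_r = "forearm_r",
                thigh_l = "abdomen", thigh_r = "abdomen",
                calf_l = "thigh_l", calf_r = "thigh_r",
                foot_l = "calf_l", foot_r = "calf_r")
  }
  if (!setequal(names(parent), nm))
    stop("network topology must cover every segment exactly once")
  pidx <- match(parent[nm], nm)
  pidx[is.na(parent[nm])] <- 0L
  root <- which(pidx == 0L)
  if (length(root) != 1) stop("network must have exactly one root")
  # depth-sorted traversal: deepest first => children visited before parents
  depth <- integer(length(nm))
  for (i in seq_along(nm)) {
    k <- i; d <- 0L
    while (pidx[k] != 0L) {
      k <- pidx[k]; d <- d + 1L
      if (d > length(nm)) stop("cycle in network topology")
    }
    depth[i] <- d
  }
  ord <- setdiff(order(depth, decreasing = TRUE), root)
  kappa <- body$thermo$kappa_vessel
  structure(list(parent = pidx, order = ord, root = root, names = nm,
                 h_a = kappa * body$segments$C_bl_a,
                 h_v = kappa * body$segments$C_bl_v),
            class = "bioheat_network")
}

#' Update blood flows from perfusion demands
#'
#' Accumulates arterial mass flow leaf-to-root so that the flow entering
#' each segment equals its local consumption (core perfusion plus skin
#' perfusion) plus everything passed on to distal segments; venous return
#' mirrors the arterial side, so the heart outflow equals the total
#' venous return by construction.
#'
#' @param network a `bioheat_network`.
#' @param m_cr per-segment core perfusion, cm^3/h.
#' @param m_sk per-segment total skin perfusion, cm^3/h.
#' @param rho_bl blood density, kg/m^3.
#' @return list with `m_a` (arterial mass flow through each segment,
#'   kg/s), `m_v` (venous mass flow, kg/s, equal to `m_a`), `demand`
#'   (local consumption, kg/s) and `heart_outflow` (kg/s).
#' @export
update_flows <- function(network, m_cr, m_sk, rho_bl = 1059) {
  if (any(m_cr < 0) || any(m_sk < 0)) stop("perfusion demands must be >= 0")
  to_kgs <- 1e-6 / 3600 * rho_bl
  demand <- (m_cr + m_sk) * to_kgs
  m_a <- demand
  for (k in network$order) {
    p <- network$parent[k]
    m_a[p] <- m_a[p] + m_a[k]
  }
  list(m_a = m_a, m_v = m_a, demand = demand,
       heart_outflow = m_a[network$root])
}

#' Basal core perfusion
#'
#' Distributes the basal core blood flow over segments in proportion to
#' their basal core metabolic rate, scaled to the configured total
#' (`thermo$co_core`, cm^3/h).
#'
#' @param body a `bioheat_body`.
#' @return per-segment core perfusion, cm^3/h.
#' @export
core_perfusion <- function(body) {
  m <- body$segments$M_cr
  body$thermo$co_core * m / sum(m)
}
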