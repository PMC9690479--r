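# Staged-scenario execution: pre-equilibration, fixed-step RK4 (or
# adaptive stiff) integration across environment stages, result
# containers and writers, and the packaged validation-protocol fixtures.

#' Simulation scenario
#'
#' Bundles everything a run needs: the body, clothing, the time-staged
#' environment, the blood-network topology, physics flags and integrator
#' settings. The initial state defaults to the neutral steady state found
#' by [equilibrate()] under the first stage's environment.
#'
#' @param stages list of [environment_stage()] objects, executed in order.
#' @param body a `bioheat_body` (default standard body).
#' @param clothing a [clothing_spec()] (default nude).
#' @param network optional `bioheat_network` topology override.
#' @param flags physics flags passed to [build_context()].
#' @param dt integrator step, s. @param cadence output sampling, s.
#' @param method `"rk4"` (fixed step, default) or `"lsoda"` (adaptive
#'   stiff).
#' @param initial optional `bioheat_state` used at t = 0.
#' @param seed integer stored with the scenario; the simulation itself is
#'   deterministic, the seed is reserved for stochastic variants.
#' @param name scenario label.
#' @return object of class `bioheat_scenario`.
#' @export
scenario <- function(stages, body = default_body(),
                     clothing = clothing_spec(), network = NULL,
                     flags = list(), dt = 1, cadence = 60,
                     method = c("rk4", "lsoda"), initial = NULL,
                     seed = 1L, name = "scenario") {
  method <- match.arg(method)
  stopifnot(length(stages) >= 1)
  total <- sum(vapply(stages, `[[`, numeric(1), "duration"))
  if (total <= 0) stop("total duration must be positive")
  if (cadence > total) stop("output cadence must not exceed total duration")
  structure(list(stages = stages, body = body, clothing = clothing,
                 network = network, flags = flags, dt = dt,
                 cadence = cadence, method = method, initial = initial,
                 seed = seed, name = name),
            class = "bioheat_scenario")
}

#' Packaged validation-protocol fixtures
#'
#' Two staged exposure protocols ship with the package:
#' \describe{
#'   \item{`uniform-fourstage`}{Four 30-min stages alternating a neutral
#'     (29 C, 50% RH) and a hot (45 C, 30% RH) uniform environment;
#'     subjects wearing only shorts (light cover on abdomen and thighs).}
#'   \item{`fanger-warmwall`}{One hour facing an unheated wall (23 C),
#'     then five 30-min stages with the wall at 32.6, 42, 51.6, 61.1 and
#'     70.1 C while the air temperature is lowered to 21.9, 20.7, 19.3,
#'     17.9 and 16.7 C to keep the operative temperature stable. The wall
#'     is a 2.5 m x 2.5 m vertical panel 0.5 m to the body's left,
#'     irradiating the left-facing (exterior) sectors; the subject wears
#'     a standard uniform (trunk and limbs clothed, head and hands
#'     bare).}
#' }
#'
#' @param name fixture name.
#' @param ... overrides passed on to [scenario()] (e.g. `dt`, `cadence`).
#' @return a `bioheat_scenario`.
#' @export
fixture_scenario <- function(name = c("uniform-fourstage",
                                      "fanger-warmwall"), ...) {
  name <- match.arg(name)
  if (name == "uniform-fourstage") {
    shorts <- clothing_spec(c("abdomen", "thigh_l", "thigh_r"),
                            i_cl = 0.016, r_ecl = 0.003)
    stages <- list(
      environment_stage(1800, t_air = 29, rh = 0.50),
      environment_stage(1800, t_air = 45, rh = 0.30),
      environment_stage(1800, t_air = 29, rh = 0.50),
      environment_stage(1800, t_air = 45, rh = 0.30))
    scenario(stages, clothing = shorts, name = name, ...)
  } else {
    uniform <- clothing_spec(
      c("chest", "abdomen", "upper_arm_l", "upper_arm_r",
        "forearm_l", "forearm_r", "thigh_l", "thigh_r",
        "calf_l", "calf_r", "foot_l", "foot_r"),
      i_cl = 0.093, r_ecl = 0.015)
    wall <- function(t_r) radiant_panel(t_r, width = 2.5, height = 2.5,
                                        distance = 0.5, side = "left")
    p_air <- 0.5 * p_sat_kpa(23)  # chamber vapor pressure held constant
    walls <- c(23, 32.6, 42, 51.6, 61.1, 70.1)
    airs <- c(23, 21.9, 20.7, 19.3, 17.9, 16.7)
    durs <- c(3600, rep(1800, 5))
    stages <- Map(function(d, ta, tr)
      environment_stage(d, t_air = ta, p_air = p_air, t_mrt = ta,
                        panels = list(wall(tr))),
      durs, airs, walls)
    scenario(stages, clothing = uniform, name = name, ...)
  }
}

#' Find the regulated steady state
#'
#' Integrates the full system under a constant environment with an
#' adaptive stiff solver until the temperature derivatives vanish, and
#' returns that state (with the sweat accumulator and clock reset) for
#' use as the initial condition of a staged run.
#'
#' @param scn a `bioheat_scenario`; its first stage defines the
#'   environment (pass a single-stage neutral scenario to equilibrate at
#'   29 C, 50% RH).
#' @param t_max integration horizon, model-s.
#' @param tol convergence criterion on `max |dT/dt|`, K/s.
#' @param guess optional starting `bioheat_state`.
#' @return the equilibrium `bioheat_state`.
#' @export
equilibrate <- function(scn, t_max = 1e4, tol = 1e-7, guess = NULL) {
  ctx <- build_context(scn$body, .scn_network(scn), scn$clothing, scn$flags)
  st <- .compile_stage(scn$stages[[1]], ctx)
  n <- ctx$n
  if (is.null(guess)) {
    guess <- body_state(rep(36.8, n), rep(36.6, n), rep(36.4, n),
                        matrix(34, n, 4))
  }
  y0 <- pack_state(guess)
  # Under an angularly uniform environment the steady state is solved in
  # the reduced symmetric space (one skin node per segment): the sector
  # perfusion redistribution makes asymmetric near-equilibria reachable
  # from numerical noise, and the returned state must be exactly
  # sector-symmetric.
  uniform <- length(st$panels) == 0 &&
    length(unique(st$t_air)) == 1 && length(unique(st$p_air)) == 1
  if (uniform) {
    reduce <- function(y) c(y[seq_len(3 * n)], y[3 * n + seq_len(n)],
                            y[ctx$i_sw])
    expand <- function(x) c(x[seq_len(3 * n)],
                            rep(x[3 * n + seq_len(n)], 4), x[4 * n + 1])
    nt <- 4 * n
  } else {
    reduce <- identity
    expand <- identity
    nt <- 7 * n
  }
  f <- function(t, x, parms)
    list(reduce(.rhs_raw(expand(x), st, ctx))[c(seq_len(nt), nt + 1)])
  sol <- deSolve::lsoda(reduce(y0), c(0, t_max), f, rtol = 1e-8,
                        atol = 1e-8, maxsteps = 1e5)
  y <- expand(sol[nrow(sol), -1])
  y <- .steady_polish(y, st, ctx, tol = tol, reduce = reduce,
                      expand = expand, nt = nt)
  resid <- max(abs(.rhs_raw(y, st, ctx)[seq_len(7 * ctx$n)]))
  if (resid > tol)
    stop(sprintf("equilibration did not converge: max |dT/dt| = %.3g K/s",
                 resid))
  check_state(y, ctx, t = t_max)
  out <- unpack_state(y, ctx)
  out$sweat_cumulative <- 0
  out$t <- 0
  out
}

# Damped-Newton polish of the temperature steady state, solved in
# heat-flux form (C dT/dt, W) so rows are comparably scaled across the
# three-orders-of-magnitude capacitance range. The sweat accumulator is
# held fixed: it has no steady value once sweating is active, and the
# controller depends on it only through D.
.steady_polish <- function(y, st, ctx, tol = 1e-7, max_iter = 30,
                           reduce = identity, expand = identity,
                           nt = 7 * ctx$n) {
  caps_full <- c(ctx$C_cr, ctx$C_a, ctx$C_v, rep(ctx$C_sk4, 4))
  caps <- reduce(c(caps_full, 1))[seq_len(nt)]
  sweat <- y[ctx$i_sw]
  fres <- function(x) {
    yy <- expand(c(x, sweat))
    caps * reduce(c(.rhs_raw(yy, st, ctx)[seq_len(7 * ctx$n)], 0))[seq_len(nt)]
  }
  x <- reduce(y)[seq_len(nt)]
  fx <- fres(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(fx / caps)) < tol) break
    J <- matrix(0, nt, nt)
    h <- 1e-5
    for (j in seq_len(nt)) {
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (fres(xp) - fx) / h
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- fres(xn)
      if (sqrt(sum(fn^2)) < (1 - 1e-4 * lam) * sqrt(sum(fx^2)) ||
            lam < 1 / 64) break
      lam <- lam / 2
    }
    x <- xn; fx <- fn
  }
  expand(c(x, sweat))
}

.scn_network <- function(scn) {
  if (is.null(scn$network)) blood_network(scn$body) else scn$network
}

#' Run a staged simulation
#'
#' Integrates the 105-node system across the scenario's stages (state
#' continuous across stage boundaries, environment piecewise constant),
#' sampling the state and regulatory outputs at the output cadence.
#' Deterministic: identical inputs give identical outputs.
#'
#' @param scn a `bioheat_scenario`.
#' @return object of class `bioheat_result`: a list with `time` (s),
#'   `stage` (stage index per sample), temperature matrices `T_cr`,
#'   `T_bl_a`, `T_bl_v` (samples x segments), `T_sk` (samples x segments
#'   x 4 array), `T_sk_mean_seg`, `T_sk_mean_body` (area-weighted),
#'   `sweat_cumulative`, `sweat_rate`, `D`, `dHR`, `m_sk_perfusion`, and
#'   boundary-flux arrays `CON`, `EVA`, `RAD` (samples x segments x 4).
#' @export
run_simulation <- function(scn) {
  ctx <- build_context(scn$body, .scn_network(scn), scn$clothing, scn$flags)
  state0 <- if (is.null(scn$initial)) equilibrate(scn) else scn$initial
  y <- pack_state(state0)
  dt <- scn$dt
  cadence <- scn$cadence
  durs <- vapply(scn$stages, `[[`, numeric(1), "duration")
  bounds <- cumsum(c(0, durs))
  total <- bounds[length(bounds)]
  rec_t <- sort(unique(c(seq(0, total, by = cadence), bounds)))
  nrec <- length(rec_t)
  Y <- matrix(NA_real_, nrec, length(y))
  stage_of <- pmin(findInterval(rec_t, bounds, left.open = TRUE) , length(durs))
  stage_of[1] <- 1L
  Y[1, ] <- y
  ri <- 2L
  t_now <- 0
  for (s in seq_along(scn$stages)) {
    st <- .compile_stage(scn$stages[[s]], ctx)
    t_end <- bounds[s + 1]
    while (t_now < t_end - 1e-9) {
      h <- min(dt, t_end - t_now)
      # record points falling inside this step are snapped to step ends;
      # rec_t is aligned with dt and stage bounds for default settings
      y <- .rk4_step(y, h, st, ctx)
      t_now <- t_now + h
      while (ri <= nrec && rec_t[ri] <= t_now + 1e-9) {
        Y[ri, ] <- y
        ri <- ri + 1L
      }
    }
    check_state(y, ctx, t = t_now)
  }
  .build_result(rec_t, stage_of, Y, scn, ctx)
}

.rk4_step <- function(y, h, st, ctx) {
  k1 <- .rhs_raw(y, st, ctx)
  k2 <- .rhs_raw(y + h / 2 * k1, st, ctx)
  k3 <- .rhs_raw(y + h / 2 * k2, st, ctx)
  k4 <- .rhs_raw(y + h * k3, st, ctx)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

.build_result <- function(time, stage, Y, scn, ctx) {
  n <- ctx$n
  nrec <- nrow(Y)
  T_sk <- array(Y[, ctx$i_sk], dim = c(nrec, n, 4),
                dimnames = list(NULL, ctx$names, sector_names()))
  tskm_seg <- apply(T_sk, c(1, 2), mean)
  aw <- (ctx$A4 * 4) / sum(ctx$A4 * 4)
  CON <- EVA <- RAD <- array(0, dim = c(nrec, n, 4),
                             dimnames = dimnames(T_sk))
  sweat_rate <- numeric(nrec)
  m_sk <- matrix(NA_real_, nrec, n, dimnames = list(NULL, ctx$names))
  for (i in seq_len(nrec)) {
    st <- .compile_stage(scn$stages[[stage[i]]], ctx)
    det <- .rhs_raw(Y[i, ], st, ctx, details = TRUE)
    CON[i, , ] <- det$flows$CON
    EVA[i, , ] <- det$flows$EVA
    RAD[i, , ] <- det$flows$RAD1 + det$flows$RAD2
    sweat_rate[i] <- det$controls$sweat_total
    m_sk[i, ] <- det$controls$m_sk_perfusion
  }
  sweat <- Y[, ctx$i_sw]
  D <- dehydration_percent(sweat, ctx$body_mass_ref)
  structure(list(
    time = time, stage = stage,
    T_cr = `colnames<-`(Y[, ctx$i_cr, drop = FALSE], ctx$names),
    T_bl_a = `colnames<-`(Y[, ctx$i_a, drop = FALSE], ctx$names),
    T_bl_v = `colnames<-`(Y[, ctx$i_v, drop = FALSE], ctx$names),
    T_sk = T_sk,
    T_sk_mean_seg = tskm_seg,
    T_sk_mean_body = as.vector(tskm_seg %*% aw),
    sweat_cumulative = sweat, sweat_rate = sweat_rate,
    D = D, dHR = heart_rate_increase(D),
    m_sk_perfusion = m_sk,
    CON = CON, EVA = EVA, RAD = RAD,
    scenario_name = scn$name
  ), class = "bioheat_result")
}

#' Write a simulation result
#'
#' Writes a tidy long-format CSV (`time, segment, node, sector, value`)
#' holding every node temperature and the whole-body regulatory outputs,
#' plus a JSON run manifest (resolved scenario summary, package version,
#' invariant-check summary).
#'
#' @param result a `bioheat_result`.
#' @param dir output directory (created if missing).
#' @param stem file name stem.
#' @return paths of the files written, invisibly.
#' @export
write_result <- function(result, dir, stem = "result") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  segs <- colnames(result$T_cr)
  nt <- length(result$time)
  long <- function(mat, node) data.frame(
    time = rep(result$time, times = ncol(mat)),
    segment = rep(colnames(mat), each = nt),
    node = node, sector = NA_character_,
    value = as.vector(mat), stringsAsFactors = FALSE)
  sk <- do.call(rbind, lapply(seq_len(4), function(j) {
    d <- long(result$T_sk[, , j], "skin")
    d$sector <- sector_names()[j]
    d
  }))
  aux <- function(vec, node) data.frame(
    time = result$time, segment = "body", node = node,
    sector = NA_character_, value = vec, stringsAsFactors = FALSE)
  out <- rbind(long(result$T_cr, "core"),
               long(result$T_bl_a, "artery"),
               long(result$T_bl_v, "vein"),
               sk,
               aux(result$sweat_cumulative, "sweat_cumulative"),
               aux(result$sweat_rate, "sweat_rate"),
               aux(result$D, "dehydration"),
               aux(result$dHR, "heart_rate_increase"),
               aux(result$T_sk_mean_body, "t_sk_mean"))
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(out, csv, row.names = FALSE)
  manifest <- list(
    package = "bioheatr",
    version = as.character(utils::packageVersion("bioheatr")),
    scenario = result$scenario_name,
    samples = nt,
    duration_s = max(result$time),
    invariants = list(
      finite = all(is.finite(result$T_cr)) && all(is.finite(result$T_sk)),
      temp_min = min(result$T_sk, result$T_cr),
      temp_max = max(result$T_sk, result$T_cr),
      dehydration_monotone = !is.unsorted(result$D)
    ))
  js <- file.path(dir, paste0(stem, "-manifest.json"))
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, manifest = js))
}

#' Read back a result CSV
#'
#' Reconstructs the temperature trajectories written by [write_result()].
#'
#' @param path CSV path.
#' @return list with `time`, `T_cr`, `T_bl_a`, `T_bl_v`, `T_sk` matrices/
#'   array and the auxiliary series.
#' @export
read_result_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  time <- sort(unique(d$time))
  wide <- function(node) {
    sub <- d[d$node == node, ]
    segs <- unique(sub$segment)
    m <- matrix(NA_real_, length(time), length(segs),
                dimnames = list(NULL, segs))
    m[cbind(match(sub$time, time), match(sub$segment, segs))] <- sub$value
    m
  }
  sk <- d[d$node == "skin", ]
  segs <- unique(sk$segment)
  arr <- array(NA_real_, c(length(time), length(segs), 4),
               dimnames = list(NULL, segs, sector_names()))
  arr[cbind(match(sk$time, time), match(sk$segment, segs),
            match(sk$sector, sector_names()))] <- sk$value
  auxv <- function(node) d[d$node == node, "value"][order(d[d$node == node, "time"])]
  list(time = time, T_cr = wide("core"), T_bl_a = wide("artery"),
       T_bl_v = wide("vein"), T_sk = arr,
       sweat_cumulative = auxv("sweat_cumulative"),
       D = auxv("dehydration"), dHR = auxv("heart_rate_increase"),
       t_sk_mean = auxv("t_sk_mean"))
}

#' Validate a run manifest against the shipped schema
#'
#' @param manifest list (parsed JSON) or path to a manifest file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  schema <- jsonlite::read_json(
    system.file("extdata", "manifest-schema.json", package = "bioheatr"),
    simplifyVector = TRUE)
  for (k in schema$required)
    if (is.null(manifest[[k]])) stop("manifest missing required key: ", k)
  for (k in names(schema$properties)) {
    tp <- schema$properties[[k]]$type
    if (is.null(manifest[[k]])) next
    ok <- switch(tp,
                 string = is.character(manifest[[k]]),
                 number = is.numeric(manifest[[k]]),
                 object = is.list(manifest[[k]]),
                 TRUE)
    if (!ok) stop("manifest key ", k, " must have type ", tp)
  }
  invisible(TRUE)
}

#' Minimal trajectory plot
#'
#' Core and mean skin temperature against time, base graphics.
#'
#' @param result a `bioheat_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_trajectory <- function(result, ...) {
  graphics::matplot(result$time / 60,
                    cbind(result$T_cr[, "head"], result$T_sk_mean_body),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "time (min)", ylab = "temperature (C)", ...)
  graphics::legend("topleft", c("head core", "mean skin"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
}
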