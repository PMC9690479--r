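test_that("core balance reproduces direct scalar cases", {
  expect_identical(core_rhs(C_cr = 12247.1), 0)          # equilibrium
  expect_equal(core_rhs(C_cr = 12247.1, M_cr = 18.433), 18.433 / 12247.1)
  # antisymmetry: a flow entering the skin leaves the core
  q <- c(1.2, 0.3, -0.4, 0.8)
  d_core <- core_rhs(C_cr = 1000, q_cr_sk = q)
  d_skin <- sum(vapply(q, function(qi)
    skin_sector_rhs(C_sk_sector = 250, q_cr_sk = qi), numeric(1)))
  expect_equal(1000 * d_core + 250 * d_skin, 0, tolerance = 1e-12)
})

test_that("respiratory heat loss follows the two-term correlation", {
  expect_identical(respiratory_heat_loss(100, 34, 5.87), 0)
  expect_identical(respiratory_heat_loss(0, 20, 1), 0)
  expect_equal(respiratory_heat_loss(100, 24, 2.0),
               0.0014 * 100 * 10 + 0.0173 * 100 * 3.87)
  expect_equal(respiratory_heat_loss(100, 24, 2.0), 8.095, tolerance = 1e-3)
  expect_lt(respiratory_heat_loss(100, 45, 7), 0)  # hot humid air: gain
})

test_that("angular conduction conserves heat on the periodic sector ring", {
  g <- 0.01
  expect_identical(angular_conduction(rep(33, 4), g), rep(0, 4))
  # pattern (T, T+d, T, T-d): opposite sectors carry equal and opposite
  # conduction, adjacent ones none
  a <- angular_conduction(c(34, 34.5, 34, 33.5), g)
  expect_identical(a[1], 0); expect_identical(a[3], 0)
  expect_equal(a[2], -a[4])
  for (seed in 1:50) {
    set.seed(seed)
    expect_lt(abs(sum(angular_conduction(runif(4, 25, 40), g))), 1e-15)
  }
})

test_that("perfusion redistribution favours hot sectors and conserves flow", {
  expect_identical(perfusion_redistribution(rep(34, 4), 400),
                   rep(100, 4))  # isothermal fallback
  expect_equal(perfusion_redistribution(c(35, 34, 34, 33), 400),
               c(200, 100, 100, 0))
  for (seed in 1:200) {
    set.seed(seed)
    t_sk <- runif(4, 28, 40)
    total <- runif(1, 0, 30000)
    m <- perfusion_redistribution(t_sk, total)
    expect_lt(abs(sum(m) - total), 1e-12 * max(total, 1))
    expect_true(all(m >= 0))
    expect_equal(order(m), order(t_sk))  # hotter sector, more flow
  }
})

test_that("assembled derivative has the full node count and flags work", {
  body <- default_body()
  ctx <- build_context(body)
  stg <- environment_stage(600, t_air = 29, rh = 0.5)
  d <- assemble_rhs(uniform_state(34), stg, ctx)
  expect_length(d, 105 + 1)  # temperatures plus cumulative sweat

  # isothermal body at environment temperature with metabolism and
  # sweating off: exact equilibrium
  ctx0 <- build_context(body, flags = list(metabolism = FALSE,
                                           active = FALSE))
  stg0 <- environment_stage(600, t_air = 34, rh = 0.5, t_mrt = 34)
  d0 <- assemble_rhs(uniform_state(34), stg0, ctx0)
  expect_lt(max(abs(d0)), 1e-12)

  # adiabatic body: d/dt of total enthalpy equals total metabolic heat
  ctxA <- build_context(body, flags = list(boundary = FALSE,
                                           active = FALSE))
  caps <- c(ctxA$C_cr, ctxA$C_a, ctxA$C_v, rep(ctxA$C_sk4, 4))
  dA <- assemble_rhs(random_body_state(7), stg, ctxA)
  expect_equal(sum(caps * dA[1:105]),
               sum(body$segments$M_cr + body$segments$M_sk -
                     body$segments$W_cr),
               tolerance = 1e-9)
})

test_that("state sanity checks flag the offending node", {
  ctx <- build_context(default_body())
  y <- pack_state(uniform_state(34))
  expect_true(check_state(y, ctx))
  y_bad <- y
  y_bad[16] <- 75  # first artery node
  expect_error(check_state(y_bad, ctx), "head/artery")
  y_nan <- y; y_nan[50] <- NaN
  expect_error(check_state(y_nan, ctx), "state invariant")
})

test_that("production RHS matches the independent scalar oracle on the toy body", {
  body <- toy_body()
  ctx <- toy_context(body)
  env <- bioheatr:::.compile_stage(toy_env(), ctx)
  for (seed in 1:20) {
    y <- pack_state(random_body_state(seed, n = 2))
    d_prod <- bioheatr:::.rhs_raw(y, env, ctx)
    d_orc <- scalar_rhs_oracle(y, env, body)
    expect_equal(d_prod, d_orc, tolerance = 1e-13)
  }
})
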