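test_that("convective loss is linear and sign-correct", {
  expect_identical(convective_loss(34, 34, 0.05, 3), 0)
  expect_equal(convective_loss(39, 29, 0.035, 3), 1.05)
  expect_lt(convective_loss(30, 45, 0.05, 3), 0)  # hot air = gain
})

test_that("evaporative loss uses wetted saturation pressure with a zero floor", {
  psat35 <- p_sat_kpa(35)
  expect_equal(psat35, 5.62, tolerance = 0.01)
  expect_equal(evaporative_loss(35, 2, 1, 0.05, 16.5),
               0.05 * 16.5 * (psat35 - 2))
  expect_equal(evaporative_loss(35, 2, 1, 0.05, 16.5), 2.99, tolerance = 0.02)
  # ambient vapor pressure above skin vapor pressure: floored at zero
  expect_identical(evaporative_loss(30, 6, 0.06, 0.05, 16.5), 0)
  expect_error(evaporative_loss(35, 2, 1.4, 0.05, 16.5), "wettedness")
})

test_that("radiative loss vanishes at equilibrium and scales with view factor", {
  expect_identical(radiative_loss(34, 34, list(), 0.05, 4.7), 0)
  p <- list(t_r = 34, f_vf = 0.5)
  expect_equal(radiative_loss(34, 34, list(p), 0.05, 4.7), 0)
  p1 <- list(t_r = 60, f_vf = 0.3)
  p2 <- list(t_r = 60, f_vf = 0.6)
  base <- radiative_loss(34, 34, list(p1), 0.05, 4.7)
  expect_equal(radiative_loss(34, 34, list(p2), 0.05, 4.7), 2 * base)
  expect_lt(base, 0)  # hot panel = radiant gain
})

test_that("view factor obeys limits, additivity and the quadrature oracle", {
  # enclosure limit: huge panel very close
  expect_equal(view_factor_rect(-500, 500, -500, 500, 0.01), 1,
               tolerance = 1e-4)
  expect_identical(view_factor_rect(1, 1, 0, 1, 0.5), 0)  # degenerate
  expect_error(view_factor_rect(-1, 1, 0, 1, 0), "positive")
  # additivity: halves sum to the whole (signed corner decomposition)
  whole <- view_factor_rect(-1, 1, -0.5, 1.5, 0.7)
  left <- view_factor_rect(-1, 0, -0.5, 1.5, 0.7)
  right <- view_factor_rect(0, 1, -0.5, 1.5, 0.7)
  expect_equal(whole, left + right, tolerance = 1e-12)
  # off-axis panel against the brute-force quadrature oracle
  for (geom in list(list(0.3, 1.8, -0.2, 1.1, 0.9),
                    list(-2, -0.5, 0.5, 2, 1.3))) {
    prod <- view_factor_rect(geom[[1]], geom[[2]], geom[[3]], geom[[4]],
                             geom[[5]])
    tiny <- 5e-4
    orc <- quadrature_view_factor(
      list(x1 = -tiny, x2 = tiny, z1 = -tiny, z2 = tiny),
      list(x1 = geom[[1]], x2 = geom[[2]], z1 = geom[[3]], z2 = geom[[4]]),
      geom[[5]], res = 96)
    expect_equal(prod, orc, tolerance = 1e-4)
  }
  expect_lt(view_factor_rect(-1, 1, -1, 1, 200), 1e-3)  # distance limit
})

test_that("clothing factors are identity at zero and monotone in insulation", {
  fl <- list(dry = 10, evap = 5)
  expect_identical(apply_clothing(fl, 0, 0, 3, 4.7, 49.5), fl)
  heavy <- apply_clothing(fl, 1e6, 1e6, 3, 4.7, 49.5)
  expect_lt(heavy$dry, 1e-4)
  expect_lt(heavy$evap, 1e-4)
  icl <- seq(0, 0.3, by = 0.05)
  dry <- vapply(icl, function(i) apply_clothing(fl, i, 0, 3, 4.7, 49.5)$dry,
                numeric(1))
  expect_true(all(diff(dry) < 0))
  expect_error(apply_clothing(fl, -0.1, 0, 3, 4.7, 49.5), ">= 0")
})

test_that("environment stages validate their inputs and derive vapor pressure", {
  expect_error(environment_stage(0, t_air = 29, rh = 0.5), "positive")
  expect_error(environment_stage(60, t_air = 29), "rh or p_air")
  expect_error(environment_stage(60, t_air = 29, rh = 0.5, h_c = -1),
               "positive")
  st <- environment_stage(60, t_air = 29, rh = 0.5)
  expect_equal(st$p_air, rep(0.5 * p_sat_kpa(29), 4))
  expect_equal(st$t_mrt, 29)
  expect_equal(st$h_e, 16.5 * 3.0)  # Lewis relation default
  st4 <- environment_stage(60, t_air = c(29, 30, 31, 32), rh = 0.5)
  expect_equal(st4$t_air, c(29, 30, 31, 32))
})

test_that("panels irradiate only their target sectors", {
  body <- default_body()
  ctx <- build_context(body)
  wall <- radiant_panel(60, 2.5, 2.5, 0.5, side = "left")
  st <- bioheatr:::.compile_stage(
    environment_stage(60, t_air = 25, rh = 0.5, panels = list(wall)), ctx)
  f <- st$panel_f[[1]]$f
  i_l <- match("upper_arm_l", segment_names())
  i_r <- match("upper_arm_r", segment_names())
  expect_gt(f[i_l, 2], 0.5)       # left arm exterior sees the wall
  expect_identical(f[i_r, 2], 0)  # contralateral exterior does not
  expect_identical(f[i_l, 3], 0)  # posterior sector untargeted
  expect_true(all(f >= 0 & f <= 1))
  expect_error(radiant_panel(60, 2, 2, 0), "positive")
})
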