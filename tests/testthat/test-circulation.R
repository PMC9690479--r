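test_that("arterial flows conserve mass at every branch point", {
  body <- default_body()
  net <- blood_network(body)
  m_cr <- core_perfusion(body)
  fl <- update_flows(net, m_cr, body$segments$m_sk_basal)
  to_kgs <- 1e-6 / 3600 * 1059
  # heart outflow equals total demand
  expect_equal(fl$heart_outflow,
               sum(m_cr + body$segments$m_sk_basal) * to_kgs)
  # every branch: inflow = local demand + children
  for (s in seq_along(net$parent)) {
    kids <- which(net$parent == s)
    expect_equal(fl$m_a[s], fl$demand[s] + sum(fl$m_a[kids]),
                 tolerance = 1e-12 * fl$heart_outflow)
  }
  expect_equal(fl$m_v, fl$m_a)  # venous return mirrors arterial supply
  # zero demand, zero flow
  z <- update_flows(net, rep(0, 15), rep(0, 15))
  expect_true(all(z$m_a == 0))
  expect_error(update_flows(net, rep(-1, 15), rep(0, 15)), ">= 0")
})

test_that("a perfusion increment propagates along the root path only", {
  body <- default_body()
  net <- blood_network(body)
  m_cr <- core_perfusion(body)
  m_sk <- body$segments$m_sk_basal
  base <- update_flows(net, m_cr, m_sk)
  bump <- m_sk
  i_hand <- match("hand_l", segment_names())
  bump[i_hand] <- bump[i_hand] + 1000
  new <- update_flows(net, m_cr, bump)
  dm <- new$m_a - base$m_a
  inc <- 1000 * 1e-6 / 3600 * 1059
  path <- c("hand_l", "forearm_l", "upper_arm_l", "chest")
  on_path <- segment_names() %in% path
  expect_equal(dm[on_path], rep(inc, 4))
  expect_true(all(dm[!on_path] == 0))
})

test_that("vessel balances reproduce scalar cases and steady-state bounds", {
  # zero flows, pure convective gain (upper-arm artery capacitance)
  v <- vessel_rhs(t_cr = 37, t_a = 36, t_v = 36, t_a_up = 36, t_v_in = 36,
                  h_a = 5, h_v = 0, w_a = 0, w_cr = 0, w_v = 0,
                  C_a = 49.6, C_v = 151.9)
  expect_equal(v$dT_a, 5 / 49.6)
  # isothermal: both derivatives vanish
  v0 <- vessel_rhs(36, 36, 36, 36, 36, 3, 8, 2, 1, 2, 49.6, 151.9)
  expect_identical(v0$dT_a, 0); expect_identical(v0$dT_v, 0)
  # steady artery temperature is the conductance-weighted mean of the
  # core and upstream temperatures, hence lies between them
  h_a <- 2; w_a <- 3; t_cr <- 37.5; t_up <- 36.5
  t_star <- (h_a * t_cr + w_a * t_up) / (h_a + w_a)
  v1 <- vessel_rhs(t_cr, t_star, 36, t_up, 36, h_a, 0, w_a, 0, 0, 50, 150)
  expect_equal(v1$dT_a, 0, tolerance = 1e-14)
  expect_gt(t_star, t_up); expect_lt(t_star, t_cr)
})

test_that("advective exchange conserves enthalpy over the whole network", {
  body <- default_body()
  ctx <- build_context(body, flags = list(boundary = FALSE,
                                          metabolism = FALSE))
  st <- bioheatr:::.compile_stage(environment_stage(60, 29, rh = 0.5), ctx)
  caps <- c(ctx$C_cr, ctx$C_a, ctx$C_v, rep(ctx$C_sk4, 4))
  for (seed in 1:25) {
    y <- pack_state(random_body_state(seed))
    d <- bioheatr:::.rhs_raw(y, st, ctx)
    expect_lt(abs(sum(caps * d[1:105])), 1e-9)
  }
})

test_that("malformed topologies are rejected", {
  body <- default_body()
  expect_error(blood_network(body, parent = c(head = "chest")), "every segment")
  par <- c(head = "chest", chest = "head", abdomen = "chest",
           upper_arm_l = "chest", upper_arm_r = "chest",
           forearm_l = "upper_arm_l", forearm_r = "upper_arm_r",
           hand_l = "forearm_l", hand_r = "forearm_r",
           thigh_l = "abdomen", thigh_r = "abdomen",
           calf_l = "thigh_l", calf_r = "thigh_r",
           foot_l = "calf_l", foot_r = "calf_r")
  expect_error(blood_network(body, parent = par), "root|cycle")
})
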