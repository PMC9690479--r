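test_that("mean skin temperature averages the four sectors", {
  expect_identical(mean_skin_temperature(c(34, 34, 34, 34)), 34)
  expect_identical(mean_skin_temperature(c(33, 34, 35, 36)), 34.5)
  expect_identical(mean_skin_temperature(c(36, 33, 35, 34)), 34.5)
})

test_that("metabolic multiplier activates only above the ambient threshold", {
  expect_identical(metabolic_multiplier(40, 30), 1)
  expect_identical(metabolic_multiplier(42, 38.9), 1)
  expect_equal(metabolic_multiplier(40, 45), 1.13)
  expect_identical(metabolic_multiplier(39, 45), 1)   # boundary
  expect_identical(metabolic_multiplier(37.5, 45), 1) # floored, never < 1
  expect_equal(metabolic_multiplier(41.5, 39), 1 + 0.13 * 2.5)
})

test_that("dehydration and heart-rate increment follow the linear forms", {
  expect_identical(dehydration_percent(0), 0)
  expect_equal(dehydration_percent(0.743), 1.0)
  expect_identical(heart_rate_increase(0), 0)
  expect_equal(heart_rate_increase(2), 9.5)
  d <- runif(5, 0, 4)
  expect_equal(heart_rate_increase(2 * d), 2 * heart_rate_increase(d))
})

test_that("sweating controller reproduces rate, threshold and sensitivity", {
  expect_identical(sweating_rate(37, 0, 0, 0), 0)
  expect_equal(sweating_rate(38, 0, 0, 0), 0.2898)
  expect_identical(sweating_rate(36.5, 0, 0, 0), 0)  # clamped at zero
  # onset threshold shifts by 0.06 C per % dehydration
  expect_equal(sweating_onset(0), 37, tolerance = 1e-9)
  expect_equal(sweating_onset(1), 37.06, tolerance = 1e-9)
  for (d in c(0.5, 2, 3.5))
    expect_equal(sweating_onset(d), 37 + 0.06 * d, tolerance = 1e-9)
  # sensitivity (slope above threshold) degrades by 0.068 per %
  slope <- function(d) {
    t0 <- 37 + 0.06 * d
    (sweating_rate(t0 + 1e-3, 0, 0, d) - sweating_rate(t0, 0, 0, d)) / 1e-3
  }
  expect_equal(slope(0), 0.2898, tolerance = 1e-9)
  expect_equal(slope(1), 0.2898 - 0.068, tolerance = 1e-9)
  # beyond D ~ 4.26 % the printed sensitivity would go negative; floored
  expect_identical(slope(5), 0)
  expect_gte(sweating_rate(39, 0, 0, 5), 0)
  # cold skin suppresses, warm skin adds
  expect_equal(sweating_rate(38, 2, 0, 0), 0.2898 + 0.03364 * 2)
  expect_lt(sweating_rate(38, 0, 1, 0), 0.2898)
})

test_that("vasomotor flow sits at basal with zero drives and clamps at the limits", {
  body <- default_body()
  expect_equal(vasomotor_skin_flow(0, 0, 0, 0, body),
               body$segments$m_sk_basal)
  hot <- vasomotor_skin_flow(5, 0, 10, 0, body)
  expect_equal(hot[1], 16552)                       # head m_sk_max
  expect_true(all(hot == body$segments$m_sk_max))
  cold <- vasomotor_skin_flow(0, 5, 0, 10, body)
  expect_equal(cold[body$segments$name == "hand_l"], 627)  # hand m_sk_min
  expect_equal(cold[1], 4518)                              # head m_sk_min
  expect_true(all(cold >= body$segments$m_sk_min))
  expect_true(all(cold < body$segments$m_sk_basal))        # constricted
})

test_that("shivering power is distributed by the shivering coefficients", {
  body <- default_body()
  sh <- shivering_heat(1.5, 0.8, body)
  total <- body$thermo$gains$sh * 1.5 * 0.8
  expect_equal(sum(sh), total)
  expect_equal(sh[body$segments$name == "chest"] / total, 0.485)
  expect_identical(sum(shivering_heat(0, 2, body)), 0)  # warm core
  expect_true(all(shivering_heat(2, 1, body) >= 0))
})

test_that("control signals satisfy the exclusivity and range invariants", {
  body <- default_body()
  for (seed in 1:20) {
    st <- random_body_state(seed)
    cs <- control_signals(st, body)
    expect_true(all(cs$wrm * cs$cld == 0))
    expect_true(all(cs$m_sk_perfusion >= body$segments$m_sk_min - 1e-9))
    expect_true(all(cs$m_sk_perfusion <= body$segments$m_sk_max + 1e-9))
    expect_gte(cs$sweat_total, 0)
    expect_true(all(cs$shiver >= 0))
    expect_true(all(cs$mult >= 1))
    expect_gte(cs$D, 0)
    expect_equal(cs$dHR, 4.75 * cs$D)
  }
})
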