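test_that("trunk cosine follows the published line 3.70 h/H - 0.63", {
  ps <- trunk_cosine(70, std)
  expect_equal(ps$cos_alpha, 0.9117, tolerance = 5e-4)
  expect_true(ps$in_range)
  expect_equal(ps$cos_alpha^2 + ps$sin_alpha^2, 1, tolerance = 1e-12)
  # just above the lower bound the trunk is almost fully bent
  lo <- trunk_cosine(28.61, std)
  expect_true(lo$in_range)
  expect_equal(lo$alpha_deg, 90, tolerance = 0.1)
  expect_equal(lo$sin_alpha, 1, tolerance = 1e-6)
  # exact-fraction mode admits the printed lower bound itself
  expect_true(trunk_cosine(28.6, std, mode = "derived")$in_range)
  # above the upright bound: flagged, not an error
  expect_false(trunk_cosine(74.1, std)$in_range)
  expect_false(trunk_cosine(74.1, std, mode = "derived")$in_range)
  expect_error(trunk_cosine(-1, std), "non-negative")
})

test_that("valid height range matches the published 28.6-74.0 cm window", {
  rng <- valid_height_range(std)
  expect_equal(round(rng[["h_min"]], 1), 28.6)
  expect_equal(round(rng[["h_max"]], 1), 74.0)
  # exact-fraction bounds: H (a - b) and H (a - b + k2)
  drng <- valid_height_range(std, mode = "derived")
  expect_equal(drng[["h_min"]], 168 * 0.17, tolerance = 1e-9)
  expect_equal(drng[["h_max"]], 168 * 0.44, tolerance = 1e-9)
  # linear in stature: a 25% taller worker gets 25% wider bounds
  tall <- valid_height_range(custom_profile(210, 59))
  expect_equal(unname(tall), unname(rng) * 210 / 168, tolerance = 1e-12)
  # at the lower bound the trunk is horizontal: sin(alpha) = 1
  expect_equal(trunk_cosine(rng[["h_min"]], std)$sin_alpha, 1,
               tolerance = 1e-6)
})

test_that("force coefficients reproduce (3.42, 9.06) and their derivation", {
  expect_equal(unname(force_coefficients(std)), c(3.42, 9.06))
  cf <- force_coefficients(std, mode = "derived")
  expect_equal(cf[["c1"]], 0.101946 / 0.0298, tolerance = 1e-9)
  expect_equal(cf[["c2"]], 0.27 / 0.0298, tolerance = 1e-9)
  expect_equal(unname(round(cf, 3)), c(3.421, 9.060))
  # c2 is k2 over the erector arm: doubling k2 doubles it
  wide <- std
  wide$k2 <- 2 * std$k2
  cf2 <- force_coefficients(wide, mode = "derived")
  expect_equal(cf2[["c2"]], 2 * cf[["c2"]])
  expect_equal(cf2[["c1"]],
               (std$j1 * std$k1 + std$j2 * 2 * std$k2 + std$j3 * std$k3) /
                 std$erector_arm_frac)
})

test_that("erector force reproduces the published anchor values", {
  # at the limit load for h = 34 cm (G = 145.74 N)
  G34 <- rwl_force(34)
  expect_within(G34, 145.74, 0.01)
  expect_within(erector_force(G34, 34, std)$erector_force_F, 3273.82, 0.5)
  # unloaded at the fully bent posture: F = 3.42 M = 1976.76 N
  h_min <- valid_height_range(std)[["h_min"]]
  expect_equal(erector_force(0, h_min, std)$erector_force_F, 3.42 * 578,
               tolerance = 1e-6)
  # abdominal pressure relief is the constant F4 L4 / arm = 13.19 N
  on <- erector_force(200, 50, std, mode = "derived",
                      include_abdominal = TRUE)$erector_force_F
  off <- erector_force(200, 50, std, mode = "derived")$erector_force_F
  expect_within(off - on, 0.0228 * 578, 0.1)
  expect_error(erector_force(-5, 50, std), "non-negative")
  expect_error(erector_force(100, 80, std), "valid range")
  expect_error(erector_force(100, 20, std), "valid range")
})

test_that("erector force is monotone in load and in height", {
  G <- seq(0, 60 * g, length.out = 25)
  F_G <- erector_force(G, 50, std)$erector_force_F
  expect_true(all(diff(F_G) > 0))
  h <- seq(29, 73.5, by = 0.5)
  for (load in c(0, 10 * g, 40 * g)) {
    F_h <- erector_force(load, h, std)$erector_force_F
    expect_true(all(diff(F_h) < 0))
  }
  # F never drops below the posture-holding floor c1 M sin(alpha)
  s <- trunk_cosine(h, std)$sin_alpha
  expect_true(all(erector_force(10 * g, h, std)$erector_force_F >
                    3.42 * 578 * s))
})

test_that("force depends on height only through the ratio h/H", {
  base <- custom_profile(168, 70)
  tall <- custom_profile(210, 70)  # same body weight, 25% taller
  h <- c(36, 48, 60, 70)
  F_base <- erector_force(30 * g, h, base)$erector_force_F
  F_tall <- erector_force(30 * g, h * 210 / 168, tall)$erector_force_F
  expect_equal(F_tall, F_base, tolerance = 1e-12)
})

test_that("closed form agrees with the lever-by-lever torque balance", {
  grid <- expand.grid(G = seq(0, 588, length.out = 10),
                      h = seq(29, 73, length.out = 5))
  oracle <- torque_balance_oracle(grid$G, grid$h, std)
  closed <- erector_force(grid$G, grid$h, std, mode = "derived")$erector_force_F
  expect_equal(closed, oracle, tolerance = 1e-12)
  # with the abdominal term on both sides
  oracle_ab <- torque_balance_oracle(grid$G, grid$h, std,
                                     include_abdominal = TRUE)
  closed_ab <- erector_force(grid$G, grid$h, std, mode = "derived",
                             include_abdominal = TRUE)$erector_force_F
  expect_equal(closed_ab, oracle_ab, tolerance = 1e-12)
  # unloaded value at the fully bent posture, unrounded constants
  h_min_d <- valid_height_range(std, mode = "derived")[["h_min"]]
  expect_equal(torque_balance_oracle(0, h_min_d, std),
               (std$j1 * std$k1 + std$j2 * std$k2 + std$j3 * std$k3) /
                 std$erector_arm_frac * 578,
               tolerance = 1e-12)
  expect_within(torque_balance_oracle(0, h_min_d, std), 1977.34, 0.01)
  # linear in G: subtracting the zero-load oracle leaves c2 G sin(alpha)
  s <- trunk_cosine(grid$h, std, mode = "derived")$sin_alpha
  expect_equal(oracle - torque_balance_oracle(0, grid$h, std),
               (0.27 / 0.0298) * grid$G * s, tolerance = 1e-9)
})

test_that("published-rounded and exact-fraction modes agree closely", {
  # coefficients agree to 0.1%
  cf_r <- force_coefficients(std)
  cf_d <- force_coefficients(std, mode = "derived")
  expect_equal(unname(cf_r), unname(cf_d), tolerance = 1e-3)
  # forces agree to 0.5% over the lower and middle heights; near the
  # upright end the sine amplifies the two-decimal cosine rounding beyond
  # that (by design: the rounded form is the published model)
  for (h in seq(34, 64, by = 5)) {
    for (G in c(0, 20 * g, 60 * g)) {
      F_r <- erector_force(G, h, std)$erector_force_F
      F_d <- erector_force(G, h, std, mode = "derived")$erector_force_F
      expect_equal(F_r, F_d, tolerance = 5e-3)
    }
  }
})
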