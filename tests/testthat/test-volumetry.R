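test_that("compute_pf matches the closed-form slope formula exactly", {
  g <- std_geom()
  slope <- 0.06
  tr <- linear_traj(slope, times = seq(0, 1 / 3, by = 1 / 30))
  r <- compute_pf(tr, g, osm_in = 200, osm_out = 20,
                  window = slope_window(0, 1 / 3))
  expected <- g$V0 * slope / (g$S * 18 * 180e-6)
  expect_equal(r$value, expected, tolerance = 1e-12)
  expect_equal(r$value, 4.115e-2, tolerance = 1e-3)
  expect_equal(r$slope, slope, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  # flat trajectory: Pf = 0
  r0 <- compute_pf(linear_traj(0), g, 200, 20)
  expect_equal(r0$value, 0)

  # unfolded area: exactly 9x larger
  g1 <- oocyte_geometry(0.12, physical_constants(area_fold_factor = 1))
  r1 <- compute_pf(tr, g1, 200, 20, window = slope_window(0, 1 / 3))
  expect_equal(r1$value, 9 * r$value, tolerance = 1e-12)

  expect_error(compute_pf(tr, g, 200, 200), "zero osmotic gradient")
  expect_error(compute_pf(tr, g, 200, 20, window = slope_window(0, 0.01)),
               "fewer than 2")
  expect_warning(compute_pf(linear_traj(-0.01), g, 200, 20), "negative Pf")
})

test_that("compute_ps is slope/(S/V0) and linear in V0", {
  g <- std_geom()
  tr <- linear_traj(0.012)
  r <- compute_ps(tr, g)
  expect_equal(r$value, 0.012 / (g$S / g$V0), tolerance = 1e-12)
  expect_equal(r$value, 2.667e-5, tolerance = 1e-3)  # S/V0 = 450 /cm

  expect_equal(compute_ps(linear_traj(0), g)$value, 0)

  # doubling V0 at fixed S and slope doubles Ps
  tr2 <- volume_trajectory(tr$time_min, tr$rel_volume, 2 * g$V0)
  expect_equal(compute_ps(tr2, g)$value, 2 * r$value, tolerance = 1e-12)
})

test_that("window handling: OLS equals two-point oracle on linear data", {
  g <- std_geom()
  tr <- linear_traj(0.03, times = seq(0, 2, by = 0.1))
  for (w in list(slope_window(0, 0.5), slope_window(0.5, 1.5),
                 slope_window(1, 2))) {
    ols <- compute_pf(tr, g, 200, 20, window = w)
    tp <- compute_pf(tr, g, 200, 20, window = w, slope_method = "two_point")
    expect_equal(ols$slope, 0.03, tolerance = 1e-12)
    expect_equal(ols$value, tp$value, tolerance = 1e-12)
  }
})

test_that("estimate_lp_linear: degenerate cases and secant attenuation", {
  g <- std_geom()
  bath <- sucrose_bath(1460)
  flat <- volume_trajectory(seq(0, 10, by = 0.5), rep(1, 21), g$V0)
  expect_equal(estimate_lp_linear(flat, g, bath)$value, 0)

  expect_error(estimate_lp_linear(flat, g, eg_bath()), "impermeant-only")
  expect_error(estimate_lp_linear(flat, g, bath, t_cutoff = 20),
               "beyond the trajectory")

  # on a simulated shrinkage the 10-min secant is below the 2-min secant,
  # and both are below the generating Lp (tangent): convex decay
  tr <- kk_simulate(kk_parameters(2.57), g, bath, duration = 10)
  lp2 <- estimate_lp_linear(tr, g, bath, t_cutoff = 2)$value
  lp10 <- estimate_lp_linear(tr, g, bath, t_cutoff = 10)$value
  expect_lt(lp10, lp2)
  expect_lt(lp2, 2.57)
  expect_gt(lp10, 0)
})

test_that("short-window Pf on a small gradient matches LpRT/Vw", {
  # tangent limit: simulate with sigma = 1, Ps = 0 and a small osmotic
  # step; the initial-slope Pf equals pf_from_lp(Lp) within 1%.
  # compute_pf uses the folded area, so simulate on the same basis.
  g <- std_geom()
  lp <- 2.0
  bath <- bath_solution(210)
  tr <- kk_simulate(kk_parameters(lp), g, bath, duration = 0.005,
                    sample_interval = 5e-4, area_basis = "folded")
  r <- compute_pf(tr, g, osm_in = 200, osm_out = 210,
                  window = slope_window(0, 0.005))
  expect_equal(r$value, pf_from_lp(lp), tolerance = 0.01)
})

test_that("summarize_batch: hand-checked arithmetic and degenerate input", {
  s <- summarize_batch(c(2, 4, 6), c(1, 1, 1))
  expect_equal(s$mean, 4)
  expect_equal(s$sem, sd(c(2, 4, 6)) / sqrt(3))
  expect_equal(s$sem, 1.155, tolerance = 1e-3)
  expect_equal(s$fold, 4)

  ident <- summarize_batch(c(3, 3), c(3, 3))
  expect_equal(ident$fold, 1)

  single <- summarize_batch(5, c(1, 2))
  expect_true(is.na(single$sem))

  expect_error(summarize_batch(numeric(), 1), "empty")
  expect_error(summarize_batch(1, 0), "zero control mean")

  # also accepts permeability_result lists
  g <- std_geom()
  r <- compute_ps(linear_traj(0.012), g)
  expect_equal(summarize_batch(list(r, r), list(r))$fold, 1)
})
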