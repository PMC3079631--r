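test_that("noise-free round trips recover the generating parameters", {
  g <- std_geom()
  eg <- eg_bath()
  cases <- list(
    list(p = kk_parameters(2.64, 25.49e-3, 0.8)),   # fast transporter
    list(p = kk_parameters(0.36, 0.47e-3, 0.9)),    # water-injected control
    list(p = kk_parameters(1.96, 22.24e-3, 0.8)))
  for (cs in cases) {
    tr <- kk_simulate(cs$p, g, eg, duration = 10)
    f <- fit_kk(tr, g, eg)
    expect_equal(f$params$Lp, cs$p$Lp, tolerance = 1e-3)
    expect_equal(f$params$Ps, cs$p$Ps, tolerance = 1e-3)
    expect_equal(f$params$sigma, cs$p$sigma, tolerance = 1e-3)
    expect_lt(f$rss, 1e-10)
    expect_gt(f$n_starts_converged, 0)
  }
})

test_that("one-parameter sucrose fit recovers Lp exactly", {
  g <- std_geom()
  bath <- sucrose_bath(1460)
  tr <- kk_simulate(kk_parameters(2.57), g, bath, duration = 10)
  f <- fit_kk(tr, g, bath, spec = fit_spec(free = "Lp"))
  expect_equal(f$params$Lp, 2.57, tolerance = 1e-6)
  expect_identical(f$params$Ps, 0)
  expect_identical(f$params$sigma, 1)

  # restricting to the first 2 min still recovers the generating value
  f2 <- fit_kk(tr, g, bath, spec = fit_spec(free = "Lp"), t_max = 2)
  expect_equal(f2$params$Lp, 2.57, tolerance = 1e-3)
})

test_that("property: round trips across the parameter space (seeded)", {
  set.seed(42)
  g <- std_geom()
  eg <- eg_bath()
  for (i in 1:5) {
    p <- kk_parameters(Lp = exp(runif(1, log(0.3), log(5))),
                       Ps = exp(runif(1, log(1e-3), log(5e-2))),
                       sigma = runif(1, 0.5, 0.95))
    tr <- kk_simulate(p, g, eg, duration = 10)
    f <- fit_kk(tr, g, eg)
    expect_equal(f$params$Lp, p$Lp, tolerance = 1e-3)
    expect_equal(f$params$Ps, p$Ps, tolerance = 1e-3)
    expect_equal(f$params$sigma, p$sigma, tolerance = 1e-3)
  }
})

test_that("fit is deterministic and validates its inputs", {
  g <- std_geom()
  eg <- eg_bath()
  tr <- kk_simulate(t85a_eg_params(), g, eg, duration = 5)
  f1 <- fit_kk(tr, g, eg)
  f2 <- fit_kk(tr, g, eg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$se, f2$se)

  short <- volume_trajectory(c(0, 1), c(1, 0.9), g$V0)
  expect_error(fit_kk(short, g, eg), "at least 5 samples")
  flat <- volume_trajectory(0:5, rep(1, 6), g$V0)
  expect_error(fit_kk(flat, g, eg), "degenerate")
  expect_error(fit_spec(free = character()), "at least one free parameter")
})

test_that("reported standard errors scale with trajectory noise", {
  set.seed(7)
  g <- std_geom()
  eg <- eg_bath()
  clean <- kk_simulate(t85a_eg_params(), g, eg, duration = 10)
  noisy <- volume_trajectory(
    clean$time_min,
    clean$rel_volume * c(1, exp(rnorm(nrow(clean) - 1, 0, 0.01))),
    attr(clean, "V0"))
  f <- fit_kk(noisy, g, eg)
  expect_true(all(is.finite(f$se)))
  expect_gt(f$se[["Lp"]], 0)
  # recovered within a few percent despite 1% noise
  expect_equal(f$params$Lp, 2.64, tolerance = 0.1)
  expect_equal(f$params$Ps, 25.49e-3, tolerance = 0.1)
})

test_that("sigma profile: interior minimum with a permeant, flat without", {
  g <- std_geom()
  eg <- eg_bath()
  tr <- kk_simulate(t85a_eg_params(), g, eg, duration = 10)
  prof <- profile_identifiability(tr, g, eg,
                                  sigma_grid = seq(0.6, 1, by = 0.1))
  expect_false(attr(prof, "flat"))
  expect_equal(prof$sigma[which.min(prof$rss)], 0.8, tolerance = 1e-6)

  # impermeant protocol: sigma enters no active term, profile is flat
  bath <- sucrose_bath(1460)
  trs <- kk_simulate(kk_parameters(2.57), g, bath, duration = 10)
  prof2 <- profile_identifiability(trs, g, bath,
                                   sigma_grid = c(0.2, 0.6, 1))
  expect_true(attr(prof2, "flat"))

  # single-point grid returns one row
  prof3 <- profile_identifiability(tr, g, eg, sigma_grid = 0.8)
  expect_equal(nrow(prof3), 1)
})
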