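test_that("geometry follows the sphere formulas and folding convention", {
  g <- oocyte_geometry(0.12)
  expect_equal(g$V0, pi / 6 * 0.12^3, tolerance = 1e-12)
  expect_equal(g$V0, 9.048e-4, tolerance = 1e-3)
  expect_equal(g$A_apparent, 4.524e-2, tolerance = 1e-3)
  expect_equal(g$S, 0.4071, tolerance = 1e-3)
  expect_equal(g$S, 9 * g$A_apparent)

  g1 <- oocyte_geometry(0.12, physical_constants(area_fold_factor = 1))
  expect_equal(g1$S, g1$A_apparent)

  expect_error(oocyte_geometry(0), "positive")
  expect_error(oocyte_geometry(-1), "positive")
  expect_error(physical_constants(R = -1), "positive")
  expect_error(physical_constants(area_fold_factor = 0.5), ">= 1")
})

test_that("kk_derivatives: equilibrium, impermeable membrane, sign analysis", {
  g <- std_geom()
  vb <- 0.75
  Vb <- vb * g$V0
  Nimp <- 200e-6 * (g$V0 - Vb)
  st <- oocyte_state(V = g$V0, Ns = 0, N_imp_osm = Nimp, Vb = Vb)

  # impermeable membrane: zero fluxes whatever the gradient
  d0 <- kk_derivatives(st, sucrose_bath(), kk_parameters(0, 0, 1), g)
  expect_identical(unname(d0), c(0, 0))

  # internal == external concentrations: equilibrium
  deq <- kk_derivatives(st, bath_solution(200), kk_parameters(2, 0.01, 0.8), g)
  expect_equal(unname(deq), c(0, 0), tolerance = 1e-15)

  # sigma = 1, Ps = 0, hypertonic impermeant bath: water out, no solute
  dhyp <- kk_derivatives(st, sucrose_bath(), kk_parameters(2.57, 0, 1), g)
  expect_lt(dhyp[["dV"]], 0)
  expect_identical(dhyp[["dNs"]], 0)

  # invalid state rejected
  expect_error(oocyte_state(V = Vb, Ns = 0, N_imp_osm = Nimp, Vb = Vb),
               "free water")
})

test_that("R and compiled right-hand sides agree (dual route)", {
  g <- std_geom()
  vb <- 0.75
  Nimp <- 200e-6 * (g$V0 - vb * g$V0)
  baths <- list(sucrose_bath(), eg_bath(), bath_solution(20))
  params <- list(kk_parameters(2.64, 25.49e-3, 0.8),
                 kk_parameters(0.36, 0.47e-3, 0.9),
                 kk_parameters(5, 0, 1))
  states <- list(c(V = g$V0, Ns = 0),
                 c(V = 0.9 * g$V0, Ns = 2e-8),
                 c(V = 0.8 * g$V0, Ns = 1e-7))
  for (drag in c(TRUE, FALSE)) for (b in baths) for (p in params)
    for (s in states) {
      st <- oocyte_state(s[["V"]], s[["Ns"]], Nimp, vb * g$V0)
      r_rhs <- kk_derivatives(st, b, p, g, drag = drag)
      cpp <- aquaflux:::kk_rhs_cpp(
        s[["V"]], s[["Ns"]],
        aquaflux:::kk_pars_list(p, g, b, Nimp, vb * g$V0,
                                physical_constants(), "apparent", drag))
      expect_equal(unname(r_rhs), unname(cpp), tolerance = 1e-14)
    }
})

test_that("simulation: flat at Lp = 0, BvH equilibrium, invariants", {
  g <- std_geom()
  tr0 <- kk_simulate(kk_parameters(0), g, sucrose_bath(), duration = 5)
  expect_true(all(tr0$rel_volume == 1))

  # long-time impermeant equilibrium matches the closed form to 1e-6
  tr <- kk_simulate(kk_parameters(2.57), g, sucrose_bath(1460),
                    duration = 120, sample_interval = 2)
  expect_equal(tail(tr$rel_volume, 1), bvh_equilibrium(0.75, 200, 1460),
               tolerance = 1e-6)

  # volume floor: never below the inactive fraction
  expect_gte(min(tr$rel_volume), 0.75 - 1e-9)

  # shrink is monotone without a permeant (to solver tolerance)
  expect_true(all(diff(tr$rel_volume) <= 1e-9))
})

test_that("shrink-then-swell under a permeant and solute equilibration", {
  g <- std_geom()
  tr <- kk_simulate(t85a_eg_params(), g, eg_bath(), duration = 60)
  # non-monotone: initial shrinkage then re-swelling
  imin <- which.min(tr$rel_volume)
  expect_gt(imin, 1)
  expect_lt(imin, nrow(tr))
  expect_lt(min(tr$rel_volume), 1)
  expect_gt(tail(tr$rel_volume, 1), min(tr$rel_volume))

  # free-water permeant concentration approaches the bath concentration
  n <- nrow(tr)
  Vb <- 0.75 * g$V0
  vfree <- tr$volume_cm3[n] - Vb - tr$ns_mol[n] * 54
  cs_in <- tr$ns_mol[n] / vfree
  expect_equal(cs_in, 1.3e-3, tolerance = 1e-6)
})

test_that("impermeant osmoles are conserved and solver converges in tolerance", {
  g <- std_geom()
  # N_imp enters only via the recorded metadata: re-derive it from the
  # states by inverting the flux balance at equilibrium instead; here we
  # check the direct invariant exposed by the model: a rerun at halved
  # tolerance changes nothing beyond 1e-6
  tr1 <- kk_simulate(t85a_eg_params(), g, eg_bath(), duration = 10,
                     rtol = 1e-8, atol = 1e-12)
  tr2 <- kk_simulate(t85a_eg_params(), g, eg_bath(), duration = 10,
                     rtol = 5e-9, atol = 5e-13)
  expect_lt(max(abs(tr1$rel_volume - tr2$rel_volume)), 1e-6)
  meta <- attr(tr1, "meta")
  expect_equal(meta$N_imp_osm, 200e-6 * 0.25 * g$V0)
})

test_that("bvh_equilibrium closed form and limits", {
  expect_equal(bvh_equilibrium(0.75, 200, 1460), 0.7842466,
               tolerance = 1e-6)
  expect_equal(bvh_equilibrium(0.75, 200, 200), 1)
  # infinite-osmolarity limit: loss capped at the free-water content (25%)
  expect_equal(bvh_equilibrium(0.75, 200, 1e12), 0.75, tolerance = 1e-9)
  expect_error(bvh_equilibrium(0.75, 200, 100), "osm_hyper")
  expect_error(bvh_equilibrium(1.2, 200, 400), "vb_fraction")
})

test_that("Pf-Lp conversion is LpRT/Vw", {
  expect_identical(pf_from_lp(0), 0)
  expect_equal(pf_from_lp(2.57), 2.57e-4 * 82.3 * 293.15 / 18,
               tolerance = 1e-15)
  expect_equal(pf_from_lp(2.57), 0.344, tolerance = 2e-3)
  expect_equal(pf_from_lp(2 * 2.57), 2 * pf_from_lp(2.57))
})

test_that("trajectory container validates its invariants", {
  expect_error(volume_trajectory(c(0, 1), c(1, 0.9, 0.8), 1e-3), "length")
  expect_error(volume_trajectory(c(0.5, 1), c(1, 0.9), 1e-3), "time 0")
  expect_error(volume_trajectory(c(0, 1), c(0.9, 0.8), 1e-3),
               "rel_volumes\\[1\\]")
  expect_error(volume_trajectory(c(0, 1, 1), c(1, 0.9, 0.8), 1e-3),
               "increasing")
  expect_error(volume_trajectory(c(0, 1), c(1, -0.1), 1e-3), "> 0")
})
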