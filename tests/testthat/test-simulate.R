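# Synthetic-data generation: network propagation, saturation factors, FID
# synthesis and relaxation series.

test_that("a network without reactions keeps every pool constant", {
  net <- reaction_network(tracer_catalog(c("Fum", "Mal")), list(),
                          initial_d = c(Fum = 44, Mal = 2), hdo_baseline = 15)
  traj <- simulate_concentrations(net, c(0, 10, 100))
  expect_equal(traj[2, ], traj[1, ])
  expect_equal(traj[3, ], traj[1, ])
  expect_equal(unname(traj[1, "Fum"]), 44)
})

test_that("fumarate-to-malate conversion conserves deuterium and leaves water flat", {
  traj <- simulate_concentrations(fum_network(), seq(0, 180, by = 5))
  expect_equal(unname(traj[, "Fum"] + traj[, "Mal"]), rep(44, nrow(traj)),
               tolerance = 1e-12)
  expect_equal(unname(traj[, "HDO"]), rep(15, nrow(traj)), tolerance = 1e-12)
})

test_that("deuterium is conserved for arbitrary routed networks", {
  cats <- tracer_catalog(c("Pyr", "Eth3", "Ac3"))
  for (seed in 1:5) {
    set.seed(seed)
    r1 <- diff(sort(c(0, runif(2), 1)))
    r2 <- diff(sort(c(0, runif(2), 1)))
    net <- reaction_network(
      cats,
      list(reaction_edge("Pyr", "Eth3", runif(1, 0.01, 0.07),
                         retained = r1[1], to_hdo = r1[2], to_unobserved = r1[3]),
           reaction_edge("Eth3", "Ac3", runif(1, 0.01, 0.07),
                         retained = r2[1], to_hdo = r2[2], to_unobserved = r2[3])),
      initial_d = c(Pyr = runif(1, 10, 90)), hdo_baseline = 15)
    traj <- simulate_concentrations(net, c(0, 7, 33, 150))
    expect_lt(max(abs(rowSums(traj) - sum(traj[1, ]))), 1e-9)
    expect_true(all(traj >= -1e-12))
  }
})

test_that("matrix-exponential trajectories match brute-force RK4 integration", {
  cats <- tracer_catalog(c("Pyr", "Eth3", "Ac3"))
  net <- reaction_network(
    cats,
    list(reaction_edge("Pyr", "Eth3", 0.07, retained = 0.6, to_hdo = 0.25,
                       to_unobserved = 0.15),
         reaction_edge("Eth3", "Ac3", 0.03, retained = 0.8, to_hdo = 0.1,
                       to_unobserved = 0.1)),
    initial_d = c(Pyr = 45), hdo_baseline = 15)
  tg <- c(5, 15, 30)
  exact <- simulate_concentrations(net, tg)
  oracle <- rk4_trajectories(net, tg, dt = 1e-3)
  expect_equal(as.numeric(exact), as.numeric(oracle), tolerance = 1e-6)
})

test_that("malformed networks are rejected with diagnostics", {
  expect_error(reaction_edge("A", "B", -0.1), "nonnegative")
  expect_error(reaction_edge("A", "B", 0.1, retained = 0.5, to_hdo = 0.2,
                             to_unobserved = 0.2), "sum to 1")
  expect_error(reaction_network(tracer_catalog("Fum"),
                                list(reaction_edge("Fum", "Xyz", 0.1))),
               "neither a declared species")
  expect_error(simulate_concentrations(fum_network(), c(5, 1)), "nondecreasing")
  expect_error(simulate_concentrations(fum_network(), c(-1, 1)), "nonnegative")
})

test_that("steady-state factor follows the saturation closed form", {
  expect_equal(steady_state_factor(1, 1), 1 - exp(-1), tolerance = 1e-12)
  # glucose-d2 at TR 6.3 s is fully relaxed
  expect_equal(steady_state_factor(0.077, 6.3), 1, tolerance = 1e-30)
  # acetonitrile-d3 is strongly saturated at TR 2.1 s
  expect_equal(steady_state_factor(5.322, 2.1), 1 - exp(-2.1 / 5.322),
               tolerance = 1e-12)
  # monotone in TR, saturating to 1
  trs <- c(0.5, 1, 2, 5, 20, 100)
  f <- steady_state_factor(1.5, trs)
  expect_true(all(diff(f) > 0))
  expect_equal(f[length(f)], 1, tolerance = 1e-12)
  # general flip-angle form reduces correctly at 90 degrees
  expect_equal(steady_state_factor(1, 2, flip_deg = 90), 1 - exp(-2))
  expect_lt(steady_state_factor(1, 2, flip_deg = 30),
            steady_state_factor(1, 2, flip_deg = 90))
  expect_error(steady_state_factor(-1, 1), "positive")
  expect_error(steady_state_factor(1, 0), "positive")
})

test_that("spectral integrals are linear in concentration and scan count", {
  sch <- std_scheme()
  sp <- tracer_catalog("Pyr")[[1]]
  r <- integration_region("Pyr", 2.2, 2.75)
  base <- integrate_region(process_fid(synth_fid(c(Pyr = 10), list(sp), sch,
                                                 hdo_mm = 0), reference = FALSE), r)
  for (fac in c(2, 3.5, 7)) {
    s <- integrate_region(process_fid(synth_fid(c(Pyr = 10 * fac), list(sp), sch,
                                                hdo_mm = 0), reference = FALSE), r)
    expect_equal(s / base, fac, tolerance = 1e-6)
  }
  sch2 <- acquisition_scheme(tr = 11.5, ns = 16)
  s2 <- integrate_region(process_fid(synth_fid(c(Pyr = 10), list(sp), sch2,
                                               hdo_mm = 0), reference = FALSE), r)
  expect_equal(s2 / base, 2, tolerance = 1e-6)
  # the HDO integral is untouched by another species' concentration, apart
  # from that species' far Lorentzian tail (< 0.5% here)
  rh <- integration_region("HDO", 4.45, 4.95)
  h1 <- integrate_region(process_fid(synth_fid(c(Pyr = 10), list(sp), sch,
                                               hdo_mm = 15), reference = FALSE), rh)
  h2 <- integrate_region(process_fid(synth_fid(c(Pyr = 70), list(sp), sch,
                                               hdo_mm = 15), reference = FALSE), rh)
  expect_equal(h1, h2, tolerance = 5e-3)
})

test_that("a noiseless line has the Lorentzian width 1/(pi T2)", {
  sch <- std_scheme()
  fid <- synth_fid(c(Fum = 44), tracer_catalog("Fum"), sch, hdo_mm = 15)
  s <- transform_fid(zero_fill(fid, 131072L))
  expect_equal(fwhm_hz(s, c(6.2, 7.1)), 1 / (pi * 0.246), tolerance = 0.02)
})

test_that("zero concentrations give a pure HDO FID, and none at zero water", {
  sch <- std_scheme()
  sp <- tracer_catalog("Fum")
  fid0 <- synth_fid(c(Fum = 0), sp, sch, hdo_mm = 0)
  expect_true(all(Mod(fid0$values) == 0))
  fid <- synth_fid(c(Fum = 0), sp, sch, hdo_mm = 15)
  ref <- synth_fid(numeric(0), list(), sch, hdo_mm = 15)
  expect_equal(fid$values, ref$values)
  expect_gt(max(Mod(fid$values)), 0)
})

test_that("resonances outside the spectral window are rejected", {
  sch <- acquisition_scheme(tr = 2, ns = 1, sw_ppm = 6)
  sp <- species_spec("X", 9.8, 1, 1, 1)
  expect_error(synth_fid(c(X = 1), list(sp), sch), "outside the spectral window")
})

test_that("time series covers the duration at the spectral interval with midpoint stamps", {
  net <- fum_network()
  sch <- acquisition_scheme(tr = 6.3, ns = 8, spectrum_interval = 50.4, td = 512L)
  ser <- synth_timeseries(net, sch, NULL, duration = 350)
  expect_length(ser$fids, 416)
  expect_equal(diff(ser$time_min), rep(50.4 / 60, 415), tolerance = 1e-12)
  expect_equal(ser$time_min[1], (8 * 6.3 / 2) / 60, tolerance = 1e-12)
  expect_error(acquisition_scheme(tr = 6.3, ns = 8, spectrum_interval = 10),
               "shorter than ns \\* tr")
})

test_that("identical seeds give bit-identical noisy series", {
  net <- fum_network()
  sch <- acquisition_scheme(tr = 11.5, ns = 8, td = 1024L)
  s1 <- synth_timeseries(net, sch, noise_model(0.0367, 42), duration = 10)
  s2 <- synth_timeseries(net, sch, noise_model(0.0367, 42), duration = 10)
  s3 <- synth_timeseries(net, sch, noise_model(0.0367, 43), duration = 10)
  expect_identical(s1$fids, s2$fids)
  expect_false(identical(s1$fids[[1]]$values, s3$fids[[1]]$values))
})

test_that("inversion-recovery series follow the signed recovery model", {
  d <- ir_delay_schedule()
  # independent formula evaluation for HDO's T1
  expect_equal(synth_ir_series(0.63, d), 1 - 2 * exp(-d / 0.63), tolerance = 1e-12)
  # full recovery at long delay, null point at T1 ln 2
  expect_equal(synth_ir_series(0.1, delays = 25), 1, tolerance = 1e-12)
  expect_equal(synth_ir_series(0.5, delays = 0.5 * log(2)), 0, tolerance = 1e-12)
  # imperfect inversion
  expect_equal(synth_ir_series(1, delays = 1e-6, inv_efficiency = 0.9), -0.9,
               tolerance = 1e-5)
  expect_error(synth_ir_series(-1), "positive")
  expect_error(synth_ir_series(1, inv_efficiency = 0), "inv_efficiency")
})

test_that("CPMG series follow the echo-train decay model", {
  n <- cpmg_echo_schedule()
  expect_equal(synth_cpmg_series(0.246, n, te = 0.001),
               exp(-n * 0.001 / 0.246), tolerance = 1e-12)
  expect_equal(synth_cpmg_series(0.001, echo_counts = 1, te = 0.001),
               exp(-1), tolerance = 1e-12)
  expect_equal(synth_cpmg_series(1, echo_counts = 0), 1)
  expect_error(synth_cpmg_series(0), "positive")
  expect_error(synth_cpmg_series(1, echo_counts = 2.5), "integers")
})
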