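# Internal-standard quantification, deuterium budget, and concentration
# arithmetic.

test_that("natural-abundance deuterium in water is 17.3 mM", {
  expect_equal(signif(natural_abundance_d(1.56e-4, 55.56), 3), 17.3)
  expect_equal(natural_abundance_d(0, 55.56), 0)
  expect_equal(natural_abundance_d(0.5, 55.56), 55.56 * 0.75 * 1000)
  expect_error(natural_abundance_d(1.5), "\\[0, 1\\]")
})

test_that("the internal-standard conversion reproduces the worked reference cases", {
  cal <- calibration_constants(ref_integral = 100, ref_ns = 8)
  # the reference integral itself converts to the reference concentration
  expect_equal(concentration_from_integral(100, 8, cal),
               natural_abundance_d(), tolerance = 1e-12)
  # a signal reduced by the yeast factor 0.866 reads 15 mM
  expect_equal(signif(concentration_from_integral(86.6, 8, cal), 3), 15.0)
  # doubling the number of scans at fixed integral halves the estimate
  expect_equal(concentration_from_integral(100, 16, cal),
               concentration_from_integral(100, 8, cal) / 2)
  expect_error(concentration_from_integral(1, 8, calibration_constants()),
               "no reference")
})

test_that("buffer- and cell-referenced conversions are identical for any reduction factor", {
  s_pbs <- 137.2
  for (fr in c(0.25, 0.5, 0.866, 0.99, 1)) {
    cal_pbs <- calibration_constants(fr = 1, ref_integral = s_pbs, ref_ns = 8)
    cal_yst <- calibration_constants(fr = fr, ref_integral = fr * s_pbs, ref_ns = 8)
    for (s_x in c(0, 12.3, 137.2, 400)) {
      expect_equal(concentration_from_integral(s_x, 8, cal_pbs),
                   concentration_from_integral(s_x, 8, cal_yst),
                   tolerance = 1e-12)
    }
  }
})

test_that("the reduction factor is the plain reference ratio", {
  expect_equal(reduction_factor(1, 1), 1)
  expect_equal(reduction_factor(0.866, 1), 0.866)
  expect_error(reduction_factor(1, 0), "positive")
  # simulated references at 15 vs 17.3 mM HDO reproduce the observed factor
  sch <- acquisition_scheme(tr = 17.5, ns = 8)
  r <- integration_region("HDO", 4.2, 5.2)
  s_yst <- integrate_region(process_fid(synth_fid(numeric(0), list(), sch,
                                                  hdo_mm = 15)), r)
  s_pbs <- integrate_region(process_fid(synth_fid(numeric(0), list(), sch,
                                                  hdo_mm = 17.3)), r)
  expect_equal(reduction_factor(s_yst, s_pbs), 15 / 17.3, tolerance = 1e-3)
})

test_that("the added-deuterium budget tracks the visible tracer load", {
  # only baseline water: nothing added
  expect_equal(added_d(c(HDO = 15), 15), 0)
  expect_error(added_d(c(HDO = 15), 15, expected_pools = c("HDO", "Fum")),
               "Fum")
  # fully retained routing: added-D equals the injected load at all times
  traj <- simulate_concentrations(fum_network(), seq(0, 150, by = 10))
  for (i in seq_len(nrow(traj)))
    expect_equal(added_d(traj[i, ], 15), 44, tolerance = 1e-9)
  # 20% routed to the unobserved pool: added-D decays towards 80%
  cats <- tracer_catalog(c("Fum", "Mal"))
  net <- reaction_network(cats,
                          list(reaction_edge("Fum", "Mal", 0.0561,
                                             retained = 0.8, to_unobserved = 0.2)),
                          initial_d = c(Fum = 44), hdo_baseline = 15)
  tr2 <- simulate_concentrations(net, c(0, 200))
  expect_equal(added_d(tr2[1, ], 15), 44, tolerance = 1e-9)
  expect_equal(added_d(tr2[2, ], 15), 0.8 * 44, tolerance = 1e-3)
})

test_that("deuterium-to-molecule conversion reproduces the worked examples", {
  # ethanol from glucose-d2: every second molecule labelled, two deuterons,
  # 18/15 water-rise exchange compensation
  expect_equal(molecule_conc(30, 2, 1 / 2, 18 / 15), 36, tolerance = 1e-12)
  # ethanol from pyruvate-d3
  expect_equal(molecule_conc(26, 3), 26 / 3, tolerance = 1e-12)
  expect_equal(molecule_conc(0, 5, 0.5, 2), 0)
  expect_error(molecule_conc(10, 0), "deuterons_per_molecule")
  expect_error(molecule_conc(10, 2, 0), "labeled_fraction")
  expect_error(molecule_conc(10, 2, 1, 0.5), "exchange_correction")
})

test_that("cell counts convert by the chamber formula", {
  expect_equal(cells_per_ml(0, 200), 0)
  expect_equal(cells_per_ml(50, 200), 1e8)
  expect_equal(cells_per_ml(1, 1), 1e4)
  expect_error(cells_per_ml(-1, 200), ">= 0")
})

test_that("a noiseless simulated series quantifies back to the injected trajectories", {
  cfg <- paper_scenarios("fum_d2")[[1]]
  ser <- synth_timeseries(cfg$network, cfg$scheme, NULL, duration = 30)
  q <- quantify_series(ser, cfg$regions)
  for (p in c("Fum", "Mal", "HDO")) {
    est <- q$d_conc_mM[q$pool == p]
    tru <- ser$trajectories[, p]
    expect_lt(max(abs(est - tru)) / max(tru), 0.01)
  }
  expect_true(all(q$flag == ""))
})

test_that("the reference-calibrated noise makes the quantified HDO fluctuate by ~3.67%", {
  net <- reaction_network(list(), list(), hdo_baseline = 15)
  sch <- acquisition_scheme(tr = 17.5, ns = 8)
  ser <- synth_timeseries(net, sch, noise_model(0.0367, 7),
                          duration = 120 * 140 / 60)
  q <- quantify_series(ser, list(integration_region("HDO", 4.2, 5.2)))
  v <- q$d_conc_mM[q$pool == "HDO"]
  expect_gte(length(v), 100)
  cv <- 100 * stats::sd(v) / mean(v)
  expect_gt(cv, 2.5)
  expect_lt(cv, 5)
})

test_that("negative noise-driven estimates are reported raw and clipped only in budgets", {
  q <- data.frame(time_min = c(0, 0, 1, 1), pool = c("A", "HDO", "A", "HDO"),
                  d_conc_mM = c(-0.4, 15, 0.5, 15),
                  flag = c("negative", "", "", ""))
  b <- added_d_series(q, 15)
  expect_equal(b$added_d_mM, c(0, 0.5))
  expect_equal(attr(b, "n_clipped"), 1L)
  b2 <- added_d_series(q, 15, clip = FALSE)
  expect_equal(b2$added_d_mM, c(-0.4, 0.5))
})
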