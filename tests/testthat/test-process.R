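# Spectral processing: apodization, zero filling, Fourier transform, phase
# correction, HDO referencing, and region integration.

test_that("apodization is exponential line broadening with an untouched first sample", {
  sch <- std_scheme()
  fid <- synth_fid(numeric(0), list(), sch, hdo_mm = 15)
  expect_identical(apodize(fid, 0)$values, fid$values)
  a <- apodize(fid, 3)
  expect_equal(a$values[1], fid$values[1])
  t <- (seq_along(fid$values) - 1) * fid$dwell
  expect_equal(a$values, fid$values * exp(-pi * 3 * t))
  expect_error(apodize(fid, -1), ">= 0")
  # 3 Hz broadening adds 3 Hz to the natural width of the HDO line (T2 0.61 s)
  s <- transform_fid(zero_fill(a, 131072L))
  expect_equal(fwhm_hz(s, c(4.2, 5.2)), 1 / (pi * 0.61) + 3, tolerance = 0.02)
})

test_that("zero filling pads without altering the acquired points or integrals", {
  sch <- std_scheme()
  fid <- synth_fid(c(Pyr = 20), tracer_catalog("Pyr"), sch, hdo_mm = 15)
  zf <- zero_fill(fid, 32768L)
  expect_length(zf$values, 32768L)
  expect_equal(zf$values[1:16384], fid$values)
  expect_true(all(zf$values[16385:32768] == 0))
  expect_identical(zero_fill(fid, 16384L)$values, fid$values)
  expect_error(zero_fill(fid, 8192L), "smaller than the FID")
  r <- integration_region("Pyr", 2.2, 2.75)
  a <- apodize(fid, 3)
  ints <- vapply(c(16384L, 32768L, 65536L), function(n)
    integrate_region(transform_fid(zero_fill(a, n)), r), numeric(1))
  expect_lt(max(abs(diff(ints)) / ints[1]), 0.001)
})

test_that("the transform places peaks at their chemical shift and preserves energy", {
  sch <- std_scheme()
  fid <- synth_fid(c(Pyr = 20), tracer_catalog("Pyr"), sch, hdo_mm = 0)
  s <- transform_fid(fid)
  step <- diff(s$ppm[1:2])
  expect_lt(abs(s$ppm[which.max(s$real)] - 2.468), step + 1e-12)
  # axis spans the spectral width, stored ascending
  expect_equal(diff(range(s$ppm)), sch$sw_ppm * (1 - 1 / sch$td), tolerance = 1e-9)
  expect_true(!is.unsorted(s$ppm))
  # all-zero FID transforms to an all-zero spectrum
  z <- fid; z$values[] <- 0
  sz <- transform_fid(z)
  expect_true(all(sz$real == 0) && all(sz$imag == 0))
  # Parseval: time- and frequency-domain energies agree
  sp <- transform_fid(fid, first_point_half = FALSE)
  et <- sum(Mod(fid$values)^2)
  ef <- sum(sp$real^2 + sp$imag^2) / (length(sp$real) * fid$dwell^2)
  expect_equal(ef / et, 1, tolerance = 1e-9)
})

test_that("auto phasing recovers injected zero-order phases to a small fraction of a degree", {
  sch <- std_scheme()
  fid <- synth_fid(c(Pyr = 20), tracer_catalog("Pyr"), sch, hdo_mm = 15)
  s0 <- process_fid(fid, reference = FALSE)
  # zero-phase spectrum: auto phase is ~0
  expect_lt(abs(phase_correct(s0, mode = "auto")$log$ph0), 0.5)
  for (inj in c(-90, -45, 30, 60, 90)) {
    rec <- phase_correct(rotate_phase(s0, inj), mode = "auto")
    expect_lt(abs(rec$log$ph0 + inj), 0.5)
  }
  # a full turn is the identity
  s360 <- phase_correct(s0, 360)
  expect_equal(s360$real, s0$real, tolerance = 1e-12)
  expect_equal(s360$imag, s0$imag, tolerance = 1e-12)
  # auto phase on an empty spectrum is diagnosed
  z <- s0; z$real[] <- 0; z$imag[] <- 0
  expect_error(phase_correct(z, mode = "auto"), "no signal")
})

test_that("HDO referencing finds and corrects the water position", {
  sch <- std_scheme()
  fid <- synth_fid(numeric(0), list(), sch, hdo_mm = 15)
  s <- reference_to_hdo(transform_fid(zero_fill(apodize(fid, 3))))
  expect_equal(s$log$ref_shift %||% 0, 0, tolerance = 1e-3)
  # water synthesized 0.05 ppm downfield: a -0.05 ppm shift is applied
  mis <- fid
  t <- (seq_along(fid$values) - 1) * fid$dwell
  mis$values <- fid$values * exp(complex(imaginary = 2 * pi * 0.05 * 61.4 * t))
  sm <- reference_to_hdo(transform_fid(zero_fill(apodize(mis, 3))))
  expect_equal(sm$log$ref_shift, -0.05, tolerance = 1e-3)
  expect_equal(sm$ppm[which.max(sm$real)], 4.70, tolerance = 5e-3)
  # a window devoid of signal leaves the axis untouched with a warning
  z <- transform_fid(synth_fid(numeric(0), list(), sch, hdo_mm = 0))
  expect_warning(zr <- reference_to_hdo(z), "no peak")
  expect_identical(zr$ppm, z$ppm)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("region integration matches the analytic Lorentzian area", {
  sch <- std_scheme()
  sp <- tracer_catalog("Pyr")[[1]]
  fid <- synth_fid(c(Pyr = 20), list(sp), sch, hdo_mm = 0)
  s <- process_fid(fid, lb = 3, reference = FALSE)
  r <- integration_region("Pyr", 1.97, 2.97)
  amp <- 20 * sch$ns * steady_state_factor(sp$t1, sch$tr)
  w <- 1 / (pi * sp$t2) + 3
  coverage <- (atan(2 * (2.97 - 2.468) * 61.4 / w) -
                 atan(2 * (1.97 - 2.468) * 61.4 / w)) / pi
  expect_equal(integrate_region(s, r), amp / 2 * coverage, tolerance = 0.01)
  # a signal-free region integrates to a numerical floor (the far Lorentzian
  # tail, well under 0.1% of the line amplitude)
  expect_lt(abs(integrate_region(s, integration_region("bg", 7, 8))),
            1e-3 * amp)
  # additive over disjoint sub-regions
  i1 <- integrate_region(s, integration_region("a", 1.97, 2.468))
  i2 <- integrate_region(s, integration_region("b", 2.468, 2.97))
  expect_equal(i1 + i2, integrate_region(s, r), tolerance = 1e-6)
})

test_that("two sites with a 2:1 deuterium ratio integrate 2:1", {
  sch <- std_scheme()
  cats <- tracer_catalog(c("Pyr", "Fum"))
  fid <- synth_fid(c(Pyr = 30, Fum = 15), cats, sch, hdo_mm = 0)
  s <- process_fid(fid, reference = FALSE)
  # normalize out the physics that differs between the two lines: T1
  # saturation and the window's Lorentzian coverage (independent arctan form)
  cov <- function(p, t2, lo, hi) {
    w <- 1 / (pi * t2) + 3
    (atan(2 * (hi - p) * 61.4 / w) - atan(2 * (lo - p) * 61.4 / w)) / pi
  }
  ip <- integrate_region(s, integration_region("Pyr", 2.1, 2.85)) /
    (steady_state_factor(cats$Pyr$t1, sch$tr) * cov(2.468, 1.95, 2.1, 2.85))
  if_ <- integrate_region(s, integration_region("Fum", 6.28, 7.03)) /
    (steady_state_factor(cats$Fum$t1, sch$tr) * cov(6.653, 0.246, 6.28, 7.03))
  expect_equal(ip / if_, 2, tolerance = 0.005)
})

test_that("region declarations are validated", {
  expect_error(integration_region("x", 2, 1), "lo must be < hi")
  expect_error(dmrskit:::check_regions_disjoint(
    list(integration_region("a", 1, 2), integration_region("b", 1.5, 3))),
    "overlap")
  sch <- std_scheme()
  s <- transform_fid(synth_fid(numeric(0), list(), sch, hdo_mm = 15))
  expect_error(integrate_region(s, integration_region("x", 70, 80)),
               "outside the spectrum axis")
})
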