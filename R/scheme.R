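#' Acquisition scheme for a 2H spectrum series
#'
#' Bundles the spectrometer settings that govern signal amplitude and timing:
#' repetition time, number of transients per spectrum, flip angle, spectral
#' width, time-domain points, spectrometer frequency, and the wall-clock
#' interval between successive spectra.
#'
#' @param tr Repetition time in seconds (> 0).
#' @param ns Number of summed transients per spectrum (>= 1).
#' @param spectrum_interval Seconds between the starts of successive spectra;
#'   must be at least `ns * tr` (the time needed to record one spectrum).
#'   Defaults to `ns * tr`.
#' @param flip_deg Excitation flip angle in degrees; the study design uses 90.
#' @param sw_ppm Spectral width in ppm.
#' @param td Number of complex time-domain points.
#' @param freq_mhz 2H Larmor frequency in MHz (61.4 at 9.4 T).
#' @param carrier_ppm Transmitter position in ppm; on-resonance with water.
#' @return An object of class `dmrs_scheme`.
#' @export
acquisition_scheme <- function(tr, ns = 8L, spectrum_interval = ns * tr,
                               flip_deg = 90, sw_ppm = 133.4, td = 16384L,
                               freq_mhz = 61.4, carrier_ppm = 4.70) {
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive (seconds)")
  ns <- as.integer(ns)
  if (ns < 1L) stop("ns must be >= 1")
  td <- as.integer(td)
  if (td < 2L) stop("td must be a positive point count")
  if (sw_ppm <= 0 || freq_mhz <= 0) stop("sw_ppm and freq_mhz must be positive")
  if (spectrum_interval < ns * tr - 1e-9)
    stop("spectrum_interval (", spectrum_interval, " s) is shorter than ns * tr = ",
         ns * tr, " s")
  structure(list(tr = as.numeric(tr), ns = ns,
                 spectrum_interval = as.numeric(spectrum_interval),
                 flip_deg = as.numeric(flip_deg), sw_ppm = as.numeric(sw_ppm),
                 td = td, freq_mhz = as.numeric(freq_mhz),
                 carrier_ppm = as.numeric(carrier_ppm)),
            class = "dmrs_scheme")
}

#' @export
print.dmrs_scheme <- function(x, ...) {
  cat(sprintf("<dmrs_scheme> TR %g s, NS %d, interval %g s, flip %g deg, SW %g ppm, TD %d, %g MHz\n",
              x$tr, x$ns, x$spectrum_interval, x$flip_deg, x$sw_ppm, x$td, x$freq_mhz))
  invisible(x)
}

# Spectral width in Hz and the complex dwell time in seconds.
sw_hz <- function(scheme) scheme$sw_ppm * scheme$freq_mhz
dwell_s <- function(scheme) 1 / sw_hz(scheme)

#' Noise model for synthetic spectra
#'
#' Time-domain Gaussian noise calibrated so that the integral of the HDO
#' reference line fluctuates with a standard deviation of
#' `sigma_frac_of_ref` times its mean, matching the observed stability of the
#' reference signal (about 3.67%).
#'
#' @param sigma_frac_of_ref Fractional standard deviation of the HDO reference
#'   integral (>= 0). Default 0.0367.
#' @param seed Integer seed; all synthetic noise is reproducible from it.
#' @return An object of class `dmrs_noise`.
#' @export
noise_model <- function(sigma_frac_of_ref = 0.0367, seed = 1L) {
  if (sigma_frac_of_ref < 0) stop("sigma_frac_of_ref must be >= 0")
  structure(list(sigma_frac_of_ref = as.numeric(sigma_frac_of_ref),
                 seed = as.integer(seed)),
            class = "dmrs_noise")
}

#' Steady-state amplitude factor under repeated excitation
#'
#' Fraction of the equilibrium longitudinal magnetization available per
#' excitation in a spoiled steady state with repetition time `tr`, relaxation
#' time `t1` and flip angle `theta`:
#' `sin(theta) * (1 - E1) / (1 - cos(theta) * E1)` with `E1 = exp(-tr/t1)`.
#' For the 90-degree pulses used throughout the study this reduces to
#' `1 - exp(-tr/t1)`; a short repetition time relative to T1 saturates the
#' signal and would bias concentration estimates.
#'
#' @param t1 Longitudinal relaxation time in seconds (> 0).
#' @param tr Repetition time in seconds (> 0).
#' @param flip_deg Flip angle in degrees (default 90).
#' @return Dimensionless factor in (0, 1], monotone increasing in `tr`.
#' @examples
#' steady_state_factor(1, 1)          # 1 - exp(-1)
#' steady_state_factor(0.077, 6.3)    # ~1: full recovery
#' @export
steady_state_factor <- function(t1, tr, flip_deg = 90) {
  if (any(t1 <= 0)) stop("t1 must be positive")
  if (any(tr <= 0)) stop("tr must be positive")
  th <- flip_deg * pi / 180
  e1 <- exp(-tr / t1)
  sin(th) * (1 - e1) / (1 - cos(th) * e1)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded simulations never perturb surrounding
#' stochastic code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible child seed
#'
#' Stable integer derivation so that one study seed fans out to independent
#' per-stage / per-spectrum seeds, keeping every stage reproducible on its
#' own. Result is always in \[1, 2^31 - 2\].
#'
#' @param seed Parent integer seed.
#' @param index Nonnegative integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  for (k in c(as.double(index) + 1, 104729)) {
    s <- (s * 48271 + k) %% 2147483647
  }
  as.integer(s + 1)
}
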