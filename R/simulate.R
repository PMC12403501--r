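# Synthetic DMRS data generation: concentration trajectories from first-order
# reaction networks, the FIDs/spectra they produce, and IR/CPMG relaxation
# series.

# Pool order used throughout: declared species, then HDO, then UNOBSERVED.
network_pools <- function(network) {
  c(vapply(network$species, `[[`, character(1), "name"), .reserved_pools)
}

# Per-site line table for a set of species: pool, shift, share of the pool's
# deuterium on this site, T1, T2.
spectral_lines <- function(species) {
  if (inherits(species, "dmrs_species")) species <- list(species)
  do.call(rbind, lapply(species, function(sp) {
    share <- sp$site_deuterons / sum(sp$site_deuterons)
    data.frame(pool = sp$name, shift = sp$shifts, share = share,
               t1 = sp$t1, t2 = sp$t2, stringsAsFactors = FALSE)
  }))
}

# Generator matrix of the first-order deuterium flow. Columns sum to zero, so
# total deuterium is conserved exactly by the propagator.
network_generator <- function(network) {
  pools <- network_pools(network)
  n <- length(pools)
  M <- matrix(0, n, n, dimnames = list(pools, pools))
  for (e in network$edges) {
    if (e$rate_k < 0) stop("negative rate on edge ", e$substrate, " -> ", e$product)
    s <- match(e$substrate, pools)
    M[s, s] <- M[s, s] - e$rate_k
    tgt <- function(pool, frac) {
      if (frac > 0) M[pool, s] <<- M[pool, s] + e$rate_k * frac
    }
    if (e$product %in% .reserved_pools) {
      # Routing into a reserved pool collapses: retained deuterium ends up in
      # the named pool itself.
      tgt(e$product, e$routing[["retained"]])
    } else {
      tgt(e$product, e$routing[["retained"]])
    }
    tgt("HDO", e$routing[["to_hdo"]])
    tgt("UNOBSERVED", e$routing[["to_unobserved"]])
  }
  M
}

#' Simulate deuterium-concentration trajectories of a reaction network
#'
#' Solves the linear first-order system exactly with a matrix exponential.
#' Deuterium leaving each substrate is routed between the product pool, HDO
#' (proton exchange) and an unobserved pool, so the total deuterium over all
#' pools is constant in time. A species' unreactive residual (`residual_d`)
#' rides along as a constant offset.
#'
#' @param network A [reaction_network()].
#' @param t_grid Nonnegative, nondecreasing times in minutes.
#' @return A numeric matrix, one row per time and one column per pool
#'   (declared species, then `HDO`, then `UNOBSERVED`), in mM of deuterium,
#'   with attribute `time_min`.
#' @examples
#' net <- reaction_network(
#'   list(species_spec("Fum", 6.653, 2, 0.247, 0.246),
#'        species_spec("Mal", c(4.368, 2.474), c(1, 1), 0.147, 0.146, 2)),
#'   list(reaction_edge("Fum", "Mal", 0.0561)),
#'   initial_d = c(Fum = 44), hdo_baseline = 15)
#' traj <- simulate_concentrations(net, c(0, 30, 120))
#' rowSums(traj)  # constant: deuterium is conserved
#' @export
simulate_concentrations <- function(network, t_grid) {
  stopifnot(inherits(network, "dmrs_network"))
  t_grid <- as.numeric(t_grid)
  if (any(t_grid < 0)) stop("t_grid must be nonnegative (minutes)")
  if (is.unsorted(t_grid)) stop("t_grid must be nondecreasing")
  pools <- network_pools(network)
  M <- network_generator(network)
  c0 <- c(network$initial_d - network$residual_d, 0, 0)
  names(c0) <- pools
  c0["HDO"] <- network$hdo_baseline
  out <- matrix(0, length(t_grid), length(pools), dimnames = list(NULL, pools))
  if (all(M == 0)) {
    out[] <- rep(c0, each = length(t_grid))
  } else {
    Mm <- Matrix::Matrix(M)
    for (i in seq_along(t_grid)) {
      out[i, ] <- as.numeric(Matrix::expm(Mm * t_grid[i]) %*% c0)
    }
  }
  nsp <- length(network$species)
  if (nsp) out[, seq_len(nsp)] <- out[, seq_len(nsp), drop = FALSE] +
      rep(network$residual_d, each = length(t_grid))
  attr(out, "time_min") <- t_grid
  out
}

#' Tidy data frame of simulated trajectories
#'
#' @param traj Matrix returned by [simulate_concentrations()].
#' @return Data frame with columns `time_min`, `pool`, `d_conc_mM`.
#' @export
trajectories_df <- function(traj) {
  t <- attr(traj, "time_min")
  data.frame(time_min = rep(t, times = ncol(traj)),
             pool = rep(colnames(traj), each = nrow(traj)),
             d_conc_mM = as.vector(traj),
             stringsAsFactors = FALSE)
}

ppm_window <- function(scheme) {
  scheme$carrier_ppm + c(-0.5, 0.5) * scheme$sw_ppm
}

# Exact standard deviation of a processed-spectrum region integral per unit
# time-domain noise SD, for the standard processing chain (apodization lb,
# zero filling zf, Fourier transform with half first point, trapezoidal
# integration over `region` ppm). The region integral is a linear functional
# of the complex time-domain noise; its variance follows from the frequency-
# domain trapezoid weights pulled back through the DFT.
region_noise_gain <- function(scheme, region, lb = 3, zf = 32768L) {
  n2 <- max(as.integer(zf), scheme$td)
  dt <- dwell_s(scheme)
  ax <- spectrum_axis(scheme, n2)
  w <- trapezoid_weights(ax$ppm, region) * scheme$freq_mhz  # Hz-unit weights
  g <- numeric(n2)
  g[ax$order] <- w                                  # back to DFT bin order
  G <- stats::fft(g)
  apod <- exp(-pi * lb * (0:(scheme$td - 1)) * dt)
  apod[1] <- apod[1] * 0.5
  sqrt(sum((apod * Mod(G[seq_len(scheme$td)]))^2)) * dt
}

# Time-domain noise SD (per real/imaginary component) that makes the HDO
# reference integral fluctuate by sigma_frac of its mean under the standard
# processing chain.
calibrate_noise_sd <- function(scheme, noise, hdo_mm, lb = 3, zf = 32768L,
                               hdo_region = c(4.2, 5.2)) {
  if (noise$sigma_frac_of_ref == 0) return(0)
  fid0 <- synth_fid(stats::setNames(numeric(0), character(0)), list(), scheme,
                    noise = NULL, hdo_mm = hdo_mm)
  sp0 <- transform_fid(zero_fill(apodize(fid0, lb), zf))
  s0 <- integrate_region(sp0, integration_region("HDO", hdo_region[1], hdo_region[2]))
  noise$sigma_frac_of_ref * s0 / region_noise_gain(scheme, hdo_region, lb, zf)
}

#' Synthesize a free induction decay for a tracer mixture
#'
#' Forward model for one 2H spectrum: each resonance site contributes a damped
#' complex exponential with amplitude proportional to the deuterium
#' concentration on that site, the number of summed transients, and the
#' steady-state saturation factor for its T1 at the scheme's repetition time.
#' The natural-abundance HDO line at 4.70 ppm is always present. Optional
#' time-domain Gaussian noise is calibrated so that the HDO reference integral
#' (standard processing: 3 Hz line broadening, zero fill to 32 k, trapezoid
#' over 4.2-5.2 ppm) has SD equal to `noise$sigma_frac_of_ref` of its mean.
#'
#' @param d_concs Named numeric vector of deuterium concentrations (mM) per
#'   species; may include `"HDO"` to override `hdo_mm`.
#' @param species List of [species_spec()] for the named species.
#' @param scheme An [acquisition_scheme()].
#' @param noise A [noise_model()] or `NULL` for noiseless output.
#' @param hdo_mm HDO concentration (mM) when `d_concs` carries no `"HDO"`.
#' @param seed Overrides `noise$seed` when given.
#' @return An object of class `dmrs_fid`.
#' @export
synth_fid <- function(d_concs, species, scheme, noise = NULL, hdo_mm = 17.3,
                      seed = NULL) {
  stopifnot(inherits(scheme, "dmrs_scheme"))
  if (any(d_concs < 0)) stop("concentrations must be nonnegative")
  if (inherits(species, "dmrs_species")) species <- list(species)
  spn <- vapply(species, `[[`, character(1), "name")
  hdo <- if ("HDO" %in% names(d_concs)) unname(d_concs[["HDO"]]) else hdo_mm
  use <- intersect(names(d_concs), spn)
  lines <- spectral_lines(c(species[match(use, spn)], list(hdo_species())))
  conc <- c(d_concs[use], HDO = hdo)
  lines$amp <- unname(conc[lines$pool]) * lines$share * scheme$ns *
    steady_state_factor(lines$t1, scheme$tr, scheme$flip_deg)
  win <- ppm_window(scheme)
  if (any(lines$shift < win[1] | lines$shift > win[2]))
    stop("resonance outside the spectral window [", round(win[1], 2), ", ",
         round(win[2], 2), "] ppm")
  dt <- dwell_s(scheme)
  t <- (0:(scheme$td - 1)) * dt
  vals <- complex(real = numeric(scheme$td), imaginary = numeric(scheme$td))
  for (i in seq_len(nrow(lines))) {
    if (lines$amp[i] == 0) next
    f <- (lines$shift[i] - scheme$carrier_ppm) * scheme$freq_mhz
    vals <- vals + lines$amp[i] * exp(complex(imaginary = 2 * pi * f * t) - t / lines$t2[i])
  }
  if (!is.null(noise) && noise$sigma_frac_of_ref > 0) {
    sdt <- calibrate_noise_sd(scheme, noise, hdo)
    sd_use <- if (is.null(seed)) noise$seed else seed
    eta <- with_seed(sd_use, complex(real = stats::rnorm(scheme$td, 0, sdt),
                                     imaginary = stats::rnorm(scheme$td, 0, sdt)))
    vals <- vals + eta
  }
  new_fid(vals, scheme, log = list())
}

new_fid <- function(values, scheme, log = list()) {
  structure(list(values = values, dwell = dwell_s(scheme), scheme = scheme,
                 log = log),
            class = "dmrs_fid")
}

#' @export
print.dmrs_fid <- function(x, ...) {
  cat(sprintf("<dmrs_fid> %d complex points, dwell %.4g s (SW %.4g Hz)\n",
              length(x$values), x$dwell, 1 / x$dwell))
  if (length(x$log)) cat("  processing:", paste(names(x$log), collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize a spectral time series of a metabolizing mixture
#'
#' Concentrations are evaluated at the midpoint of each spectrum's scan block
#' (symmetric averaging over the `ns * tr` acquisition), one FID per interval.
#' Noise, when requested, is seeded per spectrum from the noise model's seed
#' so the series is reproducible; the noise SD is calibrated once against the
#' network's HDO baseline.
#'
#' @param network A [reaction_network()].
#' @param scheme An [acquisition_scheme()]; `spectrum_interval` sets the
#'   spacing between spectra and must be at least `ns * tr`.
#' @param noise A [noise_model()] or `NULL`.
#' @param duration Total duration in minutes (> 0).
#' @return An object of class `dmrs_series`: times (minutes, midpoints), the
#'   list of `dmrs_fid`s, the true trajectories at those times, and metadata.
#' @export
synth_timeseries <- function(network, scheme, noise = NULL, duration) {
  stopifnot(inherits(network, "dmrs_network"), inherits(scheme, "dmrs_scheme"))
  if (duration <= 0) stop("duration must be positive (minutes)")
  if (scheme$spectrum_interval < scheme$ns * scheme$tr - 1e-9)
    stop("spectrum_interval is shorter than ns * tr")
  nspec <- floor(duration * 60 / scheme$spectrum_interval)
  if (nspec < 1) stop("duration too short for a single spectrum")
  starts <- (seq_len(nspec) - 1) * scheme$spectrum_interval
  mids_min <- (starts + scheme$ns * scheme$tr / 2) / 60
  traj <- simulate_concentrations(network, mids_min)
  sdt <- if (!is.null(noise) && noise$sigma_frac_of_ref > 0)
    calibrate_noise_sd(scheme, noise, network$hdo_baseline) else 0
  dt <- dwell_s(scheme)
  fids <- vector("list", nspec)
  for (i in seq_len(nspec)) {
    concs <- traj[i, setdiff(colnames(traj), "UNOBSERVED")]
    fid <- synth_fid(concs, network$species, scheme, noise = NULL)
    if (sdt > 0) {
      eta <- with_seed(derive_seed(noise$seed, i),
                       complex(real = stats::rnorm(scheme$td, 0, sdt),
                               imaginary = stats::rnorm(scheme$td, 0, sdt)))
      fid$values <- fid$values + eta
    }
    fids[[i]] <- fid
  }
  structure(list(time_min = mids_min, fids = fids, trajectories = traj,
                 scheme = scheme, network = network, noise = noise),
            class = "dmrs_series")
}

#' @export
print.dmrs_series <- function(x, ...) {
  cat(sprintf("<dmrs_series> %d spectra, %.4g to %.4g min, interval %g s\n",
              length(x$fids), min(x$time_min), max(x$time_min),
              x$scheme$spectrum_interval))
  invisible(x)
}

#' Synthetic inversion-recovery series
#'
#' `I(tau) = i0 * (1 - (1 + eff) * exp(-tau / t1))`; ideal inversion
#' (`eff = 1`) gives the textbook `1 - 2 exp(-tau/T1)` with a null at
#' `t1 * log(2)`.
#'
#' @param t1 Longitudinal relaxation time in seconds (> 0).
#' @param delays Recovery delays in seconds; defaults to the standard
#'   27-delay pseudo-logarithmic schedule ([ir_delay_schedule()]).
#' @param inv_efficiency Inversion efficiency in (0, 1].
#' @param i0 Fully relaxed amplitude.
#' @return Numeric vector of intensities, one per delay.
#' @export
synth_ir_series <- function(t1, delays = ir_delay_schedule(),
                            inv_efficiency = 1, i0 = 1) {
  if (t1 <= 0) stop("t1 must be positive")
  if (any(delays <= 0)) stop("delays must be positive")
  if (inv_efficiency <= 0 || inv_efficiency > 1)
    stop("inv_efficiency must be in (0, 1]")
  i0 * (1 - (1 + inv_efficiency) * exp(-delays / t1))
}

#' Synthetic CPMG echo-train series
#'
#' `I(n) = i0 * exp(-n * te / t2)` for echo-train length `n` at echo time
#' `te`.
#'
#' @param t2 Transverse relaxation time in seconds (> 0).
#' @param echo_counts Echo-train lengths; defaults to the standard 28-length
#'   schedule ([cpmg_echo_schedule()]).
#' @param te Echo time in seconds (default 1 ms).
#' @param i0 Initial amplitude.
#' @return Numeric vector of intensities, one per echo-train length.
#' @export
synth_cpmg_series <- function(t2, echo_counts = cpmg_echo_schedule(),
                              te = 0.001, i0 = 1) {
  if (t2 <= 0) stop("t2 must be positive")
  if (te <= 0) stop("te must be positive")
  if (any(echo_counts < 0) || any(echo_counts != round(echo_counts)))
    stop("echo_counts must be nonnegative integers")
  i0 * exp(-echo_counts * te / t2)
}
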