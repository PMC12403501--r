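# Shared fixtures and independent oracles for the test suite.

fum_network <- function() {
  cats <- tracer_catalog(c("Fum", "Mal"))
  reaction_network(cats, list(reaction_edge("Fum", "Mal", 0.0561)),
                   initial_d = c(Fum = 44), hdo_baseline = 15)
}

std_scheme <- function(...) acquisition_scheme(tr = 11.5, ns = 8, ...)

# Independent brute-force oracle: classic RK4 integration of the first-order
# network at a fixed small step, kept free of the matrix-exponential path.
rk4_trajectories <- function(network, t_grid, dt = 1e-3) {
  M <- dmrskit:::network_generator(network)
  pools <- colnames(M)
  x <- c(network$initial_d - network$residual_d, 0, 0)
  names(x) <- pools
  x["HDO"] <- network$hdo_baseline
  out <- matrix(NA_real_, length(t_grid), length(pools),
                dimnames = list(NULL, pools))
  t <- 0
  for (i in seq_along(t_grid)) {
    while (t < t_grid[i] - 1e-12) {
      h <- min(dt, t_grid[i] - t)
      k1 <- M %*% x
      k2 <- M %*% (x + h / 2 * k1)
      k3 <- M %*% (x + h / 2 * k2)
      k4 <- M %*% (x + h * k3)
      x <- x + h / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- x
  }
  nsp <- length(network$species)
  if (nsp) out[, seq_len(nsp)] <- out[, seq_len(nsp), drop = FALSE] +
      rep(network$residual_d, each = length(t_grid))
  out
}

# A replicate set with exactly the requested sample mean and SD.
replicates_with <- function(mean, sd, n = 5) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# Paper-scenario sampling grids and trace parameters (concentration level),
# amplitudes in mM of deuterium.
scenario_pars <- list(
  ace = list(k = 0.0123, grid = seq(0, 300, by = 140 / 60),
             a_s = 67.2, y0_s = 28.8, a_p = -36, y0_p = 36, type = "shared"),
  glc = list(k = 0.0282, grid = seq(0, 210, by = 50.4 / 60),
             a_p = -20.86, y0_p = 20.86, type = "mono"),
  fum = list(k = 0.0561, grid = seq(0, 180, by = 92 / 60),
             a_s = 37.5, y0_s = 6.5, a_p = -31, y0_p = 31, type = "shared"),
  nam = list(k = 0.0669, grid = seq(0, 150, by = 168 / 60),
             a_s = 48, y0_s = 0, a_p = -43.2, y0_p = 43.2, type = "shared"))
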