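# Study orchestration: configuration, simulate -> process -> quantify -> fit
# -> report, with bundled fixtures for the yeast tracer experiments.

#' Assemble a study configuration
#'
#' Bundles everything a reproducible run needs: the reaction network, the
#' acquisition scheme, the noise model, the integration regions, an optional
#' species-to-pool merge map (for inherently unresolved resonances), the fit
#' plan and the study duration.
#'
#' @param name Study label.
#' @param network A [reaction_network()].
#' @param scheme An [acquisition_scheme()].
#' @param regions List of [integration_region()], pairwise disjoint.
#' @param duration_min Study duration in minutes.
#' @param noise A [noise_model()].
#' @param pool_map Optional named character vector mapping species to
#'   reported pools.
#' @param fit_plan List of fit requests; each a list with `name`, `type`
#'   (`"independent"` or `"shared"`), and either `pool` + `role` or
#'   `substrate` + `product` pool labels.
#' @param seed Integer seed; mandatory for any stochastic run.
#' @return An object of class `dmrs_config`.
#' @export
study_config <- function(name, network, scheme, regions, duration_min,
                         noise = noise_model(), pool_map = NULL,
                         fit_plan = list(), seed = NULL) {
  cfg <- structure(list(name = name, network = network, scheme = scheme,
                        regions = regions, duration_min = duration_min,
                        noise = noise, pool_map = pool_map,
                        fit_plan = fit_plan, seed = seed),
                   class = "dmrs_config")
  validate_study_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' Checks that every reference resolves before any simulation starts: region
#' labels are unique and disjoint, the pool map names declared species, and
#' every pool named by the fit plan is a reported pool.
#'
#' @param config A `dmrs_config`.
#' @return The config, invisibly; errors otherwise.
#' @export
validate_study_config <- function(config) {
  stopifnot(inherits(config, "dmrs_config"))
  if (!inherits(config$network, "dmrs_network")) stop("config$network is not a dmrs_network")
  if (!inherits(config$scheme, "dmrs_scheme")) stop("config$scheme is not a dmrs_scheme")
  regions <- config$regions
  if (inherits(regions, "dmrs_region")) regions <- list(regions)
  labs <- vapply(regions, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate region labels")
  check_regions_disjoint(regions)
  spn <- vapply(config$network$species, `[[`, character(1), "name")
  if (!is.null(config$pool_map)) {
    bad <- setdiff(names(config$pool_map), spn)
    if (length(bad)) stop("pool_map names undeclared species: ",
                          paste(bad, collapse = ", "))
  }
  pools <- reported_pools(config)
  for (f in config$fit_plan) {
    want <- c(f$pool, f$substrate, f$product)
    bad <- setdiff(want, pools)
    if (length(bad))
      stop("fit plan '", f$name, "' references undeclared pool(s): ",
           paste(bad, collapse = ", "))
  }
  if (config$duration_min <= 0) stop("duration_min must be positive")
  invisible(config)
}

reported_pools <- function(config) {
  spn <- vapply(config$network$species, `[[`, character(1), "name")
  if (is.null(config$pool_map)) c(spn, "HDO")
  else unique(c(unname(config$pool_map[spn]), "HDO"))
}

#' @export
print.dmrs_config <- function(x, ...) {
  cat("<dmrs_config> ", x$name, ": ", length(x$network$species), " species, ",
      length(x$regions), " regions, ", x$duration_min, " min, ",
      length(x$fit_plan), " planned fit(s)\n", sep = "")
  invisible(x)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # strip environments/closures-free plain list for stable serialization
  writeBin(serialize(unclass_deep(config), NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, function(e) if (is.list(e)) unclass_deep(e) else e)
  else x
}

#' Run a configured study end to end
#'
#' Simulates the configured experiment, quantifies it, tracks the
#' added-deuterium budget and executes the fit plan. Two fidelity modes are
#' available: `"spectra"` synthesizes and processes every 2H spectrum
#' (FID -> apodize -> zero fill -> transform -> phase -> reference ->
#' integrate -> concentration), while `"trajectory"` works on the exactly
#' simulated concentrations with reference-calibrated Gaussian noise
#' (SD = `sigma_frac_of_ref` x HDO baseline per point), which is the
#' appropriate level for rate-recovery studies. Identical (config, seed)
#' give identical reports.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; defaults to `config$seed`. Required unless
#'   `noiseless = TRUE`.
#' @param mode `"spectra"` or `"trajectory"`.
#' @param noiseless Disable all noise (deterministic round trip).
#' @return An object of class `dmrs_report`.
#' @export
run_study <- function(config, seed = config$seed,
                      mode = c("spectra", "trajectory"), noiseless = FALSE) {
  mode <- match.arg(mode)
  validate_study_config(config)
  if (!noiseless && is.null(seed))
    stop("a seed is mandatory for any stochastic run")
  net <- config$network
  scheme <- config$scheme
  nspec <- floor(config$duration_min * 60 / scheme$spectrum_interval)
  mids <- ((seq_len(nspec) - 1) * scheme$spectrum_interval +
             scheme$ns * scheme$tr / 2) / 60
  traj <- simulate_concentrations(net, mids)
  if (mode == "spectra") {
    noise <- if (noiseless) NULL else
      noise_model(config$noise$sigma_frac_of_ref, derive_seed(seed, 1))
    series <- synth_timeseries(net, scheme, noise, config$duration_min)
    quant <- quantify_series(series, config$regions, pool_map = config$pool_map)
  } else {
    pools <- setdiff(colnames(traj), "UNOBSERVED")
    est <- traj[, pools, drop = FALSE]
    if (!is.null(config$pool_map)) {
      rp <- reported_pools(config)
      merged <- matrix(0, nrow(est), length(rp), dimnames = list(NULL, rp))
      map <- c(config$pool_map, HDO = "HDO")
      for (p in pools) merged[, map[[p]]] <- merged[, map[[p]]] + est[, p]
      est <- merged
    }
    if (!noiseless) {
      sd_pt <- config$noise$sigma_frac_of_ref * net$hdo_baseline
      eps <- with_seed(derive_seed(seed, 2),
                       matrix(stats::rnorm(length(est), 0, sd_pt), nrow(est)))
      est <- est + eps
    }
    quant <- data.frame(time_min = rep(mids, times = ncol(est)),
                        pool = rep(colnames(est), each = nrow(est)),
                        d_conc_mM = as.vector(est), stringsAsFactors = FALSE)
    quant$flag <- ifelse(quant$d_conc_mM < 0, "negative", "")
  }
  budget <- added_d_series(quant, net$hdo_baseline)
  fits <- list()
  for (f in config$fit_plan) {
    if (identical(f$type, "shared")) {
      s <- quant[quant$pool == f$substrate, ]
      p <- quant[quant$pool == f$product, ]
      fits[[f$name]] <- fit_shared_rate(
        kinetic_trace(s$time_min, s$d_conc_mM, f$substrate, "substrate"),
        kinetic_trace(p$time_min, p$d_conc_mM, f$product, "product"))
    } else {
      q <- quant[quant$pool == f$pool, ]
      fits[[f$name]] <- fit_monoexp(
        kinetic_trace(q$time_min, q$d_conc_mM, f$pool, f$role %||% "product"))
    }
  }
  fit_table <- do.call(rbind, lapply(names(fits), function(nm) {
    ft <- fits[[nm]]
    data.frame(fit = nm, parameter = names(ft$par),
               estimate = unname(ft$par), se = unname(ft$se),
               converged = ft$converged,
               flags = paste(ft$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(fit_table))
    fit_table <- data.frame(fit = character(), parameter = character(),
                            estimate = numeric(), se = numeric(),
                            converged = logical(), flags = character(),
                            stringsAsFactors = FALSE)
  structure(list(name = config$name, quantified = quant, budget = budget,
                 fits = fits, fit_table = fit_table, trajectories = traj,
                 provenance = list(config_hash = config_hash(config),
                                   seed = seed, mode = mode,
                                   noiseless = noiseless,
                                   n_spectra = nspec,
                                   package_version =
                                     as.character(utils::packageVersion("dmrskit")))),
            class = "dmrs_report")
}

#' @export
print.dmrs_report <- function(x, ...) {
  cat("<dmrs_report> ", x$name, ": ", x$provenance$n_spectra, " spectra (",
      x$provenance$mode, if (x$provenance$noiseless) ", noiseless" else "",
      "), config ", substr(x$provenance$config_hash, 1, 8), "\n", sep = "")
  if (nrow(x$fit_table)) {
    cat("  fits:\n")
    print(x$fit_table, row.names = FALSE)
  }
  invisible(x)
}

#' Export a study report to files
#'
#' Writes the quantified series, budget and fit table as CSV and the fit
#' records plus provenance as JSON. Re-importing with [import_report()]
#' reproduces the tables.
#'
#' @param report A `dmrs_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @return Invisibly, the paths written.
#' @export
export_report <- function(report, dir, formats = c("csv", "json")) {
  stopifnot(inherits(report, "dmrs_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wcsv <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if ("csv" %in% formats) {
    wcsv(report$quantified, "quantified.csv")
    wcsv(report$budget, "budget.csv")
    wcsv(report$fit_table, "fit_table.csv")
  }
  if ("json" %in% formats) {
    recs <- lapply(report$fits, function(ft) {
      list(parameters = as.list(ft$par), se = as.list(ft$se),
           covariance = unname(apply(as.matrix(ft$cov), 1, as.list)),
           converged = ft$converged, rss = ft$rss, sigma = ft$sigma,
           flags = as.list(ft$flags), n_points = ft$n_points)
    })
    p <- file.path(dir, "fits.json")
    jsonlite::write_json(recs, p, auto_unbox = TRUE, digits = NA, null = "null")
    paths <- c(paths, p)
    p2 <- file.path(dir, "provenance.json")
    jsonlite::write_json(report$provenance, p2, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p2)
  }
  invisible(paths)
}

#' Import exported report tables
#'
#' @param dir Directory written by [export_report()].
#' @return List with `quantified`, `budget`, `fit_table` data frames and
#'   `fits`, `provenance` lists (when present).
#' @export
import_report <- function(dir) {
  out <- list()
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  if (file.exists(file.path(dir, "quantified.csv"))) out$quantified <- rd("quantified.csv")
  if (file.exists(file.path(dir, "budget.csv"))) out$budget <- rd("budget.csv")
  if (file.exists(file.path(dir, "fit_table.csv"))) out$fit_table <- rd("fit_table.csv")
  if (file.exists(file.path(dir, "fits.json")))
    out$fits <- jsonlite::read_json(file.path(dir, "fits.json"), simplifyVector = FALSE)
  if (file.exists(file.path(dir, "provenance.json")))
    out$provenance <- jsonlite::read_json(file.path(dir, "provenance.json"))
  out
}

# ---- bundled paper-scenario fixtures ---------------------------------------

#' Bundled yeast tracer study fixtures
#'
#' Ready-made configurations for the six tracer experiments: glucose-d2 and
#' -d7 fermentation to ethanol, pyruvate-d3 to ethanol and acetate, fumarate-
#' d2 to malate, acetone-d6 to propan-2-ol, and nicotinamide-d4 to nicotinic
#' acid. Rates, initial deuterium loads, asymptotes and acquisition timings
#' follow the reported experiments; deuteron routing fractions are derived
#' from the reported asymptotic pool sizes. The NAM/NA resonances are not
#' resolvable by simple integration and are reported as one merged pool.
#'
#' @param names Optional subset of
#'   `c("glc_d2","glc_d7","pyr_d3","fum_d2","ace_d6","nam_d4")`.
#' @param seed Seed stored in each config.
#' @return Named list of [study_config()] objects.
#' @export
paper_scenarios <- function(names = NULL, seed = 1L) {
  cats <- tracer_catalog()
  reg <- integration_region
  sc <- list()

  # Glucose-d2: 20 mM x 2 D = 40 mM [D]; ethanol asymptote 20.86 mM,
  # HDO 15 -> 18 mM; k_ge = 0.0282/min; spectra every 50.4 s (NS 8, TR 6.3).
  sc$glc_d2 <- study_config(
    "glc_d2",
    reaction_network(cats[c("Glc2", "Eth2")],
                     list(reaction_edge("Glc2", "Eth2", 0.0282,
                                        retained = 20.86 / 40, to_hdo = 3 / 40,
                                        to_unobserved = 1 - 20.86 / 40 - 3 / 40)),
                     initial_d = c(Glc2 = 40), hdo_baseline = 15),
    acquisition_scheme(tr = 6.3, ns = 8, spectrum_interval = 50.4),
    list(reg("Eth2", 0.95, 1.55), reg("Glc2", 3.55, 4.25), reg("HDO", 4.45, 5.15)),
    duration_min = 210,
    fit_plan = list(list(name = "k_ge", type = "independent", pool = "Eth2",
                         role = "product")),
    seed = seed)

  # Glucose-d7: 19 mM x 7 D = 133 mM [D]; rapid exchange drives HDO from 15
  # to 62 mM; k = 0.0271/min. The beta-anomer C1 resonance overlaps water and
  # is not modelled.
  sc$glc_d7 <- study_config(
    "glc_d7",
    reaction_network(cats[c("Glc7", "Eth3")],
                     list(reaction_edge("Glc7", "Eth3", 0.0271,
                                        retained = 33 / 133, to_hdo = 47 / 133,
                                        to_unobserved = 1 - 33 / 133 - 47 / 133)),
                     initial_d = c(Glc7 = 133), hdo_baseline = 15),
    acquisition_scheme(tr = 6.3, ns = 8, spectrum_interval = 50.4),
    list(reg("Eth3", 0.95, 1.55), reg("Glc7", 3.30, 4.10),
         reg("HDO", 4.30, 4.95), reg("Glc7a", 5.05, 5.50)),
    duration_min = 210,
    pool_map = c(Glc7 = "Glc7", Eth3 = "Eth3"),
    fit_plan = list(list(name = "k_ge7", type = "independent", pool = "Eth3",
                         role = "product")),
    seed = seed)

  # Pyruvate-d3: 15 mM x 3 D = 45 mM [D], 2 mM (6 mM [D]) left unconverted;
  # ethanol 26 mM [D] (k 0.0274), acetate 3.1 mM [D]; HDO rises by ~3 mM.
  # Spectra every 124 s (NS 8, TR 15.5).
  k_e <- 0.0245; k_a <- 0.0029; ktot <- k_e + k_a
  r_e <- 26 * ktot / (k_e * 39); r_a <- 3.1 * ktot / (k_a * 39); h <- 3 / 39
  sc$pyr_d3 <- study_config(
    "pyr_d3",
    reaction_network(cats[c("Pyr", "Eth3", "Ac3")],
                     list(reaction_edge("Pyr", "Eth3", k_e, retained = r_e,
                                        to_hdo = h, to_unobserved = 1 - r_e - h),
                          reaction_edge("Pyr", "Ac3", k_a, retained = r_a,
                                        to_hdo = h, to_unobserved = 1 - r_a - h)),
                     initial_d = c(Pyr = 45), residual_d = c(Pyr = 6),
                     hdo_baseline = 15),
    acquisition_scheme(tr = 15.5, ns = 8, spectrum_interval = 124),
    list(reg("Eth3", 0.95, 1.50), reg("Ac3", 1.75, 2.20), reg("Pyr", 2.25, 2.70),
         reg("HDO", 4.40, 5.00)),
    duration_min = 250,
    fit_plan = list(list(name = "k_pe", type = "independent", pool = "Eth3",
                         role = "product"),
                    list(name = "k_pa", type = "independent", pool = "Ac3",
                         role = "product")),
    seed = seed)

  # Fumarate-d2: 44 mM [D] -> 31 mM [D] malate, 6.5 mM residual fumarate;
  # shared k_fm = 0.0561/min; water stable. Spectra every 92 s (NS 8, TR 11.5).
  sc$fum_d2 <- study_config(
    "fum_d2",
    reaction_network(cats[c("Fum", "Mal")],
                     list(reaction_edge("Fum", "Mal", 0.0561,
                                        retained = 31 / 37.5, to_hdo = 0,
                                        to_unobserved = 1 - 31 / 37.5)),
                     initial_d = c(Fum = 44), residual_d = c(Fum = 6.5),
                     hdo_baseline = 15),
    acquisition_scheme(tr = 11.5, ns = 8, spectrum_interval = 92),
    list(reg("MalC3", 2.20, 2.75), reg("MalC2", 4.14, 4.50),
         reg("HDO", 4.55, 4.90), reg("Fum", 6.35, 6.95)),
    duration_min = 180,
    fit_plan = list(list(name = "k_fm", type = "shared", substrate = "Fum",
                         product = "Mal")),
    seed = seed)

  # Acetone-d6: 16 mM x 6 D = 96 mM [D]; 6 mM propan-2-ol (36 mM [D]) and
  # 4.8 mM acetone (28.8 mM [D]) at the end; shared k_ap = 0.0123/min;
  # volatile losses routed to the unobserved pool. Spectra every 140 s
  # (NS 8, TR 17.5).
  sc$ace_d6 <- study_config(
    "ace_d6",
    reaction_network(cats[c("Ace", "Prop")],
                     list(reaction_edge("Ace", "Prop", 0.0123,
                                        retained = 36 / 67.2, to_hdo = 0,
                                        to_unobserved = 1 - 36 / 67.2)),
                     initial_d = c(Ace = 96), residual_d = c(Ace = 28.8),
                     hdo_baseline = 15),
    acquisition_scheme(tr = 17.5, ns = 8, spectrum_interval = 140),
    list(reg("Prop", 0.95, 1.45), reg("Ace", 2.05, 2.60), reg("HDO", 4.40, 5.00)),
    duration_min = 300,
    fit_plan = list(list(name = "k_ap", type = "shared", substrate = "Ace",
                         product = "Prop")),
    seed = seed)

  # Nicotinamide-d4: 12 mM x 4 D = 48 mM [D]; k_NA = 0.0669/min; the NAM and
  # NA aromatic lines are 2.7-10 Hz apart at ~5-8 Hz width and cannot be
  # separated by integration, so the two species are reported as one merged
  # pool. Spectra every 168 s (NS 80, TR 2.1).
  sc$nam_d4 <- study_config(
    "nam_d4",
    reaction_network(cats[c("NAM", "NA_")],
                     list(reaction_edge("NAM", "NA_", 0.0669,
                                        retained = 0.9, to_hdo = 0,
                                        to_unobserved = 0.1)),
                     initial_d = c(NAM = 48), hdo_baseline = 15),
    acquisition_scheme(tr = 2.1, ns = 80, spectrum_interval = 168),
    list(reg("Aromatic", 7.30, 9.50), reg("HDO", 4.40, 5.00)),
    duration_min = 150,
    pool_map = c(NAM = "NAM_NA", NA_ = "NAM_NA"),
    fit_plan = list(),
    seed = seed)

  if (!is.null(names)) {
    bad <- setdiff(names, base::names(sc))
    if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
    sc <- sc[names]
  }
  sc
}
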