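# Plain-text interchange: spectra as columnar (ppm, real, imag) files with a
# header block, region definitions as CSV, trajectories as tidy CSV, network
# and acquisition configuration as JSON documents mirroring the constructor
# fields, and a minimal JCAMP-DX export of the real part.

#' Write a spectrum as columnar text
#'
#' Header lines (`# key: value`) carry the acquisition metadata and the
#' processing log; the body is three columns, `ppm real imag`, one row per
#' point in ascending ppm.
#'
#' @param spectrum A `dmrs_spectrum`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "dmrs_spectrum"))
  s <- spectrum$scheme
  hdr <- c(sprintf("# tr: %.10g", s$tr), sprintf("# ns: %d", s$ns),
           sprintf("# spectrum_interval: %.10g", s$spectrum_interval),
           sprintf("# flip_deg: %.10g", s$flip_deg),
           sprintf("# sw_ppm: %.10g", s$sw_ppm), sprintf("# td: %d", s$td),
           sprintf("# freq_mhz: %.10g", s$freq_mhz),
           sprintf("# carrier_ppm: %.10g", s$carrier_ppm))
  for (nm in names(spectrum$log))
    hdr <- c(hdr, sprintf("# log_%s: %.10g", nm, spectrum$log[[nm]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("ppm real imag", con)
  utils::write.table(
    data.frame(ppm = spectrum$ppm, real = spectrum$real, imag = spectrum$imag),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a columnar spectrum file
#'
#' @param path File written by [write_spectrum()].
#' @return A `dmrs_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^# ([A-Za-z_0-9]+): (.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
  }
  scheme <- acquisition_scheme(tr = kv$tr, ns = kv$ns,
                               spectrum_interval = kv$spectrum_interval,
                               flip_deg = kv$flip_deg, sw_ppm = kv$sw_ppm,
                               td = kv$td, freq_mhz = kv$freq_mhz,
                               carrier_ppm = kv$carrier_ppm)
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  log <- kv[grep("^log_", names(kv))]
  names(log) <- sub("^log_", "", names(log))
  structure(list(ppm = body$ppm, real = body$real, imag = body$imag,
                 scheme = scheme, log = log),
            class = "dmrs_spectrum")
}

#' Write / read integration regions as CSV
#'
#' Columns `label, lo_ppm, hi_ppm`.
#'
#' @param regions List of [integration_region()].
#' @param path CSV file path.
#' @return For the writer, `path` invisibly; for the reader, a list of
#'   regions.
#' @export
write_regions_csv <- function(regions, path) {
  if (inherits(regions, "dmrs_region")) regions <- list(regions)
  df <- data.frame(label = vapply(regions, `[[`, character(1), "label"),
                   lo_ppm = vapply(regions, `[[`, numeric(1), "lo"),
                   hi_ppm = vapply(regions, `[[`, numeric(1), "hi"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_csv
#' @export
read_regions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    integration_region(df$label[i], df$lo_ppm[i], df$hi_ppm[i]))
}

#' Write simulated trajectories as tidy CSV
#'
#' Columns `time_min, pool, d_conc_mM`.
#'
#' @param traj Matrix from [simulate_concentrations()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(traj, path) {
  utils::write.csv(trajectories_df(traj), path, row.names = FALSE)
  invisible(path)
}

#' Minimal JCAMP-DX export of the real part of a spectrum
#'
#' Writes an XYDATA table (one `x, y` pair per line) with the standard
#' header records, sufficient for exchange with common NMR viewers.
#'
#' @param spectrum A `dmrs_spectrum`.
#' @param path Output file.
#' @param title Data-set title.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spectrum, path, title = "dmrskit spectrum") {
  stopifnot(inherits(spectrum, "dmrs_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=5.00",
    "##DATA TYPE=NMR SPECTRUM",
    paste0("##.OBSERVE FREQUENCY=", format(spectrum$scheme$freq_mhz, digits = 10)),
    "##XUNITS=PPM", "##YUNITS=ARBITRARY UNITS",
    paste0("##FIRSTX=", format(spectrum$ppm[1], digits = 12)),
    paste0("##LASTX=", format(spectrum$ppm[length(spectrum$ppm)], digits = 12)),
    paste0("##NPOINTS=", length(spectrum$ppm)),
    "##XYDATA=(XY..XY)"), con)
  writeLines(sprintf("%.8g, %.8g", spectrum$ppm, spectrum$real), con)
  writeLines("##END=", con)
  invisible(path)
}

# ---- configuration JSON -----------------------------------------------------

species_to_list <- function(sp) {
  list(name = sp$name, shifts = sp$shifts, site_deuterons = sp$site_deuterons,
       t1 = sp$t1, t2 = sp$t2, deuterons_per_molecule = sp$deuterons_per_molecule)
}

#' Write a study configuration as JSON
#'
#' The document mirrors the constructor fields: `network` (species, edges,
#' initial and residual deuterium, HDO baseline), `scheme`, `noise`,
#' `regions`, `pool_map`, `fit_plan`, `duration_min` and `seed`.
#'
#' @param config A [study_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "dmrs_config"))
  net <- config$network
  doc <- list(
    name = config$name,
    network = list(
      species = lapply(net$species, species_to_list),
      edges = lapply(net$edges, function(e)
        list(substrate = e$substrate, product = e$product, rate_k = e$rate_k,
             retained = unname(e$routing[["retained"]]),
             to_hdo = unname(e$routing[["to_hdo"]]),
             to_unobserved = unname(e$routing[["to_unobserved"]]))),
      initial_d = as.list(net$initial_d),
      residual_d = as.list(net$residual_d),
      hdo_baseline = net$hdo_baseline),
    scheme = unclass(config$scheme),
    noise = unclass(config$noise),
    regions = lapply(config$regions, function(r)
      list(label = r$label, lo = r$lo, hi = r$hi)),
    pool_map = if (is.null(config$pool_map)) NULL else as.list(config$pool_map),
    fit_plan = config$fit_plan,
    duration_min = config$duration_min,
    seed = config$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a study configuration from JSON
#'
#' @param path File written by [write_study_config()] (or hand-authored with
#'   the same fields).
#' @return A validated [study_config()].
#' @export
read_study_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  species <- lapply(doc$network$species, function(s)
    species_spec(s$name, unlist(s$shifts), unlist(s$site_deuterons),
                 unlist(s$t1), unlist(s$t2), s$deuterons_per_molecule))
  edges <- lapply(doc$network$edges, function(e)
    reaction_edge(e$substrate, e$product, e$rate_k, e$retained, e$to_hdo,
                  e$to_unobserved))
  net <- reaction_network(species, edges,
                          initial_d = unlist(doc$network$initial_d),
                          hdo_baseline = doc$network$hdo_baseline,
                          residual_d = unlist(doc$network$residual_d))
  sch <- doc$scheme
  scheme <- acquisition_scheme(tr = sch$tr, ns = sch$ns,
                               spectrum_interval = sch$spectrum_interval,
                               flip_deg = sch$flip_deg, sw_ppm = sch$sw_ppm,
                               td = sch$td, freq_mhz = sch$freq_mhz,
                               carrier_ppm = sch$carrier_ppm)
  regions <- lapply(doc$regions, function(r) integration_region(r$label, r$lo, r$hi))
  pool_map <- if (is.null(doc$pool_map)) NULL else unlist(doc$pool_map)
  study_config(doc$name, net, scheme, regions, doc$duration_min,
               noise = noise_model(doc$noise$sigma_frac_of_ref, doc$noise$seed),
               pool_map = pool_map,
               fit_plan = lapply(doc$fit_plan, function(f) f),
               seed = doc$seed)
}
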