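#' Describe an observable deuterated species
#'
#' A species is the unit of quantification: one or more 2H resonances
#' (chemical shift plus the number of deuterons resonating at that site),
#' per-site or shared relaxation times, and the total deuteron count per
#' molecule. Sites may describe a subset of the molecule's deuterons (for
#' example when one resonance overlaps water and is dropped from analysis).
#'
#' @param name Species label, e.g. `"Fum"`.
#' @param shifts Numeric vector of chemical shifts in ppm (referenced to HDO
#'   at 4.70 ppm).
#' @param site_deuterons Integer vector, deuterons resonating at each site.
#'   Recycled to `length(shifts)`.
#' @param t1 Longitudinal relaxation time(s) in seconds; one value shared by
#'   all sites or one per site.
#' @param t2 Transverse relaxation time(s) in seconds, same recycling rule.
#' @param deuterons_per_molecule Total deuterons per molecule (used to convert
#'   deuterium concentration to molecule concentration and to apportion signal
#'   across sites).
#' @return An object of class `dmrs_species`.
#' @examples
#' fum <- species_spec("Fum", 6.653, 2, t1 = 0.247, t2 = 0.246,
#'                     deuterons_per_molecule = 2)
#' @export
species_spec <- function(name, shifts, site_deuterons = 1L, t1, t2,
                         deuterons_per_molecule = sum(site_deuterons)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  shifts <- as.numeric(shifts)
  ns <- length(shifts)
  if (ns < 1L) stop("species '", name, "': at least one resonance required")
  site_deuterons <- rep_len(as.numeric(site_deuterons), ns)
  t1 <- rep_len(as.numeric(t1), ns)
  t2 <- rep_len(as.numeric(t2), ns)
  if (any(site_deuterons < 1)) stop("species '", name, "': site deuteron counts must be >= 1")
  if (any(t1 <= 0) || any(t2 <= 0)) stop("species '", name, "': relaxation times must be positive")
  if (deuterons_per_molecule < 1) stop("species '", name, "': deuterons_per_molecule must be >= 1")
  structure(
    list(name = name, shifts = shifts, site_deuterons = site_deuterons,
         t1 = t1, t2 = t2,
         deuterons_per_molecule = as.numeric(deuterons_per_molecule)),
    class = "dmrs_species")
}

#' @export
print.dmrs_species <- function(x, ...) {
  cat("<dmrs_species> ", x$name, " (", x$deuterons_per_molecule, " D/molecule)\n", sep = "")
  for (i in seq_along(x$shifts)) {
    cat(sprintf("  site %d: %.4g ppm, %g D, T1 = %g s, T2 = %g s\n",
                i, x$shifts[i], x$site_deuterons[i], x$t1[i], x$t2[i]))
  }
  invisible(x)
}

# Reserved pool names understood by the network simulator.
.reserved_pools <- c("HDO", "UNOBSERVED")

#' Relaxation parameters of the HDO internal standard
#'
#' Natural-abundance semi-heavy water resonates at 4.70 ppm; its relaxation
#' times at 9.4 T and 310 K are T1 = 630 ms and T2 = 610 ms.
#'
#' @return A `dmrs_species` describing HDO.
#' @export
hdo_species <- function() {
  species_spec("HDO", 4.70, 1, t1 = 0.630, t2 = 0.610, deuterons_per_molecule = 1)
}

#' First-order conversion edge with deuteron routing
#'
#' Each edge converts substrate deuterium at a first-order rate; the deuterons
#' leaving the substrate are routed between the product pool, semi-heavy water
#' (exchange loss) and an unobserved pool (metabolites below the detection
#' limit, protein incorporation, evaporation).
#'
#' @param substrate Substrate species name.
#' @param product Product species name, or one of the reserved pools
#'   `"HDO"` / `"UNOBSERVED"`.
#' @param rate_k First-order rate constant, per minute; must be >= 0.
#' @param retained,to_hdo,to_unobserved Routing fractions for the deuterium
#'   leaving the substrate; each in \[0, 1\] and summing to 1.
#' @return An object of class `dmrs_edge`.
#' @export
reaction_edge <- function(substrate, product, rate_k,
                          retained = 1, to_hdo = 0, to_unobserved = 0) {
  stopifnot(is.character(substrate), is.character(product))
  if (!is.numeric(rate_k) || length(rate_k) != 1L || rate_k < 0)
    stop("rate_k must be a single nonnegative number (per minute)")
  fr <- c(retained = retained, to_hdo = to_hdo, to_unobserved = to_unobserved)
  if (any(fr < 0) || any(fr > 1))
    stop("routing fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-12)
    stop("routing fractions must sum to 1 (got ", format(sum(fr), digits = 15), ")")
  structure(list(substrate = substrate, product = product,
                 rate_k = as.numeric(rate_k), routing = fr),
            class = "dmrs_edge")
}

#' Assemble a first-order deuterium reaction network
#'
#' @param species List of [species_spec()] objects (HDO is implicit and must
#'   not be declared).
#' @param edges List of [reaction_edge()] objects. Every endpoint must name a
#'   declared species or a reserved pool (`"HDO"`, `"UNOBSERVED"`).
#' @param initial_d Named numeric vector, initial deuterium concentration per
#'   species in mM (deuterons, not molecules). Unnamed species start at 0.
#' @param hdo_baseline Natural-abundance HDO baseline in mM: 17.3 for pure
#'   buffer, 15 in the presence of yeast.
#' @param residual_d Named numeric vector, the part of a species' deuterium
#'   that never reacts (constant offset reproducing nonzero substrate
#'   asymptotes). Defaults to 0 for all species.
#' @return An object of class `dmrs_network`.
#' @examples
#' fum <- species_spec("Fum", 6.653, 2, 0.247, 0.246)
#' mal <- species_spec("Mal", c(4.368, 2.474), c(1, 1), c(0.153, 0.142),
#'                     c(0.152, 0.140), 2)
#' net <- reaction_network(
#'   list(fum, mal),
#'   list(reaction_edge("Fum", "Mal", 0.0561)),
#'   initial_d = c(Fum = 44), hdo_baseline = 15)
#' @export
reaction_network <- function(species, edges = list(), initial_d = numeric(),
                             hdo_baseline = 17.3, residual_d = numeric()) {
  if (inherits(species, "dmrs_species")) species <- list(species)
  ok <- vapply(species, inherits, logical(1), "dmrs_species")
  if (!all(ok)) stop("species must be a list of dmrs_species objects")
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate species names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(nm %in% .reserved_pools))
    stop("'HDO' and 'UNOBSERVED' are reserved pool names")
  if (inherits(edges, "dmrs_edge")) edges <- list(edges)
  ok <- vapply(edges, inherits, logical(1), "dmrs_edge")
  if (length(edges) && !all(ok)) stop("edges must be a list of dmrs_edge objects")
  for (e in edges) {
    if (!e$substrate %in% nm)
      stop("edge substrate '", e$substrate, "' is not a declared species")
    if (!e$product %in% c(nm, .reserved_pools))
      stop("edge product '", e$product, "' is neither a declared species nor a reserved pool")
  }
  key <- vapply(edges, function(e) paste(e$substrate, e$product, sep = "->"), character(1))
  if (anyDuplicated(key)) stop("at most one edge per (substrate, product) pair; duplicated: ",
                               paste(unique(key[duplicated(key)]), collapse = ", "))
  init <- stats::setNames(numeric(length(nm)), nm)
  if (length(initial_d)) {
    bad <- setdiff(names(initial_d), nm)
    if (length(bad)) stop("initial_d names not in species: ", paste(bad, collapse = ", "))
    init[names(initial_d)] <- as.numeric(initial_d)
  }
  resid <- stats::setNames(numeric(length(nm)), nm)
  if (length(residual_d)) {
    bad <- setdiff(names(residual_d), nm)
    if (length(bad)) stop("residual_d names not in species: ", paste(bad, collapse = ", "))
    resid[names(residual_d)] <- as.numeric(residual_d)
  }
  if (any(init < 0) || any(resid < 0) || hdo_baseline < 0)
    stop("concentrations must be nonnegative")
  if (any(resid > init + 1e-12))
    stop("residual_d cannot exceed initial_d")
  structure(list(species = species, edges = edges, initial_d = init,
                 residual_d = resid, hdo_baseline = as.numeric(hdo_baseline)),
            class = "dmrs_network")
}

#' @export
print.dmrs_network <- function(x, ...) {
  cat("<dmrs_network> ", length(x$species), " species, ", length(x$edges),
      " edges, HDO baseline ", x$hdo_baseline, " mM\n", sep = "")
  for (e in x$edges)
    cat(sprintf("  %s -> %s  k = %g /min  (retained %.3g, to HDO %.3g, unobserved %.3g)\n",
                e$substrate, e$product, e$rate_k,
                e$routing["retained"], e$routing["to_hdo"], e$routing["to_unobserved"]))
  invisible(x)
}

#' Catalogue of tracer NMR parameters
#'
#' Chemical shifts and relaxation times (9.4 T, 310 K, PBS) for the deuterated
#' tracers and metabolic products used by the bundled study fixtures. Values
#' are per-site where resolved, otherwise the total effective ("tot") value.
#'
#' @param names Optional character vector to subset by species name.
#' @return A named list of [species_spec()] objects.
#' @export
tracer_catalog <- function(names = NULL) {
  cat_ <- list(
    # Glc-d2: two CD(6,6') sites at 3.844/3.975 ppm, T1/T2 "tot" 77 ms.
    Glc2 = species_spec("Glc2", c(3.844, 3.975), c(1, 1),
                        t1 = 0.077, t2 = 0.077, deuterons_per_molecule = 2),
    # Glc-d7: alpha-anomer CD(1) at 5.275 plus the unresolved 3.36-3.92 band,
    # represented by two effective lines; the beta-anomer CD(1) overlaps water
    # and is not modelled.
    Glc7 = species_spec("Glc7", c(5.275, 3.771, 3.510), c(1, 3, 3),
                        t1 = c(0.073, 0.075, 0.075), t2 = c(0.055, 0.063, 0.063),
                        deuterons_per_molecule = 7),
    Pyr  = species_spec("Pyr", 2.468, 3, t1 = 2.010, t2 = 1.950,
                        deuterons_per_molecule = 3),
    # Ethanol isotopomers produced from glucose/pyruvate (CD2/CD3 at ~1.25 ppm).
    Eth2 = species_spec("Eth2", 1.25, 2, t1 = 1.100, t2 = 1.250,
                        deuterons_per_molecule = 2),
    Eth3 = species_spec("Eth3", 1.2261, 3, t1 = 1.102, t2 = 1.250,
                        deuterons_per_molecule = 3),
    Ac2  = species_spec("Ac2", 1.867, 2, t1 = 3.140, t2 = 3.300,
                        deuterons_per_molecule = 2),
    Ac3  = species_spec("Ac3", 1.9775, 3, t1 = 3.140, t2 = 3.300,
                        deuterons_per_molecule = 3),
    Fum  = species_spec("Fum", 6.653, 2, t1 = 0.247, t2 = 0.246,
                        deuterons_per_molecule = 2),
    Mal  = species_spec("Mal", c(4.368, 2.474), c(1, 1),
                        t1 = c(0.153, 0.142), t2 = c(0.152, 0.140),
                        deuterons_per_molecule = 2),
    Ace  = species_spec("Ace", 2.323, 6, t1 = 3.532, t2 = 3.487,
                        deuterons_per_molecule = 6),
    Prop = species_spec("Prop", 1.201, 6, t1 = 0.713, t2 = 0.711,
                        deuterons_per_molecule = 6),
    NAM  = species_spec("NAM", c(9.094, 8.876, 8.420, 7.772), c(1, 1, 1, 1),
                        t1 = c(0.199, 0.147, 0.208, 0.173),
                        t2 = c(0.180, 0.066, 0.153, 0.262),
                        deuterons_per_molecule = 4),
    NA_  = species_spec("NA_", c(9.031, 8.714, 8.376, 7.659), c(1, 1, 1, 1),
                        t1 = c(0.201, 0.146, 0.225, 0.230),
                        t2 = c(0.177, 0.059, 0.147, 0.228),
                        deuterons_per_molecule = 4))
  if (!is.null(names)) {
    bad <- setdiff(names, base::names(cat_))
    if (length(bad)) stop("unknown tracer(s): ", paste(bad, collapse = ", "))
    cat_ <- cat_[names]
  }
  cat_
}
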