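#' Configuration for the coevolution simulator
#'
#' Builds and validates the full parameter set of the individual-based
#' host-parasite model. Hosts are diploid; each allele is a point on an
#' integer `grid_size` x `grid_size` paratope grid, and each parasite
#' genotype is a single point on the same grid. Recognition probability
#' decays with Euclidean distance under a Gaussian kernel of width
#' `recognition_scale`.
#'
#' @param host_pop_size Number of diploid hosts (>= 2).
#' @param parasite_pop_size Number of parasite genotypes per species (>= 2).
#' @param host_mut_rate Mutation probability per host allele per transmission.
#' @param parasite_mut_rate Mutation probability per parasite genotype per
#'   generation.
#' @param seeding_fraction Fraction of each parasite pool replaced every
#'   generation by genotypes drawn uniformly at random on the grid.
#' @param n_parasite_species Number of independently evolving parasite pools.
#' @param grid_size Side length of the paratope grid; coordinates live in
#'   `[0, grid_size)`.
#' @param generations Number of generations to iterate.
#' @param host_selection,parasite_selection Logical; when `FALSE` the
#'   corresponding population is recruited uniformly at random (neutrally).
#' @param recognition_scale Width (grid units) of the Gaussian recognition
#'   kernel `exp(-d^2 / (2 * recognition_scale^2))`.
#' @param selection_strength Exponent applied to host fitness before
#'   fitness-proportional recruitment (`w^selection_strength`); 1 is
#'   proportional selection, larger values sharpen selection.
#' @param parasite_selection_strength Exponent applied to parasite fitness;
#'   defaults to `NULL`, meaning the same value as `selection_strength`.
#' @param mutation_step_scale Standard deviation (grid units) of the isotropic
#'   Gaussian mutation step, rounded to the integer grid and reflected at the
#'   boundaries.
#' @param exposure_sample Number of parasites (per species) each host
#'   encounters per generation when computing its fitness; `Inf` exposes every
#'   host to the whole pool. Finite exposure adds realized-encounter noise
#'   (genetic draft) to host selection.
#' @param sample_size Number of individuals sampled per recorded generation for
#'   the effective-number-of-alleles summary.
#' @param supertype_threshold Single-linkage distance threshold (grid units)
#'   used when summarising alleles into supertype clusters.
#' @param record_every Thinning interval (generations) for trajectory records.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(host_pop_size = 50, parasite_pop_size = 50, generations = 10)
sim_config <- function(host_pop_size = 2500,
                       parasite_pop_size = 1000,
                       host_mut_rate = 0.1,
                       parasite_mut_rate = 0.1,
                       seeding_fraction = 0.01,
                       n_parasite_species = 1,
                       grid_size = 1000,
                       generations = 600,
                       host_selection = TRUE,
                       parasite_selection = TRUE,
                       recognition_scale = 300,
                       selection_strength = 4,
                       parasite_selection_strength = NULL,
                       mutation_step_scale = 10,
                       exposure_sample = Inf,
                       sample_size = 100,
                       supertype_threshold = 100,
                       record_every = 10) {
  cfg <- list(
    host_pop_size = as.integer(host_pop_size),
    parasite_pop_size = as.integer(parasite_pop_size),
    host_mut_rate = host_mut_rate,
    parasite_mut_rate = parasite_mut_rate,
    seeding_fraction = seeding_fraction,
    n_parasite_species = as.integer(n_parasite_species),
    grid_size = as.integer(grid_size),
    generations = as.integer(generations),
    host_selection = isTRUE(host_selection),
    parasite_selection = isTRUE(parasite_selection),
    recognition_scale = recognition_scale,
    selection_strength = selection_strength,
    parasite_selection_strength =
      if (is.null(parasite_selection_strength)) selection_strength
      else parasite_selection_strength,
    mutation_step_scale = mutation_step_scale,
    exposure_sample = exposure_sample,
    sample_size = as.integer(sample_size),
    supertype_threshold = supertype_threshold,
    record_every = as.integer(record_every)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$host_pop_size < 2 || cfg$parasite_pop_size < 2) {
    abort("population sizes must be >= 2", class = "mhc_config_error")
  }
  rates <- c(
    host_mut_rate = cfg$host_mut_rate,
    parasite_mut_rate = cfg$parasite_mut_rate,
    seeding_fraction = cfg$seeding_fraction
  )
  bad <- rates < 0 | rates > 1 | !is.finite(rates)
  if (any(bad)) {
    abort(
      paste0("rates must lie in [0, 1]: ", paste(names(rates)[bad], collapse = ", ")),
      class = "mhc_config_error"
    )
  }
  if (cfg$grid_size < 2) abort("grid_size must be >= 2", class = "mhc_config_error")
  if (cfg$n_parasite_species < 1) {
    abort("n_parasite_species must be >= 1", class = "mhc_config_error")
  }
  if (cfg$recognition_scale <= 0 || cfg$mutation_step_scale < 0) {
    abort("scales must be positive", class = "mhc_config_error")
  }
  if (cfg$selection_strength <= 0 || cfg$parasite_selection_strength <= 0) {
    abort("selection strengths must be > 0", class = "mhc_config_error")
  }
  if (!(is.infinite(cfg$exposure_sample) || cfg$exposure_sample >= 1)) {
    abort("exposure_sample must be >= 1 or Inf", class = "mhc_config_error")
  }
  if (cfg$record_every < 1) abort("record_every must be >= 1", class = "mhc_config_error")
  invisible(cfg)
}

#' Expected neutral equilibrium heterozygosity
#'
#' Closed-form equilibrium heterozygosity under the neutral infinite-alleles
#' model, `H = 4 Ne mu / (1 + 4 Ne mu)`. Useful as a yardstick for how much
#' allelic diversity a given mutation rate can sustain by drift-mutation
#' balance alone, without any parasite-mediated selection.
#'
#' @param Ne Effective population size (>= 1).
#' @param mu Mutation rate per allele per generation (>= 0).
#' @return Heterozygosity in `[0, 1)`.
#' @export
#' @examples
#' expected_heterozygosity(1e4, 1e-3)
expected_heterozygosity <- function(Ne, mu) {
  if (any(Ne < 1) || any(mu < 0)) {
    abort("Ne must be >= 1 and mu >= 0", class = "mhc_domain_error")
  }
  theta <- 4 * Ne * mu
  theta / (1 + theta)
}
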