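#' Scenario presets for the coevolution model
#'
#' Named parameterizations of [sim_config()]:
#' \describe{
#'   \item{original}{High host mutation rate (1e-1), 1% random parasite
#'     seeding per generation, one parasite species, selection on both sides.}
#'   \item{fig2a}{Host mutation 1e-3, parasite mutation 1e-2, host population
#'     raised to 1e5.}
#'   \item{fig2b}{Parasite selection switched off (neutral parasite
#'     recruitment), seeding retained.}
#'   \item{fig2c}{No random seeding of the parasite pool; mutation parameters
#'     as in `original`.}
#'   \item{fig2d}{As `fig2c` but ten independently evolving parasite species.}
#'   \item{custom}{The [sim_config()] defaults, to be overridden freely.}
#' }
#'
#' @param name Preset name.
#' @param overrides Named list of [sim_config()] arguments overriding the
#'   preset.
#' @return A `sim_config`.
#' @export
scenario_config <- function(name = c("original", "fig2a", "fig2b", "fig2c", "fig2d", "custom"),
                            overrides = list()) {
  presets <- list(
    original = list(),
    fig2a = list(host_mut_rate = 1e-3, parasite_mut_rate = 1e-2, host_pop_size = 1e5),
    fig2b = list(parasite_selection = FALSE),
    fig2c = list(seeding_fraction = 0),
    fig2d = list(seeding_fraction = 0, n_parasite_species = 10),
    custom = list()
  )
  if (length(name) != 1L || !name %in% names(presets)) {
    abort(
      paste0(
        "unknown scenario; available presets: ",
        paste(names(presets), collapse = ", ")
      ),
      class = "mhc_config_error"
    )
  }
  args <- utils::modifyList(presets[[name]], overrides)
  do.call(sim_config, args)
}

#' Run a coevolution scenario and record its trajectory
#'
#' Iterates the individual-based model for `config$generations` generations,
#' recording every `config$record_every` generations: the host allele count
#' table, per-species parasite genotype counts, the supertype assignment of
#' host alleles (single-linkage at `config$supertype_threshold`), supertype
#' centroids, and the effective number of alleles in a random sample of
#' `config$sample_size` individuals.
#'
#' @param scenario Preset name passed to [scenario_config()], or a
#'   `sim_config` object used as-is.
#' @param overrides Named list of parameter overrides.
#' @param seed Integer seed; when non-`NULL`, `set.seed(seed)` is called so
#'   the whole trajectory is reproducible.
#' @return A `coevo_sim` object: list with `trajectory` (tibble `generation,
#'   type, x, y, count, supertype`), `summary` (tibble `generation,
#'   n_supertypes, n_alleles, effective_alleles`), `centroids` (tibble
#'   `generation, supertype, cx, cy, size`), `config`, `seed`, `log` and the
#'   `final` state.
#' @export
#' @examples
#' sim <- run_scenario("original",
#'   overrides = list(host_pop_size = 100, parasite_pop_size = 100, generations = 20),
#'   seed = 1
#' )
#' glance(sim)
run_scenario <- function(scenario = "original", overrides = list(), seed = NULL) {
  config <- if (inherits(scenario, "sim_config")) {
    if (length(overrides)) {
      do.call(sim_config, utils::modifyList(unclass(scenario)[names(formals(sim_config))], overrides))
    } else {
      scenario
    }
  } else {
    scenario_config(scenario, overrides)
  }
  if (!is.null(seed)) set.seed(seed)

  state <- init_state(config)
  rec_gens <- unique(c(seq(0L, config$generations, by = config$record_every), config$generations))
  traj <- list()
  summ <- list()
  cents <- list()

  record <- function(state) {
    rec <- record_state(state, config)
    traj[[length(traj) + 1L]] <<- rec$trajectory
    summ[[length(summ) + 1L]] <<- rec$summary
    cents[[length(cents) + 1L]] <<- rec$centroids
  }
  record(state)
  for (gen in seq_len(config$generations)) {
    state <- step_generation(state, config)
    if (gen %in% rec_gens) record(state)
  }

  structure(
    list(
      trajectory = bind_rows(traj),
      summary = bind_rows(summ),
      centroids = bind_rows(cents),
      config = config,
      seed = seed,
      log = state$log,
      final = state
    ),
    class = "coevo_sim"
  )
}

## Summarise one state into trajectory / summary / centroid records.
record_state <- function(state, config) {
  g <- as.numeric(config$grid_size)
  hosts <- state$hosts
  n <- nrow(hosts)
  akey <- c(hosts[, 1L] * g + hosts[, 2L], hosts[, 3L] * g + hosts[, 4L])
  cnt <- table(akey)
  ax <- as.numeric(names(cnt)) %/% g
  ay <- as.numeric(names(cnt)) %% g
  alleles <- tibble(x = ax, y = ay, count = as.integer(cnt))
  st <- cluster_supertypes(alleles, threshold = config$supertype_threshold)
  cent <- attr(st, "centroids")

  host_rows <- st %>% mutate(generation = state$generation, type = "host_allele")
  par_rows <- imap(state$parasites, function(p, sp) {
    pk <- table(p[, 1L] * g + p[, 2L])
    tibble(
      generation = state$generation,
      type = paste0("parasite:", sp),
      x = as.numeric(names(pk)) %/% g,
      y = as.numeric(names(pk)) %% g,
      count = as.integer(pk),
      supertype = NA_character_
    )
  })
  trajectory <- bind_rows(
    host_rows[, c("generation", "type", "x", "y", "count", "supertype")],
    bind_rows(par_rows)
  )

  idx <- sample.int(n, min(config$sample_size, n))
  sampled <- c(akey[idx], akey[n + idx])
  summary <- tibble(
    generation = state$generation,
    n_supertypes = nrow(cent),
    n_alleles = nrow(alleles),
    effective_alleles = effective_n_alleles(as.character(sampled))
  )
  centroids <- cent %>% mutate(generation = state$generation, .before = 1L)
  list(trajectory = trajectory, summary = summary, centroids = centroids)
}

#' @export
print.coevo_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<coevo_sim> %d generations, %d hosts, %d parasite species x %d\n",
    cfg$generations, cfg$host_pop_size, cfg$n_parasite_species, cfg$parasite_pop_size
  ))
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "final: %d supertypes, %d distinct alleles, effective alleles %.1f (sample of %d)\n",
    last$n_supertypes, last$n_alleles, last$effective_alleles, cfg$sample_size
  ))
  if (length(x$log)) cat(length(x$log), "log entries\n")
  invisible(x)
}

#' Write a recorded trajectory and its supertype summary to CSV
#'
#' @param sim A `coevo_sim` object.
#' @param path Path of the trajectory CSV (one row per generation x coordinate
#'   x type). The summary is written next to it with suffix `_summary.csv`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  utils::write.csv(sim$trajectory, path, row.names = FALSE)
  utils::write.csv(sim$summary, sub("\\.csv$", "_summary.csv", path), row.names = FALSE)
  invisible(path)
}
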