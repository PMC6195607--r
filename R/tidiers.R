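#' Tidy a coevolution simulation
#'
#' @param x A `coevo_sim` object.
#' @param ... Unused.
#' @return The recorded trajectory: tibble `generation, type, x, y, count,
#'   supertype`.
#' @export
tidy.coevo_sim <- function(x, ...) {
  as_tibble(x$trajectory)
}

#' One-row summary of a coevolution simulation
#'
#' Medians of the supertype count, distinct-allele count and effective number
#' of alleles over the second half of the recorded trajectory (the
#' quasi-equilibrium window), plus run metadata.
#'
#' @param x A `coevo_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.coevo_sim <- function(x, ...) {
  s <- x$summary
  late <- s[s$generation >= max(s$generation) / 2, ]
  tibble(
    generations = x$config$generations,
    host_pop_size = x$config$host_pop_size,
    n_parasite_species = x$config$n_parasite_species,
    median_supertypes = median(late$n_supertypes),
    median_alleles = median(late$n_alleles),
    median_effective_alleles = median(late$effective_alleles),
    n_log_events = length(x$log)
  )
}

#' Plot the supertype and allelic diversity trajectory of a simulation
#'
#' @param object A `coevo_sim` object.
#' @param ... Unused.
#' @return A ggplot: supertype count and effective number of alleles over
#'   generations, on free y scales.
#' @export
autoplot.coevo_sim <- function(object, ...) {
  s <- object$summary %>%
    tidyr::pivot_longer(c("n_supertypes", "effective_alleles"),
      names_to = "metric", values_to = "value"
    ) %>%
    mutate(metric = dplyr::recode(.data$metric,
      n_supertypes = "supertype clusters",
      effective_alleles = "effective alleles (sample)"
    ))
  ggplot2::ggplot(s, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Snapshot of paratope space at one recorded generation
#'
#' @param sim A `coevo_sim` object.
#' @param generation Recorded generation to plot; default the last one.
#' @return A ggplot of host alleles (coloured by supertype) and parasite
#'   genotypes (grey) on the grid.
#' @export
plot_paratope_space <- function(sim, generation = NULL) {
  tr <- sim$trajectory
  generation <- generation %||% max(tr$generation)
  snap <- tr[tr$generation == generation, ]
  hosts <- snap[snap$type == "host_allele", ]
  pars <- snap[snap$type != "host_allele", ]
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = pars,
      ggplot2::aes(.data$x, .data$y, size = .data$count),
      colour = "grey60", alpha = 0.5
    ) +
    ggplot2::geom_point(
      data = hosts,
      ggplot2::aes(.data$x, .data$y, size = .data$count, colour = .data$supertype)
    ) +
    ggplot2::coord_fixed(
      xlim = c(0, sim$config$grid_size),
      ylim = c(0, sim$config$grid_size)
    ) +
    ggplot2::labs(
      title = paste("generation", generation),
      x = "paratope x", y = "paratope y"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a structure analysis
#'
#' @param x An `st_structure` object.
#' @param ... Unused.
#' @return Tibble `population, observed, expected_mean, expected_sd,
#'   allele_level`.
#' @export
tidy.st_structure <- function(x, ...) {
  as_tibble(x$result)
}

#' One-row summary of a structure analysis
#'
#' @param x An `st_structure` object.
#' @param ... Unused.
#' @return A one-row tibble with dataset-level means and the mean z-score of
#'   observed against the randomized expectation.
#' @export
glance.st_structure <- function(x, ...) {
  r <- x$result
  z <- (r$observed - r$expected_mean) / r$expected_sd
  tibble(
    n_populations = nrow(r),
    mean_observed = mean(r$observed),
    mean_expected = mean(r$expected_mean),
    mean_diff = mean(r$observed - r$expected_mean),
    mean_z = mean(z[is.finite(z)]),
    n_reps = x$n_reps,
    estimator = x$estimator
  )
}

#' Plot observed versus expected supertype structure
#'
#' The classic red/blue dot plot: observed supertype-level mean pairwise
#' Jost's D per population against the label-randomization expectation with
#' +/- 2 SD error bars.
#'
#' @param object An `st_structure` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.st_structure <- function(object, ...) {
  r <- object$result
  ggplot2::ggplot(r, ggplot2::aes(x = .data$population)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$expected_mean - 2 * .data$expected_sd,
        ymax = .data$expected_mean + 2 * .data$expected_sd
      ),
      width = 0.2, colour = "steelblue"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_mean),
      colour = "steelblue", size = 2
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
      colour = "firebrick", size = 2
    ) +
    ggplot2::labs(
      y = "mean pairwise Jost's D (supertype level)",
      x = NULL,
      caption = "red: observed; blue: label-randomized expectation (+/- 2 SD)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tidy a jackknife analysis
#'
#' @param x An `st_jackknife` object.
#' @param ... Unused.
#' @return The per-supertype summary tibble.
#' @export
tidy.st_jackknife <- function(x, ...) {
  as_tibble(x$result)
}

#' Plot per-supertype jackknife summaries
#'
#' @param object An `st_jackknife` object.
#' @param ... Unused.
#' @return A ggplot of the mean (observed - expected) difference after
#'   removing each supertype, with +/- 1 SD bars; the dashed line marks the
#'   full dataset's value.
#' @export
autoplot.st_jackknife <- function(object, ...) {
  r <- object$result
  full <- r$mean_diff[r$supertype == "(none)"]
  r <- r[r$supertype != "(none)", ]
  ggplot2::ggplot(r, ggplot2::aes(.data$supertype, .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = full, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_diff - .data$sd_diff,
      ymax = .data$mean_diff + .data$sd_diff
    )) +
    ggplot2::labs(
      x = "removed supertype",
      y = "mean (observed - expected) Jost's D"
    ) +
    ggplot2::theme_minimal()
}
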