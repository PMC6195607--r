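#' Allele or supertype frequencies for one population
#'
#' Frequencies are estimated from pooled allele occurrences: each allele an
#' individual carries is counted once, regardless of (unknowable) copy
#' number, and counts are normalised within the population. With
#' `level = "supertype"` occurrences are first collapsed through the
#' allele-to-supertype map.
#'
#' @param genotypes Data frame with columns `population`, `individual`,
#'   `allele` (one row per allele an individual carries).
#' @param pop Population name.
#' @param level `"allele"` or `"supertype"`.
#' @param st_map Data frame `allele, supertype`; required for supertype level.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
unit_frequencies <- function(genotypes, pop, level = c("allele", "supertype"),
                             st_map = NULL) {
  level <- match.arg(level)
  g <- genotypes[genotypes$population == pop, , drop = FALSE]
  if (nrow(g) == 0L) abort(paste0("empty population: ", pop), class = "mhc_domain_error")
  units <- as.character(g$allele)
  if (level == "supertype") {
    units <- map_alleles(units, st_map)
  }
  tab <- table(units)
  setNames(as.vector(tab) / sum(tab), names(tab))
}

map_alleles <- function(alleles, st_map) {
  if (is.null(st_map)) abort("st_map required at supertype level", class = "mhc_domain_error")
  m <- setNames(as.character(st_map$supertype), as.character(st_map$allele))
  mapped <- m[alleles]
  if (anyNA(mapped)) {
    abort(
      paste0(
        "alleles missing from supertype map: ",
        paste(unique(alleles[is.na(mapped)]), collapse = ", ")
      ),
      class = "mhc_domain_error"
    )
  }
  unname(mapped)
}

#' Pairwise Jost's D between two demes
#'
#' Jost's differentiation measure for two demes,
#' `D = (Ht - Hs) / (1 - Hs) * n/(n-1)` with `n = 2`. With
#' `estimator = "nei_chesser"`, within- and total-heterozygosity are
#' sample-size corrected: `Hs = nh/(nh-1) * mean(1 - sum p^2)` with `nh` the
#' harmonic mean sample size, and `Ht = 1 - sum(pbar^2) + Hs/(2 nh)`. With
#' `estimator = "naive"` the raw frequencies are used.
#'
#' @param freqs_a,freqs_b Named frequency vectors (allele or supertype level);
#'   indices are merged by name, absent entries count as frequency 0.
#' @param n_a,n_b Sample sizes (pooled allele occurrence counts) of the two
#'   demes; only used by the corrected estimator.
#' @param estimator `"nei_chesser"` (default) or `"naive"`.
#' @return Scalar D (can be slightly negative under the corrected estimator;
#'   `NA` with a warning if `Hs = 1`).
#' @export
#' @examples
#' jost_dest(c(a = 1), c(b = 1), 10, 10) # complete differentiation: 1
jost_dest <- function(freqs_a, freqs_b, n_a = NULL, n_b = NULL,
                      estimator = c("nei_chesser", "naive")) {
  estimator <- match.arg(estimator)
  ids <- union(names(freqs_a), names(freqs_b))
  if (is.null(ids)) abort("frequency vectors must be named", class = "mhc_domain_error")
  pa <- setNames(numeric(length(ids)), ids)
  pb <- pa
  pa[names(freqs_a)] <- freqs_a
  pb[names(freqs_b)] <- freqs_b
  pbar <- (pa + pb) / 2
  hs_raw <- mean(c(1 - sum(pa^2), 1 - sum(pb^2)))
  ht_raw <- 1 - sum(pbar^2)
  if (estimator == "nei_chesser") {
    if (is.null(n_a) || is.null(n_b) || n_a < 1 || n_b < 1) {
      abort("sample sizes >= 1 required for the corrected estimator",
        class = "mhc_domain_error"
      )
    }
    if (n_a < 2 || n_b < 2) {
      ## correction undefined at n = 1; fall back to raw
      hs <- hs_raw
      ht <- ht_raw
    } else {
      nh <- 2 / (1 / n_a + 1 / n_b)
      hs <- nh / (nh - 1) * hs_raw
      ht <- ht_raw + hs / (2 * nh)
    }
  } else {
    hs <- hs_raw
    ht <- ht_raw
  }
  if (hs >= 1) {
    warn("within-deme heterozygosity is 1; Jost's D undefined")
    return(NA_real_)
  }
  2 * (ht - hs) / (1 - hs)
}

## Per-population frequency vectors and sample sizes at a given level.
pop_freqs <- function(genotypes, level, st_map) {
  pops <- unique(as.character(genotypes$population))
  freqs <- lapply(pops, function(p) unit_frequencies(genotypes, p, level, st_map))
  sizes <- vapply(
    pops,
    function(p) sum(genotypes$population == p), numeric(1)
  )
  list(pops = pops, freqs = setNames(freqs, pops), sizes = setNames(sizes, pops))
}

#' Mean pairwise Jost's D per population
#'
#' Computes pairwise D between all population pairs at the requested level and
#' returns, for each population, the mean of its pairwise values against all
#' other populations -- the "observed dots" of the structure analysis.
#'
#' @inheritParams unit_frequencies
#' @inheritParams jost_dest
#' @return Tibble `population, mean_dest`.
#' @export
mean_pairwise_dest <- function(genotypes, level = c("allele", "supertype"),
                               st_map = NULL,
                               estimator = c("nei_chesser", "naive")) {
  level <- match.arg(level)
  estimator <- match.arg(estimator)
  pf <- pop_freqs(genotypes, level, st_map)
  k <- length(pf$pops)
  if (k < 2L) abort("need at least two populations", class = "mhc_domain_error")
  dmat <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d <- jost_dest(pf$freqs[[i]], pf$freqs[[j]], pf$sizes[i], pf$sizes[j], estimator)
      dmat[i, j] <- dmat[j, i] <- d
    }
  }
  tibble(
    population = pf$pops,
    mean_dest = vapply(seq_len(k), function(i) mean(dmat[i, -i]), numeric(1))
  )
}

#' Randomized expectation of supertype-level structure
#'
#' The permutation null of the structure analysis: supertype labels are
#' reassigned at random over the set of unique alleles, preserving the number
#' of alleles in each supertype, and the supertype-level mean pairwise D is
#' recomputed. Means and standard deviations over `n_reps` permutations give
#' the "expected dots" and their error bars.
#'
#' @inheritParams mean_pairwise_dest
#' @param st_map Data frame `allele, supertype` (must cover every allele).
#' @param n_reps Number of label permutations.
#' @return Tibble `population, expected_mean, expected_sd`, with the
#'   per-repeat matrix in attribute `reps`.
#' @export
randomized_expectation <- function(genotypes, st_map, n_reps = 1000,
                                   estimator = c("nei_chesser", "naive")) {
  estimator <- match.arg(estimator)
  if (n_reps < 1) abort("n_reps must be >= 1", class = "mhc_domain_error")
  alleles <- as.character(st_map$allele)
  labels <- as.character(st_map$supertype)
  pops <- unique(as.character(genotypes$population))
  reps <- matrix(NA_real_, n_reps, length(pops), dimnames = list(NULL, pops))
  for (r in seq_len(n_reps)) {
    perm <- tibble(allele = alleles, supertype = sample(labels))
    md <- mean_pairwise_dest(genotypes, "supertype", perm, estimator)
    reps[r, md$population] <- md$mean_dest
  }
  out <- tibble(
    population = pops,
    expected_mean = unname(colMeans(reps, na.rm = TRUE)),
    expected_sd = unname(apply(reps, 2, stats::sd))
  )
  attr(out, "reps") <- reps
  out
}

#' Observed versus expected supertype structure
#'
#' Runs the full structure analysis: observed supertype-level mean pairwise
#' Jost's D per population (the "red dots"), the label-randomized expectation
#' with its SD (the "blue dots" and error bars), plus the allele-level
#' observed values for reference. An observed value below the expectation
#' band is the signature of balancing selection at the supertype level.
#'
#' @inheritParams randomized_expectation
#' @return An `st_structure` object; its `result` is a tibble `population,
#'   observed, expected_mean, expected_sd, allele_level`.
#' @export
supertype_structure <- function(genotypes, st_map, n_reps = 1000,
                                estimator = c("nei_chesser", "naive")) {
  estimator <- match.arg(estimator)
  observed <- mean_pairwise_dest(genotypes, "supertype", st_map, estimator)
  allele_level <- mean_pairwise_dest(genotypes, "allele", NULL, estimator)
  expected <- randomized_expectation(genotypes, st_map, n_reps, estimator)
  res <- observed %>%
    dplyr::rename(observed = "mean_dest") %>%
    left_join(expected, by = "population") %>%
    left_join(
      dplyr::rename(allele_level, allele_level = "mean_dest"),
      by = "population"
    )
  structure(
    list(result = res, n_reps = n_reps, estimator = estimator),
    class = "st_structure"
  )
}

#' @export
print.st_structure <- function(x, ...) {
  cat(sprintf(
    "<st_structure> %d populations, %d permutations, %s estimator\n",
    nrow(x$result), x$n_reps, x$estimator
  ))
  print(x$result)
  invisible(x)
}

#' Remove one supertype from a genotype table (jackknife)
#'
#' Deletes every occurrence of every allele of the focal supertype. Individuals
#' left with no alleles (those "homozygous" for the focal supertype) are
#' removed, and populations left empty or monomorphic at the supertype level
#' are dropped entirely (with a note in the `dropped` attribute), since they
#' carry no differentiation signal.
#'
#' @inheritParams randomized_expectation
#' @param focal_st Supertype label to remove.
#' @return List with `genotypes` (reduced table), `st_map` (reduced map) and
#'   `dropped` (character vector of dropped populations).
#' @export
jackknife_supertype <- function(genotypes, st_map, focal_st) {
  if (!focal_st %in% st_map$supertype) {
    abort(paste0("unknown supertype: ", focal_st), class = "mhc_domain_error")
  }
  keep_alleles <- as.character(st_map$allele[st_map$supertype != focal_st])
  g <- genotypes[as.character(genotypes$allele) %in% keep_alleles, , drop = FALSE]
  map2 <- st_map[st_map$supertype != focal_st, , drop = FALSE]

  dropped <- character()
  for (p in unique(as.character(genotypes$population))) {
    gp <- g[g$population == p, , drop = FALSE]
    sts <- unique(map_alleles(as.character(gp$allele), map2))
    if (nrow(gp) == 0L || length(sts) < 2L) {
      dropped <- c(dropped, p)
    }
  }
  g <- g[!(as.character(g$population) %in% dropped), , drop = FALSE]
  list(genotypes = as_tibble(g), st_map = as_tibble(map2), dropped = dropped)
}

#' Summarise a jackknifed structure analysis against the full one
#'
#' For one jackknifed dataset, computes the mean and SD of the per-population
#' difference between observed and expected supertype structure
#' (red minus blue), and the Spearman rank correlation between the jackknifed
#' observed values and the full dataset's observed values, over the shared
#' populations.
#'
#' @param full_result,jack_result `st_structure` objects (or their `result`
#'   tibbles) for the full and jackknifed datasets.
#' @return Tibble with one row: `mean_diff, sd_diff, spearman_rho, n_shared`.
#' @export
jackknife_summary <- function(full_result, jack_result) {
  f <- if (inherits(full_result, "st_structure")) full_result$result else full_result
  j <- if (inherits(jack_result, "st_structure")) jack_result$result else jack_result
  shared <- intersect(f$population, j$population)
  if (length(shared) == 0L) abort("no shared populations", class = "mhc_domain_error")
  f <- f[match(shared, f$population), ]
  j <- j[match(shared, j$population), ]
  diff <- j$observed - j$expected_mean
  rho <- if (isTRUE(all.equal(as.numeric(j$observed), as.numeric(f$observed)))) {
    1 # identical red vectors (e.g. jackknife of an absent supertype)
  } else {
    suppressWarnings(cor(j$observed, f$observed, method = "spearman"))
  }
  tibble(
    mean_diff = mean(diff), sd_diff = stats::sd(diff),
    spearman_rho = rho, n_shared = length(shared)
  )
}

#' Jackknife every supertype and summarise its influence
#'
#' Repeats the structure analysis with each supertype removed in turn and
#' summarises each jackknife with [jackknife_summary()]. A supertype whose
#' removal moves the mean (observed - expected) difference far from the full
#' dataset's value is the one driving the dataset-level signal.
#'
#' @inheritParams randomized_expectation
#' @param supertypes Labels to jackknife; default all in `st_map`.
#' @return An `st_jackknife` object; `result` is a tibble `supertype,
#'   n_alleles, mean_diff, sd_diff, spearman_rho, n_shared, dropped_pops`
#'   with the full dataset's row labelled `"(none)"`.
#' @export
jackknife_supertypes <- function(genotypes, st_map, n_reps = 200,
                                 estimator = c("nei_chesser", "naive"),
                                 supertypes = NULL) {
  estimator <- match.arg(estimator)
  full <- supertype_structure(genotypes, st_map, n_reps, estimator)
  sts <- supertypes %||% sort(unique(as.character(st_map$supertype)))
  full_row <- jackknife_summary(full, full) %>%
    mutate(supertype = "(none)", n_alleles = length(unique(st_map$allele)),
           dropped_pops = "", .before = 1L)
  rows <- map(sts, function(st) {
    jk <- jackknife_supertype(genotypes, st_map, st)
    res <- supertype_structure(jk$genotypes, jk$st_map, n_reps, estimator)
    jackknife_summary(full, res) %>%
      mutate(
        supertype = st,
        n_alleles = sum(st_map$supertype == st),
        dropped_pops = paste(jk$dropped, collapse = ";"),
        .before = 1L
      )
  })
  structure(
    list(result = bind_rows(c(list(full_row), rows)), full = full,
         n_reps = n_reps, estimator = estimator),
    class = "st_jackknife"
  )
}

#' @export
print.st_jackknife <- function(x, ...) {
  cat(sprintf("<st_jackknife> %d permutations, %s estimator\n", x$n_reps, x$estimator))
  print(x$result)
  invisible(x)
}

#' Randomized-deletion controls for one supertype's jackknife
#'
#' Assesses whether a supertype's jackknife signature merely reflects its
#' size or frequency, via three deletion schemes matched to the focal
#' supertype: `sequence_matched` removes all occurrences of a random subset
#' of unique alleles of the same cardinality as the focal supertype;
#' `frequency_matched` removes the same total number of occurrence records,
#' drawn at random without targeting any particular allele;
#' `population_stratified` removes, within each population, as many records
#' as the focal supertype has there. After each deletion, emptied individuals
#' and supertype-monomorphic populations are dropped and the structure
#' analysis is rerun.
#'
#' @inheritParams randomized_expectation
#' @param focal_st Focal supertype label.
#' @param scheme Deletion scheme.
#' @param n_reps Number of random deletions.
#' @param n_null Permutations used inside each structure analysis.
#' @return Tibble `rep, scheme, mean_diff, sd_diff, spearman_rho, n_shared`,
#'   with attribute `deletions`: the list of deleted row indices per repeat.
#' @export
random_deletion_control <- function(genotypes, st_map, focal_st,
                                    scheme = c(
                                      "sequence_matched", "frequency_matched",
                                      "population_stratified"
                                    ),
                                    n_reps = 20, n_null = 100,
                                    estimator = c("nei_chesser", "naive")) {
  scheme <- match.arg(scheme)
  estimator <- match.arg(estimator)
  if (!focal_st %in% st_map$supertype) {
    abort(paste0("unknown supertype: ", focal_st), class = "mhc_domain_error")
  }
  full <- supertype_structure(genotypes, st_map, n_null, estimator)
  focal_alleles <- as.character(st_map$allele[st_map$supertype == focal_st])
  alleles_in_table <- as.character(genotypes$allele)
  focal_rows <- alleles_in_table %in% focal_alleles

  deletions <- vector("list", n_reps)
  rows <- map(seq_len(n_reps), function(r) {
    del <- switch(scheme,
      sequence_matched = {
        victims <- sample(unique(alleles_in_table), length(focal_alleles))
        which(alleles_in_table %in% victims)
      },
      frequency_matched = {
        k <- sum(focal_rows)
        if (k > nrow(genotypes)) {
          abort("deletion count exceeds available records", class = "mhc_domain_error")
        }
        sample(nrow(genotypes), k)
      },
      population_stratified = {
        unlist(lapply(unique(as.character(genotypes$population)), function(p) {
          in_pop <- which(genotypes$population == p)
          k <- sum(focal_rows[in_pop])
          if (k > length(in_pop)) {
            abort("deletion count exceeds available records", class = "mhc_domain_error")
          }
          sample(in_pop, k)
        }))
      }
    )
    deletions[[r]] <<- sort(del)
    g <- if (length(del)) genotypes[-del, , drop = FALSE] else genotypes
    ## drop populations left monomorphic (or empty) at supertype level
    dropped <- character()
    for (p in unique(as.character(g$population))) {
      gp <- g[g$population == p, , drop = FALSE]
      sts <- unique(map_alleles(as.character(gp$allele), st_map))
      if (nrow(gp) == 0L || length(sts) < 2L) dropped <- c(dropped, p)
    }
    g <- g[!(as.character(g$population) %in% dropped), , drop = FALSE]
    map2 <- st_map[st_map$allele %in% g$allele, , drop = FALSE]
    res <- supertype_structure(g, map2, n_null, estimator)
    jackknife_summary(full, res) %>% mutate(rep = r, scheme = scheme, .before = 1L)
  })
  out <- bind_rows(rows)
  attr(out, "deletions") <- deletions
  out
}

#' Fraction of supertype-homozygous individuals
#'
#' An individual is a "supertype homozygote" when all its detected alleles
#' map to a single supertype (true zygosity being unknowable from ambiguous
#' multi-locus genotypes). With `exclude_st`, that supertype's alleles are
#' removed first and individuals left without alleles are dropped.
#'
#' @inheritParams randomized_expectation
#' @param exclude_st Optional supertype label to remove before counting.
#' @return Fraction in `[0, 1]`.
#' @export
st_homozygosity_fraction <- function(genotypes, st_map, exclude_st = NULL) {
  g <- genotypes
  map <- st_map
  if (!is.null(exclude_st)) {
    keep <- as.character(st_map$allele[st_map$supertype != exclude_st])
    g <- g[as.character(g$allele) %in% keep, , drop = FALSE]
    map <- st_map[st_map$supertype != exclude_st, , drop = FALSE]
  }
  if (nrow(g) == 0L) abort("no individuals left after exclusion", class = "mhc_domain_error")
  key <- paste(g$population, g$individual, sep = "\r")
  sts <- map_alleles(as.character(g$allele), map)
  n_st <- tapply(sts, key, function(x) length(unique(x)))
  mean(n_st == 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
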