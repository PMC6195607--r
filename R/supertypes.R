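#' Delimit supertypes by single-linkage clustering of allele coordinates
#'
#' Two alleles belong to the same supertype iff they are connected by a chain
#' of pairwise Euclidean distances no larger than `threshold` (the connected
#' components of the threshold graph). Labels are deterministic: clusters are
#' ordered by their lexicographically smallest member coordinate and named
#' `ST1, ST2, ...`.
#'
#' @param alleles Data frame with columns `x`, `y` and optionally `count`
#'   (copy number; defaults to 1). Rows must be distinct coordinates.
#' @param threshold Linkage distance threshold in grid units.
#'
#' @details Inputs with more than 4000 distinct coordinates are pre-coarsened
#'   to a lattice of pitch `threshold/5` before linkage (each point moves by
#'   less than `threshold/7`), which bounds memory while preserving the
#'   cluster structure at the threshold scale.
#' @return A tibble `x, y, count, supertype`, with a `centroids` attribute:
#'   a tibble `supertype, cx, cy, size` where centroids are count-weighted
#'   means and `size` is the summed copy number.
#' @export
#' @examples
#' a <- data.frame(x = c(0, 10, 500), y = c(0, 0, 500), count = c(2, 1, 3))
#' cluster_supertypes(a, threshold = 100)
cluster_supertypes <- function(alleles, threshold = 100) {
  alleles <- as.data.frame(alleles)
  if (nrow(alleles) == 0L) abort("empty allele set", class = "mhc_domain_error")
  if (threshold <= 0) abort("threshold must be > 0", class = "mhc_domain_error")
  if (is.null(alleles$count)) alleles$count <- 1L

  n <- nrow(alleles)
  if (n == 1L) {
    cl <- 1L
  } else if (n <= 4000L) {
    hc <- hclust(dist(alleles[, c("x", "y")]), method = "single")
    cl <- cutree(hc, h = threshold)
  } else {
    ## very many distinct coordinates: pre-coarsen to a lattice of pitch
    ## threshold/5 (displacing each point by < threshold/7), link the occupied
    ## lattice sites, and propagate labels back; keeps memory quadratic in the
    ## number of occupied sites rather than of alleles
    pitch <- threshold / 5
    bx <- round(alleles$x / pitch)
    by <- round(alleles$y / pitch)
    key <- paste(bx, by)
    sites <- !duplicated(key)
    hc <- hclust(dist(cbind(bx[sites] * pitch, by[sites] * pitch)), method = "single")
    site_cl <- cutree(hc, h = threshold)
    cl <- site_cl[match(key, key[sites])]
  }
  ## deterministic relabelling by lexicographic minimum member
  ord <- order(alleles$x, alleles$y)
  first_seen <- cl[ord][!duplicated(cl[ord])]
  lab <- match(cl, first_seen)
  out <- tibble(
    x = alleles$x, y = alleles$y, count = alleles$count,
    supertype = paste0("ST", lab)
  )
  cent <- out %>%
    group_by(.data$supertype) %>%
    summarise(
      cx = sum(.data$x * .data$count) / sum(.data$count),
      cy = sum(.data$y * .data$count) / sum(.data$count),
      size = sum(.data$count),
      .groups = "drop"
    ) %>%
    arrange(as.integer(sub("^ST", "", .data$supertype)))
  attr(out, "centroids") <- cent
  out
}

#' Effective number of alleles (inverse Simpson index)
#'
#' `1 / sum(p_i^2)` over allele frequencies. Equals the number of distinct
#' alleles iff frequencies are uniform, and 1 for a monomorphic sample.
#'
#' @param x Either a vector of allele identifiers (one entry per allele copy),
#'   a vector of counts, or a vector of frequencies summing to 1. Counts and
#'   frequencies are distinguished by whether the values sum to 1.
#' @return A scalar `>= 1`.
#' @export
#' @examples
#' effective_n_alleles(c("a", "a", "b", "b")) # 2
#' effective_n_alleles(c(0.5, 0.25, 0.25)) # 2.667
effective_n_alleles <- function(x) {
  if (length(x) == 0L) abort("empty sample", class = "mhc_domain_error")
  if (is.numeric(x)) {
    if (any(x < 0)) abort("negative counts", class = "mhc_domain_error")
    p <- x / sum(x)
  } else {
    p <- as.vector(table(x)) / length(x)
  }
  1 / sum(p^2)
}

#' Track supertype lineages through a recorded trajectory
#'
#' Matches supertype clusters between consecutive recorded generations by
#' greedy nearest-centroid pairing (ascending centroid distance, ties broken
#' in favour of the larger cluster) within `match_radius`. A matched cluster
#' yields a `persist` event (displacement 0) or `move` event; an old cluster
#' left unmatched yields `loss`; a second new cluster whose nearest old
#' centroid was already claimed yields `branch`; a new cluster with no old
#' centroid in range yields `gain`.
#'
#' @param centroids Either a `coevo_sim` object (see [run_scenario()]) or a
#'   tibble `generation, supertype, cx, cy, size` of per-generation cluster
#'   centroids.
#' @param match_radius Maximum centroid displacement (grid units) for a match.
#' @return A tibble `generation, kind, from, to, displacement` where
#'   `generation` is the later snapshot of each transition.
#' @export
track_supertypes <- function(centroids, match_radius = 150) {
  if (inherits(centroids, "coevo_sim")) centroids <- centroids$centroids
  centroids <- as_tibble(centroids)
  gens <- sort(unique(centroids$generation))
  if (length(gens) < 2L) {
    abort("need at least two recorded generations", class = "mhc_domain_error")
  }
  events <- vector("list", length(gens) - 1L)
  for (t in seq_len(length(gens) - 1L)) {
    old <- centroids[centroids$generation == gens[t], ]
    new <- centroids[centroids$generation == gens[t + 1L], ]
    dmat <- outer(old$cx, new$cx, "-")^2 + outer(old$cy, new$cy, "-")^2
    dmat <- sqrt(dmat)
    pairs <- expand.grid(i = seq_len(nrow(old)), j = seq_len(nrow(new)))
    pairs$d <- dmat[cbind(pairs$i, pairs$j)]
    pairs <- pairs[pairs$d <= match_radius, , drop = FALSE]
    pairs <- pairs[order(pairs$d, -new$size[pairs$j]), , drop = FALSE]

    old_taken <- rep(FALSE, nrow(old))
    new_taken <- rep(FALSE, nrow(new))
    parent_of <- rep(NA_integer_, nrow(new))
    ev <- list()
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      if (new_taken[j]) next
      if (!old_taken[i]) {
        old_taken[i] <- TRUE
        new_taken[j] <- TRUE
        parent_of[j] <- i
        ev[[length(ev) + 1L]] <- tibble(
          generation = gens[t + 1L],
          kind = if (pairs$d[r] == 0) "persist" else "move",
          from = old$supertype[i], to = new$supertype[j],
          displacement = pairs$d[r]
        )
      } else {
        ## nearest available old centroid already claimed -> daughter cluster
        new_taken[j] <- TRUE
        parent_of[j] <- i
        ev[[length(ev) + 1L]] <- tibble(
          generation = gens[t + 1L], kind = "branch",
          from = old$supertype[i], to = new$supertype[j],
          displacement = pairs$d[r]
        )
      }
    }
    if (any(!old_taken)) {
      ev[[length(ev) + 1L]] <- tibble(
        generation = gens[t + 1L], kind = "loss",
        from = old$supertype[!old_taken], to = NA_character_,
        displacement = NA_real_
      )
    }
    if (any(!new_taken)) {
      ev[[length(ev) + 1L]] <- tibble(
        generation = gens[t + 1L], kind = "gain",
        from = NA_character_, to = new$supertype[!new_taken],
        displacement = NA_real_
      )
    }
    events[[t]] <- bind_rows(ev)
  }
  bind_rows(events)
}
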