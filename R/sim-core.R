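#' Initialise a simulation state
#'
#' Draws host alleles and parasite genotypes uniformly at random on the grid.
#' The state is a plain list: `hosts` is an integer matrix with one row per
#' diploid host and columns `a1x, a1y, a2x, a2y`; `parasites` is a list of
#' one integer `n x 2` matrix per parasite species.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_state` list with elements `hosts`, `parasites`, `generation`
#'   and `log`.
#' @export
init_state <- function(config) {
  validate_sim_config(config)
  g <- config$grid_size
  n <- config$host_pop_size
  hosts <- matrix(
    sample.int(g, 4L * n, replace = TRUE) - 1L,
    nrow = n, ncol = 4L,
    dimnames = list(NULL, c("a1x", "a1y", "a2x", "a2y"))
  )
  parasites <- lapply(seq_len(config$n_parasite_species), function(i) {
    matrix(sample.int(g, 2L * config$parasite_pop_size, replace = TRUE) - 1L,
      ncol = 2L, dimnames = list(NULL, c("x", "y"))
    )
  })
  structure(
    list(hosts = hosts, parasites = parasites, generation = 0L,
         log = character()),
    class = "sim_state"
  )
}

#' Probability that an allele recognises a parasite
#'
#' Gaussian recognition kernel on Euclidean distance in paratope space:
#' `exp(-d^2 / (2 s^2))`. Maximal (1) at distance zero and strictly
#' decreasing in distance.
#'
#' @param allele,parasite Length-2 integer vectors `(x, y)`, or two-column
#'   matrices of coordinates (recycled row-wise against each other).
#' @param recognition_scale Kernel width `s` in grid units.
#' @return Recognition probabilities in `[0, 1]`.
#' @export
#' @examples
#' recognition_prob(c(0, 0), c(80, 0), recognition_scale = 80) # exp(-1/2)
recognition_prob <- function(allele, parasite, recognition_scale) {
  a <- matrix(as.numeric(allele), ncol = 2L)
  p <- matrix(as.numeric(parasite), ncol = 2L)
  d2 <- (a[, 1L] - p[, 1L])^2 + (a[, 2L] - p[, 2L])^2
  exp(-d2 / (2 * recognition_scale^2))
}

## Reflect integer coordinates into [0, g-1]; steps are small relative to the
## grid so a bounded loop suffices.
reflect_coord <- function(x, g) {
  hi <- g - 1L
  for (i in 1:50) {
    out <- x < 0L | x > hi
    if (!any(out)) break
    x <- ifelse(x < 0L, -x, x)
    x <- ifelse(x > hi, 2L * hi - x, x)
  }
  pmin(pmax(x, 0L), hi)
}

## Vectorised mutation of an n x 2 integer coordinate matrix: each row is hit
## with probability `rate`; hit rows take an isotropic Gaussian step (sd =
## step_scale per axis) rounded to the integer grid and reflected.
mutate_points <- function(m, rate, step_scale, grid_size) {
  n <- nrow(m)
  if (n == 0L || rate <= 0 || step_scale <= 0) return(m)
  hit <- runif(n) < rate
  k <- sum(hit)
  if (k == 0L) return(m)
  m[hit, 1L] <- reflect_coord(m[hit, 1L] + as.integer(round(rnorm(k, 0, step_scale))), grid_size)
  m[hit, 2L] <- reflect_coord(m[hit, 2L] + as.integer(round(rnorm(k, 0, step_scale))), grid_size)
  m
}

#' Mutate a single paratope coordinate
#'
#' With probability `rate` the coordinate takes an isotropic Gaussian step
#' (standard deviation `step_scale` per axis), rounded to the integer grid and
#' reflected at the boundaries; otherwise it is returned unchanged.
#'
#' @param coord Length-2 integer vector `(x, y)`.
#' @param rate Mutation probability.
#' @param step_scale Step standard deviation in grid units.
#' @param grid_size Grid side length.
#' @return A length-2 integer vector on the grid.
#' @export
mutate_coordinate <- function(coord, rate, step_scale, grid_size = 1000) {
  m <- matrix(as.integer(coord), ncol = 2L)
  as.integer(mutate_points(m, rate, step_scale, as.integer(grid_size)))
}

#' Replace part of a parasite pool with random genotypes
#'
#' Implements per-generation seeding: `floor(fraction * n)` pool members,
#' chosen uniformly without replacement, are replaced by genotypes drawn
#' uniformly at random on the grid. Pool size is conserved.
#'
#' @param pool Integer `n x 2` matrix of parasite genotypes.
#' @param fraction Fraction of the pool to replace, in `[0, 1]`.
#' @param grid_size Grid side length.
#' @return The seeded pool (same dimensions).
#' @export
seed_random_parasites <- function(pool, fraction, grid_size = 1000) {
  if (fraction < 0 || fraction > 1) {
    abort("fraction must lie in [0, 1]", class = "mhc_domain_error")
  }
  n <- nrow(pool)
  k <- floor(fraction * n)
  if (k == 0L) return(pool)
  idx <- sample.int(n, k)
  pool[idx, ] <- sample.int(as.integer(grid_size), 2L * k, replace = TRUE) - 1L
  pool
}

#' Fitness of one host against a parasite exposure
#'
#' A host's fitness is the expected fraction of exposed parasites recognised,
#' scoring each parasite by the better of the host's two alleles ("best-allele"
#' rule) and averaging over the exposure. Values lie in `[0, 1]`.
#'
#' @param host Length-4 integer vector `(a1x, a1y, a2x, a2y)`.
#' @param parasite_exposure Integer `n x 2` matrix of parasite genotypes (the
#'   exposure sample); must be nonempty.
#' @param config A [sim_config()] (only `recognition_scale` is used).
#' @return Scalar fitness in `[0, 1]`.
#' @export
host_fitness <- function(host, parasite_exposure, config) {
  p <- matrix(as.numeric(parasite_exposure), ncol = 2L)
  if (nrow(p) == 0L) abort("empty parasite exposure", class = "mhc_domain_error")
  s <- config$recognition_scale
  r1 <- recognition_prob(matrix(rep(host[1:2], nrow(p)), ncol = 2, byrow = TRUE), p, s)
  r2 <- recognition_prob(matrix(rep(host[3:4], nrow(p)), ncol = 2, byrow = TRUE), p, s)
  mean(pmax(r1, r2))
}

#' Fitness of one parasite genotype against a host sample
#'
#' Mirror of [host_fitness()]: a parasite's fitness is the expected
#' probability of escaping recognition, averaged over the host sample, where
#' each host recognises with its better allele. Under
#' `parasite_selection = FALSE` this quantity is ignored by the recruitment
#' step and parasites are resampled uniformly.
#'
#' @param genotype Length-2 integer vector `(x, y)`.
#' @param host_sample Integer `n x 4` matrix of hosts; must be nonempty.
#' @param config A [sim_config()].
#' @return Scalar fitness in `[0, 1]`.
#' @export
parasite_fitness <- function(genotype, host_sample, config) {
  h <- matrix(as.numeric(host_sample), ncol = 4L)
  if (nrow(h) == 0L) abort("empty host sample", class = "mhc_domain_error")
  s <- config$recognition_scale
  g <- matrix(rep(as.numeric(genotype), nrow(h)), ncol = 2, byrow = TRUE)
  r1 <- recognition_prob(h[, 1:2, drop = FALSE], g, s)
  r2 <- recognition_prob(h[, 3:4, drop = FALSE], g, s)
  mean(1 - pmax(r1, r2))
}

## Joint, deduplicated fitness evaluation for a whole state. Returns
## host fitness (length N) and one fitness vector per parasite species.
## Works on unique allele coordinates / unique host genotypes / unique
## parasite genotypes so cost scales with distinctness, not population size.
compute_fitness <- function(state, config) {
  hosts <- state$hosts
  n <- nrow(hosts)
  g <- as.numeric(config$grid_size)
  s <- config$recognition_scale

  akey <- c(hosts[, 1L] * g + hosts[, 2L], hosts[, 3L] * g + hosts[, 4L])
  ua <- unique(akey)
  ai <- match(akey, ua)
  i1 <- ai[seq_len(n)]
  i2 <- ai[n + seq_len(n)]
  ax <- ua %/% g
  ay <- ua %% g

  gkey <- pmin(i1, i2) * (length(ua) + 1) + pmax(i1, i2)
  ug <- unique(gkey)
  gi <- match(gkey, ug)
  g1 <- (ug %/% (length(ua) + 1))
  g2 <- (ug %% (length(ua) + 1))
  cnt_g <- tabulate(gi, nbins = length(ug))

  host_fit <- numeric(n)
  par_fit <- vector("list", length(state$parasites))
  ## parasite columns are processed in blocks so the kernel temporaries stay
  ## bounded (~tens of MB) even when every coordinate is distinct
  block <- max(64L, as.integer(2e6 / max(length(ua), 1L)))
  for (sp in seq_along(state$parasites)) {
    p <- state$parasites[[sp]]
    pkey <- p[, 1L] * g + p[, 2L]
    up <- unique(pkey)
    pidx <- match(pkey, up)
    w <- tabulate(pidx, nbins = length(up))
    px <- up %/% g
    py <- up %% g
    E <- config$exposure_sample
    full_pool <- is.infinite(E) || E >= nrow(p)

    host_acc <- numeric(length(ug))
    par_rec <- numeric(length(up))
    enc <- NULL
    if (!full_pool) {
      E <- as.integer(E)
      enc <- matrix(pidx[sample.int(nrow(p), n * E, replace = TRUE)], nrow = n)
      enc_fit <- matrix(0, n, E)
    }
    for (start in seq(1L, length(up), by = block)) {
      blk <- start:min(start + block - 1L, length(up))
      K <- exp(-(outer(ax, px[blk], "-")^2 + outer(ay, py[blk], "-")^2) / (2 * s^2))
      M <- pmax(K[g1, , drop = FALSE], K[g2, , drop = FALSE])
      if (full_pool) {
        host_acc <- host_acc + as.vector(M %*% w[blk])
      } else {
        hit <- which(matrix(enc %in% blk, nrow = n), arr.ind = TRUE)
        if (nrow(hit)) {
          cols <- match(enc[hit], blk)
          enc_fit[hit] <- M[cbind(gi[hit[, 1L]], cols)]
        }
      }
      par_rec[blk] <- as.vector(crossprod(M, cnt_g)) / n
    }
    if (full_pool) {
      host_fit <- host_fit + host_acc[gi] / nrow(p)
    } else {
      host_fit <- host_fit + rowMeans(enc_fit)
    }
    par_fit[[sp]] <- (1 - par_rec)[pidx]
  }
  list(host = host_fit / length(state$parasites), parasite = par_fit)
}

#' Advance the simulation by one generation
#'
#' One full generation: parasite point mutation, optional random seeding of the
#' parasite pools, joint fitness evaluation, fitness-proportional sexual host
#' reproduction (random mating of selected parents, one allele inherited from
#' each parent, alleles mutating at transmission), then parasite recruitment
#' (fitness-proportional, or uniform when `parasite_selection = FALSE`).
#' Population sizes are exactly conserved. A generation in which every fitness
#' is zero falls back to uniform recruitment and appends a note to
#' `state$log`.
#'
#' @param state A `sim_state` from [init_state()] or a previous step.
#' @param config A [sim_config()].
#' @return The next `sim_state`.
#' @export
step_generation <- function(state, config) {
  n <- config$host_pop_size
  gsz <- config$grid_size

  state$parasites <- lapply(state$parasites, mutate_points,
    rate = config$parasite_mut_rate,
    step_scale = config$mutation_step_scale, grid_size = gsz
  )
  if (config$seeding_fraction > 0) {
    state$parasites <- lapply(state$parasites, seed_random_parasites,
      fraction = config$seeding_fraction, grid_size = gsz
    )
  }

  fit <- compute_fitness(state, config)

  w <- if (config$host_selection) fit$host^config$selection_strength else rep(1, n)
  if (sum(w) <= 0) {
    w <- rep(1, n)
    state$log <- c(state$log, sprintf(
      "generation %d: all host fitnesses zero; uniform recruitment",
      state$generation + 1L
    ))
  }
  mothers <- sample.int(n, n, replace = TRUE, prob = w)
  fathers <- sample.int(n, n, replace = TRUE, prob = w)
  from_m <- runif(n) < 0.5
  from_f <- runif(n) < 0.5
  a1 <- cbind(
    ifelse(from_m, state$hosts[mothers, 1L], state$hosts[mothers, 3L]),
    ifelse(from_m, state$hosts[mothers, 2L], state$hosts[mothers, 4L])
  )
  a2 <- cbind(
    ifelse(from_f, state$hosts[fathers, 1L], state$hosts[fathers, 3L]),
    ifelse(from_f, state$hosts[fathers, 2L], state$hosts[fathers, 4L])
  )
  a1 <- mutate_points(a1, config$host_mut_rate, config$mutation_step_scale, gsz)
  a2 <- mutate_points(a2, config$host_mut_rate, config$mutation_step_scale, gsz)
  new_hosts <- cbind(a1, a2)
  colnames(new_hosts) <- colnames(state$hosts)

  for (sp in seq_along(state$parasites)) {
    m <- nrow(state$parasites[[sp]])
    if (config$parasite_selection) {
      pw <- fit$parasite[[sp]]^config$parasite_selection_strength
      if (sum(pw) <= 0) {
        pw <- rep(1, m)
        state$log <- c(state$log, sprintf(
          "generation %d: all parasite fitnesses zero (species %d); uniform recruitment",
          state$generation + 1L, sp
        ))
      }
      idx <- sample.int(m, m, replace = TRUE, prob = pw)
    } else {
      idx <- sample.int(m, m, replace = TRUE)
    }
    state$parasites[[sp]] <- state$parasites[[sp]][idx, , drop = FALSE]
  }

  state$hosts <- new_hosts
  state$generation <- state$generation + 1L
  state
}
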