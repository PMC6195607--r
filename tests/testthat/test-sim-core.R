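test_that("recognition kernel is maximal at zero distance and monotone decreasing", {
  expect_equal(recognition_prob(c(5, 5), c(5, 5), 80), 1)
  d <- seq(0, 500, by = 25)
  p <- recognition_prob(cbind(rep(0, length(d)), 0), cbind(d, 0), 80)
  expect_true(all(diff(p) < 0))
  ## Gaussian kernel at d = s
  expect_equal(recognition_prob(c(0, 0), c(80, 0), 80), exp(-0.5))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("coordinate mutation respects rate, step scale and grid bounds", {
  expect_identical(mutate_coordinate(c(10L, 20L), rate = 0, step_scale = 10), c(10L, 20L))
  set.seed(1)
  expect_identical(mutate_coordinate(c(10L, 20L), rate = 1, step_scale = 0), c(10L, 20L))
  ## displacements match the declared step law: round(Normal(0, sd))
  set.seed(42)
  n <- 5000
  pts <- matrix(rep(c(500L, 500L), each = n), ncol = 2)
  out <- mhcsupertypes:::mutate_points(pts, rate = 1, step_scale = 10, grid_size = 1000)
  disp <- out[, 1] - 500
  ref <- round(rnorm(n, 0, 10))
  ks <- suppressWarnings(stats::ks.test(disp, ref))
  expect_gt(ks$p.value, 0.01)
  ## reflection keeps arbitrary mutation sequences on the grid
  x <- matrix(c(0L, 999L), ncol = 2)
  for (i in 1:200) x <- mhcsupertypes:::mutate_points(x, 1, 50, 1000)
  expect_true(all(x >= 0 & x <= 999))
})

test_that("parasite seeding replaces the exact floor(fraction * n) genotypes", {
  pool <- matrix(0L, nrow = 50, ncol = 2)
  expect_identical(seed_random_parasites(pool, 0, 1000), pool)
  set.seed(7)
  out <- seed_random_parasites(pool, 0.1, 1000)
  expect_identical(dim(out), dim(pool))
  changed <- rowSums(out != pool) > 0
  expect_lte(sum(changed), 5)
  set.seed(8)
  all_new <- seed_random_parasites(pool, 1, 1000)
  expect_true(all(all_new >= 0 & all_new <= 999))
  expect_error(seed_random_parasites(pool, 1.5), class = "mhc_domain_error")
})

test_that("initial state is uniform on the grid, sized as configured, seed-reproducible", {
  cfg <- sim_config(host_pop_size = 10, parasite_pop_size = 15, grid_size = 1000,
                    n_parasite_species = 10)
  set.seed(3)
  st <- init_state(cfg)
  expect_identical(dim(st$hosts), c(10L, 4L))
  expect_length(st$parasites, 10L)
  expect_true(all(vapply(st$parasites, nrow, integer(1)) == 15L))
  expect_true(all(st$hosts >= 0 & st$hosts < 1000))
  set.seed(3)
  st2 <- init_state(cfg)
  expect_identical(st, st2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(host_pop_size = 1), class = "mhc_config_error")
  expect_error(sim_config(host_mut_rate = 1.2), class = "mhc_config_error")
  expect_error(sim_config(seeding_fraction = -0.1), class = "mhc_config_error")
  expect_error(sim_config(recognition_scale = 0), class = "mhc_config_error")
  expect_error(scenario_config("nope"), class = "mhc_config_error")
})

test_that("expected neutral heterozygosity follows 4Nu/(1+4Nu)", {
  expect_equal(expected_heterozygosity(1e4, 0), 0)
  expect_equal(expected_heterozygosity(1e4, 1e-3), 40 / 41)
  expect_error(expected_heterozygosity(-1, 0.1), class = "mhc_domain_error")
  expect_error(expected_heterozygosity(10, -0.1), class = "mhc_domain_error")
})

test_that("host fitness follows the best-allele rule", {
  cfg <- tiny_config(recognition_scale = 50)
  ## recognizing every exposed parasite with probability ~1 -> maximal fitness
  near <- matrix(c(100L, 100L, 100L, 100L), ncol = 2, byrow = TRUE)
  expect_equal(host_fitness(c(100L, 100L, 900L, 900L), near, cfg), 1)
  ## degenerate diploid: two identical alleles equal the single-allele value
  expo <- matrix(c(120L, 130L, 400L, 700L), ncol = 2, byrow = TRUE)
  f_hom <- host_fitness(c(100L, 100L, 100L, 100L), expo, cfg)
  r <- recognition_prob(matrix(rep(c(100, 100), 2), ncol = 2, byrow = TRUE), expo, 50)
  expect_equal(f_hom, mean(r))
  ## heterozygote covering two parasite clusters beats either homozygote
  cl1 <- cbind(sample(90:110, 10, TRUE), sample(90:110, 10, TRUE))
  cl2 <- cbind(sample(790:810, 10, TRUE), sample(790:810, 10, TRUE))
  expo2 <- rbind(cl1, cl2)
  f_het <- host_fitness(c(100L, 100L, 800L, 800L), expo2, cfg)
  f_h1 <- host_fitness(c(100L, 100L, 100L, 100L), expo2, cfg)
  f_h2 <- host_fitness(c(800L, 800L, 800L, 800L), expo2, cfg)
  expect_gte(f_het, f_h1)
  expect_gte(f_het, f_h2)
  expect_error(host_fitness(c(1L, 1L, 2L, 2L), matrix(integer(0), ncol = 2), cfg),
    class = "mhc_domain_error"
  )
})

test_that("parasite fitness mirrors host recognition", {
  cfg <- tiny_config(recognition_scale = 50)
  hosts <- matrix(rep(c(100L, 100L, 100L, 100L), 5), ncol = 4, byrow = TRUE)
  ## parasite sitting on every host allele -> minimal fitness
  expect_equal(parasite_fitness(c(100L, 100L), hosts, cfg), 0)
  ## two genotypes equidistant from all hosts -> equal fitness
  f1 <- parasite_fitness(c(100L, 200L), hosts, cfg)
  f2 <- parasite_fitness(c(200L, 100L), hosts, cfg)
  expect_equal(f1, f2)
  expect_error(parasite_fitness(c(1L, 1L), matrix(integer(0), ncol = 4), cfg),
    class = "mhc_domain_error"
  )
})

test_that("a generation conserves population sizes and is closed without mutation", {
  cfg <- tiny_config(
    host_mut_rate = 0, parasite_mut_rate = 0, seeding_fraction = 0,
    host_selection = FALSE, parasite_selection = FALSE
  )
  set.seed(11)
  st <- init_state(cfg)
  key0 <- unique(c(
    paste(st$hosts[, 1], st$hosts[, 2]),
    paste(st$hosts[, 3], st$hosts[, 4])
  ))
  for (i in 1:10) st <- step_generation(st, cfg)
  expect_identical(nrow(st$hosts), cfg$host_pop_size)
  expect_identical(nrow(st$parasites[[1]]), cfg$parasite_pop_size)
  key1 <- unique(c(
    paste(st$hosts[, 1], st$hosts[, 2]),
    paste(st$hosts[, 3], st$hosts[, 4])
  ))
  expect_true(all(key1 %in% key0))
})

test_that("fixed seed reproduces trajectories bit-identically", {
  ov <- list(host_pop_size = 60, parasite_pop_size = 30, generations = 15, record_every = 5)
  s1 <- run_scenario("original", overrides = ov, seed = 99)
  s2 <- run_scenario("original", overrides = ov, seed = 99)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$summary, s2$summary)
})

test_that("neutral drift fixes a 50/50 biallelic population symmetrically", {
  cfg <- sim_config(
    host_pop_size = 16, parasite_pop_size = 2, generations = 1,
    host_mut_rate = 0, parasite_mut_rate = 0, seeding_fraction = 0,
    host_selection = FALSE, parasite_selection = FALSE, record_every = 1
  )
  set.seed(123)
  n_rep <- 400
  wins <- 0L
  for (r in seq_len(n_rep)) {
    st <- init_state(cfg)
    half <- cfg$host_pop_size / 2
    a <- c(100L, 100L); b <- c(800L, 800L)
    st$hosts <- rbind(
      matrix(rep(c(a, a), half), ncol = 4, byrow = TRUE),
      matrix(rep(c(b, b), half), ncol = 4, byrow = TRUE)
    )
    for (i in 1:400) {
      st <- step_generation(st, cfg)
      xs <- c(st$hosts[, 1], st$hosts[, 3])
      if (all(xs == 100L)) { wins <- wins + 1L; break }
      if (all(xs == 800L)) break
    }
  }
  ## Wright-Fisher symmetry: fixation probability = initial frequency = 0.5
  ci <- stats::binom.test(wins, n_rep, p = 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("neutral equilibrium heterozygosity matches the closed form at small N*mu", {
  ## theta = 4*50*0.01 = 2 -> H = 2/3 under the infinite-alleles approximation
  ov <- list(
    host_pop_size = 50, parasite_pop_size = 2, generations = 3000,
    host_mut_rate = 0.01, parasite_mut_rate = 0, seeding_fraction = 0,
    host_selection = FALSE, parasite_selection = FALSE,
    record_every = 25, sample_size = 50
  )
  sim <- run_scenario("custom", overrides = ov, seed = 5)
  late <- sim$summary[sim$summary$generation >= 1000, ]
  h_obs <- mean(1 - 1 / late$effective_alleles)
  h_exp <- expected_heterozygosity(50, 0.01)
  expect_lt(abs(h_obs - h_exp), 0.12)
})
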