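test_that("unit frequencies pool allele occurrences and collapse to supertypes", {
  g <- build_genotypes(list(
    A = list(i1 = c("a", "b")),
    B = list(i1 = c("a", "b", "c"), i2 = c("a"), i3 = c("c"))
  ))
  expect_equal(unit_frequencies(g, "A"), c(a = 0.5, b = 0.5))
  ## hand count for B: a:2, b:1, c:2 over 5 occurrences
  fb <- unit_frequencies(g, "B")
  expect_equal(fb[["a"]], 0.4)
  expect_equal(fb[["b"]], 0.2)
  expect_equal(fb[["c"]], 0.4)
  m <- build_map(c("a", "b", "c"), c("ST1", "ST1", "ST2"))
  fs <- unit_frequencies(g, "B", "supertype", m)
  expect_equal(sum(fs), 1)
  expect_equal(fs[["ST1"]], 0.6)
  expect_error(unit_frequencies(g, "Z"), class = "mhc_domain_error")
})

test_that("pairwise Jost's D matches direct textbook evaluation", {
  for (case in c("identical", "fixed_diff", "mixed_7030")) {
    fx <- dest_fixture(case)
    fa <- unit_frequencies(fx$genotypes, "A")
    fb <- unit_frequencies(fx$genotypes, "B")
    na <- sum(fx$genotypes$population == "A")
    nb <- sum(fx$genotypes$population == "B")
    expect_equal(
      jost_dest(fa, fb, na, nb, estimator = "naive"),
      fx$expected$naive,
      tolerance = 1e-12, label = paste("naive", case)
    )
    expect_equal(
      jost_dest(fa, fb, na, nb, estimator = "nei_chesser"),
      fx$expected$nei_chesser,
      tolerance = 1e-12, label = paste("corrected", case)
    )
    ## independent oracle for the naive variant
    expect_equal(jost_dest(fa, fb, na, nb, estimator = "naive"),
      oracle_jost_naive(fa, fb),
      tolerance = 1e-12
    )
  }
  ## symmetry in the demes
  fx <- dest_fixture("mixed_7030")
  fa <- unit_frequencies(fx$genotypes, "A")
  fb <- unit_frequencies(fx$genotypes, "B")
  expect_equal(jost_dest(fa, fb, 10, 10), jost_dest(fb, fa, 10, 10))
})

test_that("mean pairwise D per population matches a brute-force pair loop", {
  g <- build_genotypes(list(
    A = list(i1 = c("a", "b"), i2 = c("a")),
    B = list(i1 = c("b", "c"), i2 = c("c")),
    C = list(i1 = c("a", "c"), i2 = c("b")),
    D = list(i1 = c("d"), i2 = c("d", "a"))
  ))
  got <- mean_pairwise_dest(g, "allele")
  pops <- unique(g$population)
  for (p in pops) {
    vals <- sapply(setdiff(pops, p), function(q) {
      jost_dest(
        unit_frequencies(g, p), unit_frequencies(g, q),
        sum(g$population == p), sum(g$population == q)
      )
    })
    expect_equal(got$mean_dest[got$population == p], mean(vals))
  }
  ## two populations: each equals the single pairwise value
  g2 <- g[g$population %in% c("A", "B"), ]
  got2 <- mean_pairwise_dest(g2, "allele")
  expect_equal(got2$mean_dest[1], got2$mean_dest[2])
  ## identical populations -> all zeros (naive estimator is exactly zero)
  gid <- build_genotypes(list(
    A = list(i1 = c("a", "b"), i2 = c("a", "b")),
    B = list(i1 = c("a", "b"), i2 = c("a", "b"))
  ))
  expect_equal(mean_pairwise_dest(gid, "allele", estimator = "naive")$mean_dest, c(0, 0))
  expect_error(mean_pairwise_dest(g[g$population == "A", ], "allele"),
    class = "mhc_domain_error"
  )
})

test_that("label randomization preserves supertype sizes and matches enumeration", {
  ## 2 populations, 4 alleles, supertypes of sizes 2+2
  g <- build_genotypes(list(
    A = list(i1 = c("a", "b"), i2 = c("a", "c")),
    B = list(i1 = c("c", "d"), i2 = c("b", "d"))
  ))
  m <- build_map(c("a", "b", "c", "d"), c("S1", "S1", "S2", "S2"))
  ## exhaustive enumeration over the C(4,2) = 6 distinct label assignments
  combos <- utils::combn(c("a", "b", "c", "d"), 2, simplify = FALSE)
  enum <- sapply(combos, function(s1) {
    mm <- tibble::tibble(
      allele = c("a", "b", "c", "d"),
      supertype = ifelse(c("a", "b", "c", "d") %in% s1, "S1", "S2")
    )
    mean(mean_pairwise_dest(g, "supertype", mm)$mean_dest)
  })
  set.seed(31)
  exp_out <- randomized_expectation(g, m, n_reps = 600)
  reps <- attr(exp_out, "reps")
  ## every permutation outcome is one of the 6 enumerable values
  vals <- unique(round(rowMeans(reps), 10))
  expect_true(all(vals %in% round(enum, 10)))
  expect_equal(mean(rowMeans(reps)), mean(enum), tolerance = 0.02)

  ## one-allele-per-supertype map: permutation is a relabelling, expectation
  ## equals the observed supertype value exactly, SD 0
  m1 <- build_map(c("a", "b", "c", "d"))
  obs <- mean_pairwise_dest(g, "supertype", m1)
  exp1 <- randomized_expectation(g, m1, n_reps = 20)
  expect_equal(exp1$expected_mean, obs$mean_dest)
  expect_equal(exp1$expected_sd, c(0, 0))
})

test_that("supertype jackknife removes alleles, individuals and monomorphic populations", {
  g <- build_genotypes(list(
    A = list(i1 = c("a", "x"), i2 = c("x"), i3 = c("b")),
    B = list(i1 = c("c", "x"), i2 = c("d")),
    C = list(i1 = c("x"), i2 = c("x")) # pure focal population
  ))
  m <- build_map(c("a", "b", "c", "d", "x"), c("S1", "S1", "S2", "S2", "SX"))
  jk <- jackknife_supertype(g, m, "SX")
  expect_false("x" %in% jk$genotypes$allele)
  ## i2 in A was homozygous for SX -> removed
  expect_false("i2" %in% jk$genotypes$individual[jk$genotypes$population == "A"])
  ## population C becomes empty -> dropped and logged
  expect_true("C" %in% jk$dropped)
  expect_false("C" %in% jk$genotypes$population)
  ## A keeps S1-only alleles but has two supertypes? a->S1, b->S1: monomorphic -> dropped
  expect_true("A" %in% jk$dropped)
  ## jackknifing a supertype absent from a population leaves it unchanged
  g2 <- build_genotypes(list(
    A = list(i1 = c("a", "c")),
    B = list(i1 = c("b", "d"))
  ))
  jk2 <- jackknife_supertype(g2, m, "SX")
  expect_equal(nrow(jk2$genotypes), nrow(g2))
  expect_length(jk2$dropped, 0)
  expect_error(jackknife_supertype(g, m, "nope"), class = "mhc_domain_error")
})

test_that("jackknife summaries use tie-corrected Spearman ranks", {
  mk_res <- function(obs, exp = rep(0.1, length(obs))) {
    tibble::tibble(
      population = paste0("p", seq_along(obs)),
      observed = obs, expected_mean = exp, expected_sd = 0.01
    )
  }
  full <- mk_res(c(0.5, 0.3, 0.4, 0.2))
  ## identical -> rho 1, mean_diff = mean(obs - exp)
  s <- jackknife_summary(full, full)
  expect_equal(s$spearman_rho, 1)
  expect_equal(s$mean_diff, mean(c(0.5, 0.3, 0.4, 0.2) - 0.1))
  ## shuffled -> matches the rank-correlation oracle
  jack <- mk_res(c(0.2, 0.5, 0.3, 0.4))
  s2 <- jackknife_summary(full, jack)
  oracle <- cor(rank(full$observed), rank(jack$observed))
  expect_equal(s2$spearman_rho, oracle)
  ## ties: average ranks
  jt <- mk_res(c(0.3, 0.3, 0.4, 0.2))
  s3 <- jackknife_summary(full, jt)
  expect_equal(s3$spearman_rho, cor(rank(full$observed), rank(jt$observed)))
  expect_error(jackknife_summary(full, mk_res(1)[0, ]), class = "mhc_domain_error")
})

test_that("deletion controls respect their matching invariants", {
  set.seed(33)
  tab <- sim_genotype_tables(
    n_populations = 3, individuals_per_population = 8,
    n_supertypes = 3, alleles_per_supertype = 6
  )
  g <- tab$genotypes
  m <- tab$st_map
  focal <- "ST_out"
  focal_alleles <- m$allele[m$supertype == focal]
  n_focal_rows <- sum(g$allele %in% focal_alleles)

  ## scheme 1: exactly |alleles(focal)| unique sequences removed per repeat
  r1 <- random_deletion_control(g, m, focal, "sequence_matched", n_reps = 3, n_null = 20)
  for (del in attr(r1, "deletions")) {
    expect_equal(length(unique(g$allele[del])), length(focal_alleles))
    ## all occurrences of each victim are removed
    expect_equal(sum(g$allele %in% unique(g$allele[del])), length(del))
  }
  ## scheme 2: occurrence count matched
  r2 <- random_deletion_control(g, m, focal, "frequency_matched", n_reps = 3, n_null = 20)
  for (del in attr(r2, "deletions")) expect_length(del, n_focal_rows)
  ## scheme 3: per-population counts matched
  r3 <- random_deletion_control(g, m, focal, "population_stratified", n_reps = 3, n_null = 20)
  for (del in attr(r3, "deletions")) {
    for (p in unique(g$population)) {
      expect_equal(
        sum(g$population[del] == p),
        sum(g$population == p & g$allele %in% focal_alleles)
      )
    }
  }
  ## a zero-occurrence focal supertype is a no-op under every scheme
  m0 <- dplyr::bind_rows(m, tibble::tibble(allele = "ghost", supertype = "ST_ghost"))
  r0 <- random_deletion_control(g, m0, "ST_ghost", "frequency_matched", n_reps = 2, n_null = 20)
  for (del in attr(r0, "deletions")) expect_length(del, 0)
})

test_that("supertype homozygosity is the fraction of single-supertype individuals", {
  g <- build_genotypes(list(
    A = list(
      i1 = c("a", "b"), # S1+S1 -> homozygote
      i2 = c("a", "c"), # S1+S2
      i3 = c("c"), # S2 -> homozygote
      i4 = c("b", "d"), # S1+S2
      i5 = c("a", "b", "d") # S1+S1+S2
    )
  ))
  m <- build_map(c("a", "b", "c", "d"), c("S1", "S1", "S2", "S2"))
  expect_equal(st_homozygosity_fraction(g, m), 2 / 5)
  ## all multi-supertype -> 0; all single-allele -> 1
  g0 <- build_genotypes(list(A = list(i1 = c("a", "c"), i2 = c("b", "d"))))
  expect_equal(st_homozygosity_fraction(g0, m), 0)
  g1 <- build_genotypes(list(A = list(i1 = "a", i2 = "c")))
  expect_equal(st_homozygosity_fraction(g1, m), 1)
  ## exclusion removes the supertype and re-bases the denominator
  gx <- build_genotypes(list(A = list(
    i1 = c("a", "c"), # without S1 -> pure S2 homozygote
    i2 = c("a", "b"), # without S1 -> empty, dropped
    i3 = c("c", "d") # stays S2+S2 homozygote
  )))
  expect_equal(st_homozygosity_fraction(gx, m), 2 / 3)
  expect_equal(st_homozygosity_fraction(gx, m, exclude_st = "S1"), 1)
  g_only_s1 <- build_genotypes(list(A = list(i1 = "a", i2 = "b")))
  expect_error(st_homozygosity_fraction(g_only_s1, m, exclude_st = "S1"),
    class = "mhc_domain_error"
  )
})
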