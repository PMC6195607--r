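#' Simulate a supertype-labelled alignment with known ground truth
#'
#' Generates an aligned set of allele sequences under a Jukes-Cantor
#' substitution process on a known tree, together with an allele-to-supertype
#' map, in one of two scenarios:
#' \describe{
#'   \item{monophyletic_supertypes}{Supertypes coincide with the clades of a
#'     deep backbone tree: a coalescent backbone over supertypes (branch
#'     depth `between_div`) carries one shallow within-supertype coalescent
#'     (depth `within_div`) per supertype. Every supertype is monophyletic on
#'     the true tree by construction.}
#'   \item{convergent_supertypes}{Sequences evolve on a single coalescent
#'     tree with no supertype structure; supertype labels are then assigned
#'     from the states of a few fast-evolving "motif" columns, so alleles
#'     sharing a label typically do not share ancestry.}
#' }
#'
#' @param scenario Generating scenario.
#' @param n_supertypes Number of supertype labels.
#' @param alleles_per_supertype Alleles per supertype (monophyletic scenario);
#'   the convergent scenario generates `n_supertypes * alleles_per_supertype`
#'   alleles in total and labels them by motif.
#' @param seq_length Alignment length in nucleotide columns.
#' @param within_div Expected depth (substitutions/site) of within-supertype
#'   divergence.
#' @param between_div Expected depth of the supertype backbone.
#' @param n_motif_cols Number of label-determining columns (convergent
#'   scenario).
#' @return List with `alignment` (a `DNAbin` matrix), `st_map` (tibble
#'   `allele, supertype`) and `tree` (the true generating `phylo`).
#' @export
#' @examples
#' set.seed(1)
#' g <- sim_supertype_alignment("monophyletic_supertypes", n_supertypes = 4)
#' table(g$st_map$supertype)
sim_supertype_alignment <- function(scenario = c(
                                      "monophyletic_supertypes",
                                      "convergent_supertypes"
                                    ),
                                    n_supertypes = 8,
                                    alleles_per_supertype = 8,
                                    seq_length = 209,
                                    within_div = 0.02,
                                    between_div = 0.4,
                                    n_motif_cols = 2) {
  scenario <- match.arg(scenario)
  if (n_supertypes < 2 || alleles_per_supertype < 1) {
    abort("need >= 2 supertypes and >= 1 allele per supertype", class = "mhc_domain_error")
  }
  if (within_div < 0 || between_div < 0) {
    abort("divergence parameters must be >= 0", class = "mhc_domain_error")
  }

  if (scenario == "monophyletic_supertypes") {
    backbone <- ape::rcoal(n_supertypes, tip.label = paste0("ST", seq_len(n_supertypes)))
    backbone$edge.length <- backbone$edge.length *
      (between_div / max(ape::node.depth.edgelength(backbone)))
    tree <- backbone
    for (i in seq_len(n_supertypes)) {
      st <- paste0("ST", i)
      if (alleles_per_supertype == 1L) {
        tree$tip.label[tree$tip.label == st] <- paste0(st, "_a1")
        next
      }
      sub <- ape::rcoal(alleles_per_supertype,
        tip.label = paste0(st, "_a", seq_len(alleles_per_supertype))
      )
      depth <- max(ape::node.depth.edgelength(sub))
      if (depth > 0) sub$edge.length <- sub$edge.length * (within_div / depth)
      tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == st))
    }
    aln <- simulate_jc_sequences(tree, seq_length)
    st_map <- tibble(
      allele = tree$tip.label,
      supertype = sub("_a\\d+$", "", tree$tip.label)
    )
    return(list(alignment = aln, st_map = st_map, tree = tree))
  }

  ## convergent scenario
  n_total <- n_supertypes * alleles_per_supertype
  tree <- ape::rcoal(n_total, tip.label = paste0("al", seq_len(n_total)))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (between_div / depth)
  core <- simulate_jc_sequences(tree, seq_length - n_motif_cols)
  ## fast-evolving motif columns: high rate makes their states homoplastic
  motif <- simulate_jc_sequences(tree, n_motif_cols, rate = 25)
  aln <- cbind(core, motif[rownames(core), , drop = FALSE])
  states <- apply(as.character(motif[rownames(core), , drop = FALSE]), 1, paste, collapse = "")
  combo <- match(states, unique(states))
  st_map <- tibble(
    allele = rownames(core),
    supertype = paste0("ST", ((combo - 1L) %% n_supertypes) + 1L)
  )
  list(alignment = aln, st_map = st_map, tree = tree)
}

## JC sequence simulation on a tree (equal base frequencies, equal rates).
simulate_jc_sequences <- function(tree, l, rate = 1) {
  if (l == 0L) {
    m <- matrix(character(0), nrow = length(tree$tip.label), ncol = 0)
    rownames(m) <- tree$tip.label
    return(ape::as.DNAbin(m))
  }
  sq <- phangorn::simSeq(tree, l = l, type = "DNA", rate = rate)
  ape::as.DNAbin(sq)
}

#' Simulate multi-population genotype tables with known structure
#'
#' Emulates a multi-population MHC genotyping dataset: individuals carry
#' between `alleles_min` and `alleles_max` distinct alleles (ambiguous
#' multi-locus genotypes). Structured supertypes have population-private
#' allele pools, giving strong between-population differentiation; an
#' optional outlier supertype shares one allele pool across all populations
#' at high frequency, contributing almost no differentiation -- the
#' signature of a drift-governed, locus-like supertype.
#'
#' @param n_populations Number of populations.
#' @param individuals_per_population Individuals sampled per population.
#' @param n_supertypes Number of structured supertypes.
#' @param alleles_per_supertype Unique alleles per structured supertype
#'   (split across populations).
#' @param alleles_min,alleles_max Range of distinct alleles per individual.
#' @param outlier Logical; add the unstructured, high-frequency supertype.
#' @param outlier_weight Probability that any single allele draw comes from
#'   the outlier supertype.
#' @param outlier_n_alleles Unique alleles in the outlier supertype's shared
#'   pool.
#' @return List with `genotypes` (tibble `population, individual, allele`),
#'   `st_map` (tibble `allele, supertype`; the outlier is labelled `"ST_out"`)
#'   and `truth` (list of generator parameters).
#' @export
#' @examples
#' set.seed(1)
#' tab <- sim_genotype_tables(n_populations = 3, individuals_per_population = 10)
#' head(tab$genotypes)
sim_genotype_tables <- function(n_populations = 6,
                                individuals_per_population = 20,
                                n_supertypes = 6,
                                alleles_per_supertype = 12,
                                alleles_min = 2, alleles_max = 9,
                                outlier = TRUE,
                                outlier_weight = 0.35,
                                outlier_n_alleles = 10) {
  if (n_populations < 1) abort("need >= 1 population", class = "mhc_domain_error")
  if (alleles_min < 1 || alleles_max > 9 || alleles_min > alleles_max) {
    abort("alleles per individual must lie in 1..9", class = "mhc_domain_error")
  }
  pops <- paste0("pop", seq_len(n_populations))
  ## population-private pools per structured supertype
  pools <- list()
  st_map <- list()
  for (s in seq_len(n_supertypes)) {
    st <- paste0("ST", s)
    alleles <- paste0(st, "_al", seq_len(alleles_per_supertype))
    st_map[[st]] <- tibble(allele = alleles, supertype = st)
    owner <- rep(pops, length.out = alleles_per_supertype)
    pools[[st]] <- split(alleles, owner)
  }
  out_alleles <- character()
  if (outlier) {
    out_alleles <- paste0("ST_out_al", seq_len(outlier_n_alleles))
    st_map[["ST_out"]] <- tibble(allele = out_alleles, supertype = "ST_out")
  }
  st_labels <- paste0("ST", seq_len(n_supertypes))

  rows <- list()
  for (p in pops) {
    for (ind in seq_len(individuals_per_population)) {
      k <- sample(alleles_min:alleles_max, 1L)
      picks <- character(0)
      for (draw in seq_len(k)) {
        if (outlier && runif(1) < outlier_weight) {
          picks <- c(picks, sample(out_alleles, 1L))
        } else {
          st <- sample(st_labels, 1L)
          pool <- pools[[st]][[p]]
          if (is.null(pool) || !length(pool)) pool <- unlist(pools[[st]])
          picks <- c(picks, sample(pool, 1L))
        }
      }
      picks <- unique(picks)
      rows[[length(rows) + 1L]] <- tibble(
        population = p, individual = paste0(p, "_ind", ind), allele = picks
      )
    }
  }
  list(
    genotypes = bind_rows(rows),
    st_map = bind_rows(st_map),
    truth = list(
      n_populations = n_populations, n_supertypes = n_supertypes,
      outlier = if (outlier) "ST_out" else NULL,
      outlier_weight = outlier_weight
    )
  )
}

#' Tiny genotype fixtures with hand-checkable Jost's D
#'
#' Small two-population tables whose pairwise D can be verified by direct
#' formula evaluation:
#' \describe{
#'   \item{identical}{Both populations have allele frequencies (0.5, 0.5);
#'     D = 0.}
#'   \item{fixed_diff}{Each population fixed for a private allele; D = 1.}
#'   \item{mixed_7030}{Frequencies (0.7, 0.3) versus (0.3, 0.7) with 10
#'     occurrences per population.}
#' }
#'
#' @param case_id Fixture name.
#' @return List with `genotypes`, `st_map` (one supertype per allele) and
#'   `expected` (named list of hand-computed values, by estimator).
#' @export
dest_fixture <- function(case_id = c("identical", "fixed_diff", "mixed_7030")) {
  case_id <- match.arg(case_id)
  mk <- function(pop, alleles) {
    tibble(
      population = pop,
      individual = paste0(pop, "_i", seq_along(alleles)),
      allele = alleles
    )
  }
  g <- switch(case_id,
    identical = bind_rows(
      mk("A", c("a", "a", "b", "b")),
      mk("B", c("a", "a", "b", "b"))
    ),
    fixed_diff = bind_rows(
      mk("A", rep("a", 4)),
      mk("B", rep("b", 4))
    ),
    mixed_7030 = bind_rows(
      mk("A", c(rep("a", 7), rep("b", 3))),
      mk("B", c(rep("a", 3), rep("b", 7)))
    )
  )
  expected <- switch(case_id,
    ## identical demes: naive D is exactly 0; the small-sample corrected
    ## estimator undershoots at n = 4 per deme:
    ## Hs' = 4/3 * 0.5 = 2/3, Ht' = 0.5 + Hs'/8 = 7/12,
    ## D = 2 (7/12 - 2/3)/(1 - 2/3) = -1/2
    identical = list(naive = 0, nei_chesser = -0.5),
    fixed_diff = list(naive = 1, nei_chesser = 1),
    ## hand computation: Hs = 0.42, Ht = 0.5 (naive);
    ## nh = 10: Hs' = 10/9*0.42, Ht' = 0.5 + Hs'/20
    mixed_7030 = list(
      naive = 2 * (0.5 - 0.42) / (1 - 0.42),
      nei_chesser = {
        hs <- 10 / 9 * 0.42
        ht <- 0.5 + hs / 20
        2 * (ht - hs) / (1 - hs)
      }
    )
  )
  st_map <- tibble(
    allele = sort(unique(g$allele)),
    supertype = paste0("ST", seq_along(sort(unique(g$allele))))
  )
  list(genotypes = g, st_map = st_map, expected = expected)
}
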