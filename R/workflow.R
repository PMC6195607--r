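#' Read a genotype table from CSV
#'
#' Expects columns `population`, `individual`, `allele` (one row per allele
#' an individual carries); duplicate allele records per individual are
#' collapsed (genotypes are sets of alleles).
#'
#' @param path CSV path.
#' @return Tibble `population, individual, allele`.
#' @export
read_genotypes <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "individual", "allele")
  if (!all(need %in% names(g))) {
    abort(
      paste0(path, " must have columns: ", paste(need, collapse = ", ")),
      class = "mhc_io_error"
    )
  }
  distinct(as_tibble(g[need]))
}

#' Read an allele-to-supertype map from CSV
#'
#' @param path CSV path with columns `allele`, `supertype`.
#' @return Tibble `allele, supertype`.
#' @export
read_supertype_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("allele", "supertype")
  if (!all(need %in% names(m))) {
    abort(
      paste0(path, " must have columns: ", paste(need, collapse = ", ")),
      class = "mhc_io_error"
    )
  }
  distinct(as_tibble(m[need]))
}

#' Write a tree with branch lengths and bootstrap supports to Newick
#'
#' @param tree A `phylo` tree, optionally with `node.label` supports.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Reproduce the full synthetic workflow
#'
#' End-to-end orchestration on package-generated data: runs the simulator
#' scenario presets (at reduced scale controlled by `host_pop_size` and
#' `generations`), the population-genetic structure/jackknife pipeline on a
#' synthetic multi-population genotype table with an unstructured outlier
#' supertype, and the phylogenetic monophyly report on synthetic
#' monophyletic and convergent alignments. All outputs are CSV/Newick files
#' under `out_dir`, beside a JSON run manifest recording the seed and
#' configuration, so a run is reproducible from its manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every stage.
#' @param scenarios Simulator presets to run.
#' @param host_pop_size,generations Scale of the simulator runs.
#' @param n_reps Permutations for the structure analysis.
#' @param bootstrap Bootstrap replicates for the phylogeny stage.
#' @return Invisibly, a list with the in-memory results.
#' @export
reproduce_all <- function(out_dir, seed = 1,
                          scenarios = c("original", "fig2b", "fig2c", "fig2d"),
                          host_pop_size = 1000, generations = 300,
                          n_reps = 200, bootstrap = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sims <- list()
  for (sc in scenarios) {
    sims[[sc]] <- run_scenario(sc,
      overrides = list(host_pop_size = host_pop_size, generations = generations),
      seed = seed
    )
    write_trajectory(sims[[sc]], file.path(out_dir, paste0("sim_", sc, ".csv")))
  }

  set.seed(seed)
  tab <- sim_genotype_tables()
  utils::write.csv(tab$genotypes, file.path(out_dir, "genotypes.csv"), row.names = FALSE)
  utils::write.csv(tab$st_map, file.path(out_dir, "supertype_map.csv"), row.names = FALSE)
  jack <- jackknife_supertypes(tab$genotypes, tab$st_map, n_reps = n_reps)
  utils::write.csv(jack$result, file.path(out_dir, "jackknife.csv"), row.names = FALSE)

  set.seed(seed + 1L)
  phy <- list()
  for (sc in c("monophyletic_supertypes", "convergent_supertypes")) {
    g <- sim_supertype_alignment(sc)
    tree <- bootstrap_support(g$alignment, n_reps = bootstrap)
    rep_tbl <- supertype_monophyly_report(tree, g$st_map)
    ape::write.FASTA(g$alignment, file.path(out_dir, paste0("aln_", sc, ".fasta")))
    write_tree(tree, file.path(out_dir, paste0("tree_", sc, ".nwk")))
    utils::write.csv(rep_tbl, file.path(out_dir, paste0("monophyly_", sc, ".csv")),
      row.names = FALSE
    )
    phy[[sc]] <- rep_tbl
  }

  manifest <- list(
    package = "mhcsupertypes",
    version = as.character(utils::packageVersion("mhcsupertypes")),
    seed = seed,
    scenarios = scenarios,
    host_pop_size = host_pop_size,
    generations = generations,
    n_reps = n_reps,
    bootstrap = bootstrap
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(sims = sims, jackknife = jack, phylo = phy, manifest = manifest))
}
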