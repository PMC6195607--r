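## Small builders shared across test files.

## genotype table from a list: pop -> individual -> character vector of alleles
build_genotypes <- function(spec) {
  rows <- list()
  for (p in names(spec)) {
    for (ind in names(spec[[p]])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        population = p, individual = ind, allele = spec[[p]][[ind]]
      )
    }
  }
  dplyr::bind_rows(rows)
}

## trivial map: each allele its own supertype unless given
build_map <- function(alleles, supertypes = NULL) {
  tibble::tibble(
    allele = alleles,
    supertype = supertypes %||% paste0("ST", seq_along(alleles))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## tiny fast simulator config
tiny_config <- function(...) {
  sim_config(
    host_pop_size = 40, parasite_pop_size = 20, generations = 5,
    record_every = 1, sample_size = 20, ...
  )
}

## independent monophyly oracle: for every edge, flood-fill the tree with that
## edge removed and compare the tip set on each side with the query set
oracle_monophyletic <- function(tree, tips) {
  n <- length(tree$tip.label)
  if (length(tips) == 1L) return(TRUE)
  target <- sort(match(tips, tree$tip.label))
  edges <- tree$edge
  for (e in seq_len(nrow(edges))) {
    keep <- edges[-e, , drop = FALSE]
    adj <- split(c(keep[, 2], keep[, 1]), c(keep[, 1], keep[, 2]))
    seen <- edges[e, 2]
    frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(unlist(adj[as.character(frontier)]), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    side <- sort(intersect(seen, seq_len(n)))
    other <- sort(setdiff(seq_len(n), side))
    if (identical(side, target) || identical(other, target)) return(TRUE)
  }
  FALSE
}

## independent textbook evaluation of two-deme Jost's D (naive estimator)
oracle_jost_naive <- function(pa, pb) {
  ids <- union(names(pa), names(pb))
  a <- sapply(ids, function(i) if (i %in% names(pa)) pa[[i]] else 0)
  b <- sapply(ids, function(i) if (i %in% names(pb)) pb[[i]] else 0)
  hs <- ((1 - sum(a^2)) + (1 - sum(b^2))) / 2
  ht <- 1 - sum(((a + b) / 2)^2)
  (ht - hs) / (1 - hs) * 2
}
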