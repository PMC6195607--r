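#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) log(1 - (4/3) p)` where `p` is the proportion of differing
#' sites over pairwise-complete columns (columns where either sequence has a
#' gap, `N` or other ambiguity are excluded for that pair). Saturated pairs
#' (`p >= 0.75`) are an error by default, or capped at `cap` when
#' `on_saturation = "cap"`.
#'
#' @param seq_i,seq_j Nucleotide strings (or character vectors of single
#'   bases) of equal aligned length.
#' @param on_saturation `"error"` or `"cap"`.
#' @param cap Distance assigned to saturated pairs when capping.
#' @return Nonnegative distance in substitutions per site.
#' @export
#' @examples
#' jc_distance("ACGTACGTAC", "ACGTACGTAT") # p = 0.1
jc_distance <- function(seq_i, seq_j, on_saturation = c("error", "cap"), cap = 5) {
  on_saturation <- match.arg(on_saturation)
  a <- toupper(if (length(seq_i) == 1L) strsplit(seq_i, "")[[1]] else seq_i)
  b <- toupper(if (length(seq_j) == 1L) strsplit(seq_j, "")[[1]] else seq_j)
  if (length(a) != length(b)) abort("sequences must be aligned to equal length", class = "mhc_domain_error")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) abort("no pairwise-complete columns", class = "mhc_domain_error")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.75) {
    if (on_saturation == "error") {
      abort(sprintf("saturated pair (p = %.3f >= 0.75)", p), class = "mhc_saturation_error")
    }
    return(cap)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix for an alignment
#'
#' Pairwise-deletion Jukes-Cantor distances over all sequence pairs. Saturated
#' pairs (undefined distance) raise an error by default or are capped.
#'
#' @param aln An alignment: `ape::DNAbin` (list or matrix), a named character
#'   vector of sequences, or a character matrix.
#' @inheritParams jc_distance
#' @return A `dist` object over the sequence names.
#' @export
jc_dist_matrix <- function(aln, on_saturation = c("error", "cap"), cap = 5) {
  on_saturation <- match.arg(on_saturation)
  aln <- as_dnabin(aln)
  d <- ape::dist.dna(aln, model = "JC69", pairwise.deletion = TRUE)
  if (any(!is.finite(d))) {
    if (on_saturation == "error") {
      abort("saturated sequence pair(s); JC distance undefined",
        class = "mhc_saturation_error"
      )
    }
    d[!is.finite(d)] <- cap
  }
  d
}

## Coerce the accepted alignment representations to DNAbin.
as_dnabin <- function(aln) {
  if (inherits(aln, "DNAbin")) return(aln)
  if (inherits(aln, "phyDat")) return(ape::as.DNAbin(aln))
  if (is.character(aln)) {
    if (is.matrix(aln)) return(ape::as.DNAbin(aln))
    if (is.null(names(aln))) abort("sequences must be named", class = "mhc_domain_error")
    m <- t(vapply(aln, function(s) strsplit(tolower(s), "")[[1]],
      character(nchar(aln[[1]]))
    ))
    return(ape::as.DNAbin(m))
  }
  abort("unsupported alignment representation", class = "mhc_domain_error")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (as implemented in \pkg{ape}), with negative
#' branch lengths clamped to zero. On an additive distance matrix the true
#' topology is recovered exactly.
#'
#' @param d A `dist` object or symmetric matrix with at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.dist(d)
  if (attr(d, "Size") < 3L) abort("need at least 3 taxa", class = "mhc_domain_error")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and maps bipartition frequencies (percent of replicates)
#' onto the internal edges of the tree built from the full alignment.
#' Saturated pairs arising in replicates are capped rather than erroring.
#'
#' @param aln Alignment (see [jc_dist_matrix()]).
#' @param n_reps Number of bootstrap replicates.
#' @param tree Optional precomputed NJ tree of the full alignment.
#' @return The full-alignment NJ tree with `node.label` holding support
#'   percentages (`NA` on the root node).
#' @export
bootstrap_support <- function(aln, n_reps = 500, tree = NULL) {
  if (n_reps < 1) abort("n_reps must be >= 1", class = "mhc_domain_error")
  aln <- as_dnabin(aln)
  m <- as.matrix(aln)
  build <- function(x) nj_tree(jc_dist_matrix(x, on_saturation = "cap"))
  if (is.null(tree)) tree <- build(m)
  if (max(jc_dist_matrix(m, on_saturation = "cap")) == 0) {
    warn("all sequences identical: bootstrap supports are not meaningful")
  }
  counts <- ape::boot.phylo(tree, m, build,
    B = n_reps, rooted = FALSE, quiet = TRUE
  )
  tree$node.label <- 100 * counts / n_reps
  tree$node.label[1] <- NA # root of the unrooted representation
  tree
}

#' Is a tip set monophyletic on an unrooted tree?
#'
#' `TRUE` iff some edge of the unrooted tree bipartitions the leaves into
#' exactly `tips` versus the rest. Singleton tip sets are trivially
#' monophyletic.
#'
#' @param tree A `phylo` tree.
#' @param tips Character vector of tip labels (a proper nonempty subset of
#'   the leaves).
#' @return Logical scalar.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' tips_monophyletic(tr, c("A", "B")) # TRUE
#' tips_monophyletic(tr, c("A", "C")) # FALSE
tips_monophyletic <- function(tree, tips) {
  labs <- tree$tip.label
  if (!all(tips %in% labs)) {
    abort(
      paste0("unknown tips: ", paste(setdiff(tips, labs), collapse = ", ")),
      class = "mhc_domain_error"
    )
  }
  if (length(tips) < 1L || length(tips) >= length(labs)) {
    abort("tips must be a proper nonempty subset of the leaves", class = "mhc_domain_error")
  }
  if (length(tips) == 1L) return(TRUE)
  target <- sort(match(tips, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  parts <- ape::prop.part(tree)
  for (cl in parts) {
    scl <- sort(cl)
    if (identical(scl, target) || identical(scl, comp)) return(TRUE)
  }
  FALSE
}

#' Monophyly report for every supertype on a tree
#'
#' Applies [tips_monophyletic()] to the allele set of each supertype and,
#' when the tree carries bootstrap supports in `node.label`, attaches the
#' support of the edge separating a monophyletic supertype from the rest.
#' Single-allele supertypes are flagged as trivially monophyletic.
#'
#' @param tree A `phylo` tree whose tips are allele identifiers; optionally
#'   with `node.label` support percentages from [bootstrap_support()].
#' @param st_map Data frame `allele, supertype` covering every leaf.
#' @return Tibble `supertype, n_alleles, monophyletic, trivial, support`.
#' @export
supertype_monophyly_report <- function(tree, st_map) {
  labs <- tree$tip.label
  unmapped <- setdiff(labs, as.character(st_map$allele))
  if (length(unmapped)) {
    abort(
      paste0("leaves missing from supertype map: ", paste(unmapped, collapse = ", ")),
      class = "mhc_domain_error"
    )
  }
  m <- setNames(as.character(st_map$supertype), as.character(st_map$allele))
  sts <- sort(unique(unname(m[labs])))
  parts <- ape::prop.part(tree)
  part_keys <- vapply(parts, function(cl) paste(sort(cl), collapse = ","), character(1))
  supports <- tree$node.label

  rows <- map(sts, function(st) {
    tips <- labs[m[labs] == st]
    n <- length(tips)
    if (n == length(labs)) {
      return(tibble(
        supertype = st, n_alleles = n, monophyletic = TRUE,
        trivial = TRUE, support = NA_real_
      ))
    }
    if (n == 1L) {
      return(tibble(
        supertype = st, n_alleles = 1L, monophyletic = TRUE,
        trivial = TRUE, support = NA_real_
      ))
    }
    target <- paste(sort(match(tips, labs)), collapse = ",")
    comp <- paste(sort(setdiff(seq_along(labs), match(tips, labs))), collapse = ",")
    hit <- which(part_keys == target | part_keys == comp)
    mono <- length(hit) > 0L
    supp <- NA_real_
    if (mono && !is.null(supports) && length(supports) >= max(hit)) {
      supp <- suppressWarnings(as.numeric(supports[hit[1]]))
    }
    tibble(
      supertype = st, n_alleles = n, monophyletic = mono,
      trivial = FALSE, support = supp
    )
  })
  bind_rows(rows)
}
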