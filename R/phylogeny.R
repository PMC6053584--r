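#' Pairwise nucleotide difference matrix
#'
#' Absolute counts of differing sites per sequence pair, with pairwise
#' deletion of gaps and ambiguity characters. With `per_site = TRUE` each
#' count is divided by the pair's number of jointly unambiguous sites.
#'
#' @param aln Alignment (`DNAbin` or character matrix).
#' @param exclude Optional positions to skip.
#' @param per_site Return per-site distances instead of counts.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
difference_matrix <- function(aln, exclude = NULL, per_site = FALSE) {
  m <- aln_chars(aln)
  if (nrow(m) < 2) stop("need at least 2 sequences", call. = FALSE)
  keep <- keep_positions(ncol(m), exclude)
  cnt <- pair_difference_counts(m[, keep, drop = FALSE])
  out <- if (per_site) {
    r <- cnt$diff / cnt$valid
    r[cnt$valid == 0] <- 0
    r
  } else {
    cnt$diff
  }
  diag(out) <- 0
  out
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining of a distance matrix. Negative branch lengths
#' are clamped to zero with the deficit transferred to the adjacent edges of
#' the same node so path lengths are preserved.
#'
#' @param dist Symmetric distance matrix (or `dist`) over >= 3 items.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dist) {
  m <- as.matrix(dist)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 items", call. = FALSE)
  tree <- ape::nj(stats::as.dist(m))
  fix_negative_branches(tree)
}

# Clamp negative edges to zero; the absolute amount is added to the edges
# incident to the same child node so root-to-tip path lengths are conserved.
fix_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    amt <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    down <- which(tree$edge[, 1] == child)
    if (length(down) > 0) tree$edge.length[down] <- tree$edge.length[down] + amt
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal edge the percentage of
#' replicates containing the same bipartition. Supports are stored as
#' internal node labels.
#'
#' @param aln Alignment with >= 4 sequences.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param exclude Optional positions to skip.
#' @return The NJ [ape::phylo] tree with `node.label` holding percent
#'   support (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1L, exclude = NULL) {
  m <- aln_chars(aln)
  if (nrow(m) < 4) stop("bootstrap needs at least 4 sequences", call. = FALSE)
  keep <- keep_positions(ncol(m), exclude)
  m <- m[, keep, drop = FALSE]
  build <- function(x) nj_tree(pair_difference_counts(x)$diff)
  main <- build(m)
  set.seed(derive_seed(seed, 7L))
  counts <- ape::prop.clades(main, lapply(seq_len(n_reps), function(i) {
    build(m[, sample.int(ncol(m), replace = TRUE), drop = FALSE])
  }), rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  main$node.label <- as.character(support)
  main$node.label[1] <- "" # root of the unrooted representation
  attr(main, "n_bootstrap") <- n_reps
  main
}

#' Root a tree with an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge; ingroup
#' bipartitions are unchanged.
#'
#' @param tree An unrooted [ape::phylo].
#' @param outgroup Tip label of the outgroup.
#' @return A rooted [ape::phylo].
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' not among tips", call. = FALSE)
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root_node <- length(rooted$tip.label) + 1L
  og_tip <- which(rooted$tip.label == outgroup)
  e_og <- which(rooted$edge[, 1] == root_node & rooted$edge[, 2] == og_tip)
  e_other <- which(rooted$edge[, 1] == root_node & rooted$edge[, 2] != og_tip)
  if (length(e_og) == 1L && length(e_other) == 1L) {
    total <- rooted$edge.length[e_og] + rooted$edge.length[e_other]
    rooted$edge.length[e_og] <- total / 2
    rooted$edge.length[e_other] <- total / 2
  }
  rooted
}

# Mean path length from each node to its descendant tips.
mean_node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  n_tips_below <- numeric(nnode)
  sum_path <- numeric(nnode)
  n_tips_below[seq_len(ntip)] <- 1
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  lens <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    n_tips_below[par] <- n_tips_below[par] + n_tips_below[child]
    sum_path[par] <- sum_path[par] + sum_path[child] + n_tips_below[child] * lens[e]
  }
  sum_path / n_tips_below
}

#' Strict-clock node ages from an outgroup calibration
#'
#' Converts branch lengths to ages by assuming a constant rate: the rate is
#' the mean root-to-tip path length divided by `calibration_age`, and each
#' internal node's age is its mean path length to descendant tips divided by
#' that rate. The age of the most recent common ancestor of the non-outgroup
#' tips (the species coalescent) is reported separately.
#'
#' @param tree A rooted [ape::phylo] with branch lengths in
#'   substitutions/site (or any rate-proportional unit).
#' @param calibration_age Age of the root in years.
#' @param outgroup Optional outgroup tip label used to identify the ingroup.
#' @return An object of class `clock_tree`: `tree`, `ages` (tibble `node`,
#'   `age_years`), `rate` (branch-length units per year), `root_age`,
#'   `ingroup_tmrca`, `calibration_age`.
#' @export
clock_node_ages <- function(tree, calibration_age, outgroup = NULL) {
  stopifnot(calibration_age > 0)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  depths <- mean_node_depths(tree)
  root_node <- ntip + 1L
  if (depths[root_node] <= 0) stop("zero mean root depth: cannot calibrate", call. = FALSE)
  rate <- depths[root_node] / calibration_age
  ages <- depths / rate
  ingroup_tmrca <- NA_real_
  if (!is.null(outgroup)) {
    ingroup <- setdiff(tree$tip.label, outgroup)
    mrca <- ape::getMRCA(tree, ingroup)
    ingroup_tmrca <- ages[mrca]
  }
  out <- list(
    tree = tree,
    ages = tibble::tibble(node = (ntip + 1L):(ntip + tree$Nnode),
      age_years = ages[(ntip + 1L):(ntip + tree$Nnode)]),
    rate = rate,
    root_age = ages[root_node],
    ingroup_tmrca = ingroup_tmrca,
    calibration_age = calibration_age
  )
  class(out) <- "clock_tree"
  out
}

#' @export
print.clock_tree <- function(x, ...) {
  cat(sprintf(
    "Clock-dated tree: rate %.3g per year, root age %.4g years, ingroup TMRCA %.4g years\n",
    x$rate, x$root_age, x$ingroup_tmrca))
  invisible(x)
}
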