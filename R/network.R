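# Statistical-parsimony haplotype network with a probability-based
# connection limit.

# Probability-of-parsimony model: given two sequences differing at j of m
# sites, the per-site substitution intensity lambda is the Jukes-Cantor
# correction of p = j/m; sites evolve as Poisson(lambda) with equal exchange
# among the three alternatives. The connection is parsimonious when every
# differing site changed exactly once and no identical site hides an even
# number of changes:
#   P_pars = P(X=1 | differs)^j * P(X=0 | same)^(m-j).
# `parsimony_probability()` evaluates the conditional terms by a truncated
# recursion over the Poisson series; the test suite re-derives them from the
# closed forms.

#' Probability that a j-step connection is parsimonious
#'
#' @param j Number of observed differences (>= 0).
#' @param seq_length Sequence length m in bp.
#' @return Probability in `[0, 1]`.
#' @export
parsimony_probability <- function(j, seq_length) {
  stopifnot(seq_length >= 1, j >= 0)
  if (j == 0) return(1)
  p <- j / seq_length
  if (p >= 0.75) return(0)
  lambda <- -0.75 * log(1 - 4 * p / 3)
  # recursion over Poisson terms: w_k, (-1/3)^k
  w <- exp(-lambda)
  sgn <- 1
  sum_d <- 0 # sum_k w_k P(differ | k)
  sum_s <- 0 # sum_k w_k P(same | k)
  w1_d <- NA_real_
  w0_s <- NA_real_
  k <- 0
  repeat {
    pd <- 0.75 * (1 - sgn)
    ps <- 1 - pd
    sum_d <- sum_d + w * pd
    sum_s <- sum_s + w * ps
    if (k == 1) w1_d <- w * pd
    if (k == 0) w0_s <- w * ps
    if (k > 2 && w < 1e-18) break
    k <- k + 1
    w <- w * lambda / k
    sgn <- sgn * (-1 / 3)
  }
  r1 <- w1_d / sum_d
  s0 <- w0_s / sum_s
  exp(j * log(r1) + (seq_length - j) * log(s0))
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps j such that
#' [parsimony_probability()] at the given sequence length is at least
#' `confidence`. Pairs of haplotypes farther apart than the limit are not
#' connected in the network.
#'
#' @param seq_length Sequence length in bp.
#' @param confidence Required probability of parsimony (e.g. 0.90).
#' @return An object of class `connection_limit`: `max_steps`, `confidence`,
#'   `seq_length`.
#' @export
connection_limit <- function(seq_length, confidence = 0.90) {
  stopifnot(seq_length >= 1, confidence > 0, confidence < 1)
  j <- 0
  while (j + 1 < 0.75 * seq_length &&
    parsimony_probability(j + 1, seq_length) >= confidence) {
    j <- j + 1
  }
  structure(
    list(max_steps = j, confidence = confidence, seq_length = seq_length),
    class = "connection_limit"
  )
}

#' @export
print.connection_limit <- function(x, ...) {
  cat(sprintf("Connection limit: %d steps at %.0f%% confidence (%d bp)\n",
    x$max_steps, 100 * x$confidence, x$seq_length))
  invisible(x)
}

#' Build a statistical-parsimony haplotype network
#'
#' Joins haplotypes in order of increasing pairwise distance (ties broken by
#' total haplotype frequency, then lexicographic ids). Joins longer than the
#' connection limit are not made, leaving separate network components. Joins
#' spanning more than one step are filled with latent single-step
#' intermediate nodes (abstract step counters, not reconstructed sequences).
#' Alternative equal-length connections between the same two components are
#' retained as explicit reticulation loops by default; `resolve_loops = TRUE`
#' keeps only the first (by the deterministic ordering).
#'
#' @param haplotypes A `haplotype_table` from [collapse_haplotypes()].
#' @param limit A [connection_limit()], or `Inf` for no limit.
#' @param resolve_loops Break ties instead of retaining loops.
#' @return An object of class `haplotype_network`: `graph` (igraph; observed
#'   vertices carry `count`, latent vertices `latent = TRUE`), `joins`
#'   (tibble `from`, `to`, `distance`, `loop`), `components` (tibble
#'   `haplotype_id`, `component`), `limit`.
#' @export
build_network <- function(haplotypes, limit = NULL, resolve_loops = FALSE) {
  stopifnot(inherits(haplotypes, "haplotype_table"))
  max_steps <- if (is.null(limit)) {
    Inf
  } else if (inherits(limit, "connection_limit")) {
    limit$max_steps
  } else {
    limit
  }
  haps <- names(haplotypes$representatives)
  nh <- length(haps)
  freq <- tapply(haplotypes$counts$n, haplotypes$counts$haplotype_id, sum)[haps]
  seqs <- haplotypes$sequences
  rownames(seqs) <- haps
  joins <- tibble::tibble(from = character(), to = character(),
    distance = integer(), loop = logical())
  comp <- seq_len(nh)
  names(comp) <- haps
  if (nh > 1) {
    d <- pair_difference_counts(seqs)$diff
    pr <- which(upper.tri(d), arr.ind = TRUE)
    pairs <- tibble::tibble(
      a = haps[pr[, 1]], b = haps[pr[, 2]],
      d = as.integer(round(d[pr])),
      f = as.numeric(freq[haps[pr[, 1]]] + freq[haps[pr[, 2]]])
    )
    pairs <- pairs[order(pairs$d, -pairs$f, pairs$a, pairs$b), ]
    # plain integer union-find over hap indices
    parent <- seq_len(nh)
    find_root <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (dval in sort(unique(pairs$d))) {
      if (dval > max_steps) break
      block <- pairs[pairs$d == dval, ]
      snapshot <- vapply(seq_len(nh), find_root, integer(1))
      for (r in seq_len(nrow(block))) {
        ia <- match(block$a[r], haps)
        ib <- match(block$b[r], haps)
        live_diff <- find_root(ia) != find_root(ib)
        snap_diff <- snapshot[ia] != snapshot[ib]
        add <- if (resolve_loops) live_diff else snap_diff
        if (add) {
          joins <- dplyr::bind_rows(joins, tibble::tibble(
            from = block$a[r], to = block$b[r], distance = dval,
            loop = !live_diff
          ))
          if (live_diff) parent[find_root(ia)] <- find_root(ib)
        }
      }
    }
    comp <- vapply(seq_len(nh), find_root, integer(1))
    names(comp) <- haps
  }
  # build graph with latent intermediates
  edges <- character(0)
  latent_attrs <- character(0)
  latent_n <- 0L
  if (nrow(joins) > 0) {
    for (r in seq_len(nrow(joins))) {
      dv <- joins$distance[r]
      if (dv <= 1L) {
        edges <- c(edges, joins$from[r], joins$to[r])
      } else {
        chain <- c(joins$from[r],
          paste0("latent_", latent_n + seq_len(dv - 1L)),
          joins$to[r])
        latent_attrs <- c(latent_attrs, chain[2:(dv)])
        latent_n <- latent_n + dv - 1L
        for (s in seq_len(dv)) edges <- c(edges, chain[s], chain[s + 1])
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nh, name = haps, latent = FALSE,
    count = as.numeric(freq))
  if (latent_n > 0) {
    g <- igraph::add_vertices(g, latent_n, name = unique(latent_attrs),
      latent = TRUE, count = 0)
  }
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, match(edges, igraph::V(g)$name))
  }
  comp_ids <- match(comp, sort(unique(comp)))
  out <- list(
    graph = g,
    joins = joins,
    components = tibble::tibble(haplotype_id = haps, component = comp_ids),
    limit = max_steps,
    n_samples = haplotypes$n_samples
  )
  class(out) <- "haplotype_network"
  out
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Haplotype network:", sum(!igraph::V(x$graph)$latent), "observed +",
    sum(igraph::V(x$graph)$latent), "latent nodes,",
    igraph::ecount(x$graph), "single-step edges,",
    max(x$components$component), "component(s), limit =", x$limit, "steps\n")
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes the network as GraphML, an edge-list TSV, and/or Graphviz DOT.
#'
#' @param network A [build_network()] result.
#' @param graphml,edgelist,dot Optional output paths.
#' @return Invisibly, a named list of the written paths.
#' @export
write_network <- function(network, graphml = NULL, edgelist = NULL, dot = NULL) {
  stopifnot(inherits(network, "haplotype_network"))
  written <- list()
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
    written$graphml <- graphml
  }
  if (!is.null(edgelist)) {
    el <- igraph::as_edgelist(network$graph)
    utils::write.table(
      data.frame(from = el[, 1], to = el[, 2]),
      edgelist, sep = "\t", quote = FALSE, row.names = FALSE)
    written$edgelist <- edgelist
  }
  if (!is.null(dot)) {
    g2 <- network$graph # DOT has no boolean attribute type
    igraph::V(g2)$latent <- as.integer(igraph::V(g2)$latent)
    igraph::write_graph(g2, dot, format = "dot")
    written$dot <- dot
  }
  invisible(written)
}
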