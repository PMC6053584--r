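# Monte Carlo randomization test of phylogeographic structure: the parsimony
# length of a population-partition character on the observed tree, compared
# with its distribution over random permutations of tip states.

#' Parsimony length of a discrete tip character
#'
#' Minimum number of state changes of an unordered multistate character on a
#' fixed tree, computed by the Hartigan generalization of the Fitch downpass
#' (exact on multifurcating trees). Tips with `NA` state are pruned first.
#'
#' @param tree An [ape::phylo] (rooted or unrooted; polytomies allowed).
#' @param tip_states Named vector of states (names = tip labels), or
#'   unnamed vector in tip order.
#' @return Integer parsimony length.
#' @export
fitch_length <- function(tree, tip_states) {
  if (is.null(names(tip_states))) {
    if (length(tip_states) != length(tree$tip.label)) {
      stop("unnamed tip_states must match the number of tips", call. = FALSE)
    }
    names(tip_states) <- tree$tip.label
  }
  tip_states <- tip_states[tree$tip.label]
  keep <- names(tip_states)[!is.na(tip_states)]
  if (length(keep) == 0) stop("no tips with states", call. = FALSE)
  if (length(keep) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, keep)
    tip_states <- tip_states[tree$tip.label]
  }
  states <- sort(unique(as.character(tip_states)))
  S <- length(states)
  if (S == 1L || length(tree$tip.label) == 1L) return(0L)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- matrix(FALSE, nnode, S)
  sets[cbind(seq_len(ntip), match(as.character(tip_states), states))] <- TRUE
  post <- ape::reorder.phylo(tree, "postorder")$edge
  length_total <- 0L
  # Hartigan downpass: per internal node, count children whose set contains
  # each state; the node keeps the argmax states and adds
  # (#children - max count) changes.
  parents <- rev(unique(rev(post[, 1]))) # order of last occurrence: children final
  child_of <- split(post[, 2], post[, 1])
  for (p in parents) {
    kids <- child_of[[as.character(p)]]
    counts <- colSums(sets[kids, , drop = FALSE])
    K <- max(counts)
    sets[p, ] <- counts == K
    length_total <- length_total + length(kids) - K
  }
  as.integer(length_total)
}

#' Define a partition model for the Monte Carlo test
#'
#' @param ... Named or unnamed character vectors of population names, one per
#'   partition (up to four in the classic design; any number accepted).
#'   Populations not listed are excluded from the test.
#' @param id Optional model identifier.
#' @return An object of class `partition_model`: tibble `population`,
#'   `partition` plus the id.
#' @export
partition_model <- function(..., id = NULL) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1]])) {
    tbl <- tibble::as_tibble(parts[[1]])
    stopifnot(all(c("population", "partition") %in% names(tbl)))
  } else {
    tbl <- dplyr::bind_rows(lapply(seq_along(parts), function(i) {
      tibble::tibble(population = as.character(parts[[i]]), partition = i)
    }))
  }
  if (anyDuplicated(tbl$population)) {
    stop("partitions must be disjoint (duplicate population)", call. = FALSE)
  }
  structure(list(table = tbl, id = id), class = "partition_model")
}

#' Monte Carlo randomization test of phylogeographic structure
#'
#' Computes the parsimony length `L_obs` of the partition character implied
#' by a model on the observed tree, then the null distribution of lengths
#' over `n_rand` uniform permutations of tip states among the included tips
#' (partition counts fixed). `C%` is the percentage of null lengths less than
#' or equal to `L_obs` (the L-inclusive tail); small values indicate the
#' observed distribution of populations over the tree is more clustered than
#' random.
#'
#' @param tree An [ape::phylo] whose tips are sample ids.
#' @param assignment Sample-to-population assignment.
#' @param model A [partition_model()]. Tips in populations outside the model
#'   are pruned before both observed and null computations.
#' @param n_rand Number of random permutations (default 10000).
#' @param seed Integer seed.
#' @return An object of class `mc_test`: `L_obs`, `null_lengths`,
#'   `C_percent`, `p_value` (= C%/100), `stars`, `n_included`, `n_rand`,
#'   `seed`, `model_id`.
#' @export
mc_phylogeo_test <- function(tree, assignment, model, n_rand = 10000, seed = 1L) {
  stopifnot(inherits(model, "partition_model"))
  if (n_rand < 100) warning("n_rand < 100 gives a very coarse tail estimate")
  asg <- as_assignment(assignment)
  part_of_pop <- stats::setNames(model$table$partition, model$table$population)
  tip_pop <- stats::setNames(asg$population, asg$sample_id)[tree$tip.label]
  states <- part_of_pop[tip_pop]
  names(states) <- tree$tip.label
  included <- names(states)[!is.na(states)]
  if (length(included) < 2) stop("model includes fewer than 2 tips", call. = FALSE)
  tree2 <- if (length(included) < length(tree$tip.label)) {
    ape::keep.tip(tree, included)
  } else {
    tree
  }
  states <- states[tree2$tip.label]
  if (length(unique(states)) == 1L) {
    out <- list(L_obs = 0L, null_lengths = rep(0L, n_rand), C_percent = 100,
      p_value = 1, stars = "ns", n_included = length(included),
      n_rand = n_rand, seed = seed, model_id = model$id)
    class(out) <- "mc_test"
    return(out)
  }
  L_obs <- fitch_length(tree2, states)
  set.seed(derive_seed(seed, 8L))
  null_lengths <- vapply(seq_len(n_rand), function(i) {
    s <- states
    s[] <- sample(unname(states))
    fitch_length(tree2, s)
  }, integer(1))
  C <- 100 * sum(null_lengths <= L_obs) / n_rand
  p <- C / 100
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  out <- list(
    L_obs = L_obs, null_lengths = null_lengths, C_percent = C,
    p_value = p, stars = stars, n_included = length(included),
    n_rand = n_rand, seed = seed, model_id = model$id
  )
  class(out) <- "mc_test"
  out
}

#' @export
print.mc_test <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo phylogeography test%s: n = %d, L = %d, C%% = %.2f %s (%d randomizations)\n",
    if (is.null(x$model_id)) "" else paste0(" [", x$model_id, "]"),
    x$n_included, x$L_obs, x$C_percent, x$stars, x$n_rand))
  invisible(x)
}

#' Run several partition models and tabulate the results
#'
#' @param tree,assignment,n_rand,seed As in [mc_phylogeo_test()].
#' @param models A named list of [partition_model()] objects.
#' @return A tibble with one row per model: `model`, `n`, `L`, `C_percent`,
#'   `stars`.
#' @export
mc_phylogeo_table <- function(tree, assignment, models, n_rand = 10000, seed = 1L) {
  rows <- lapply(seq_along(models), function(i) {
    fit <- mc_phylogeo_test(tree, assignment, models[[i]],
      n_rand = n_rand, seed = derive_seed(seed, 300L + i))
    tibble::tibble(
      model = if (!is.null(names(models))) names(models)[i] else as.character(i),
      n = fit$n_included, L = fit$L_obs,
      C_percent = fit$C_percent, stars = fit$stars
    )
  })
  dplyr::bind_rows(rows)
}
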