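#' Simulation configuration
#'
#' Builds and validates the configuration for the structured-coalescent
#' generator. The generator emulates the data regime of whole-mitogenome
#' phylogeography surveys: on the order of 150 near-identical ~16.6-kb
#' sequences from 10-14 sampling locations, transition-biased mutation, and
#' optionally a sudden demographic expansion or a fixed between-group split.
#'
#' Demography is either an island model (`migration_rate` > 0, symmetric
#' migration among `n_populations` demes of haploid size `Ne`), a clean split
#' (`split_time` generations ago all demes merge into one ancestral deme of
#' size `Ne_ancestral`; `group_split` optionally makes two groups of demes
#' that merge within groups at `split_time` and between groups at
#' `group_split_time`), or a single population with a sudden expansion
#' (`expansion = sudden_expansion(tau, theta0, theta1)`): looking back, the
#' haploid size is `theta1 / (2 u)` until `tau / (2 u)` generations ago and
#' `theta0 / (2 u)` earlier, where `u = per_site_mu * seq_length` is the
#' per-genome per-generation mutation rate, so that the expected pairwise
#' mismatch mode sits at `tau` differences.
#'
#' @param n_populations Number of demes (>= 1).
#' @param samples_per_pop Samples per deme; recycled to `n_populations`.
#' @param seq_length Genome length in bp.
#' @param per_site_mu Mutation rate per site per generation.
#' @param Ne Haploid effective size of each deme.
#' @param migration_rate Per-lineage per-generation migration probability
#'   (island model). Ignored after `split_time`.
#' @param split_time Generations ago at which all demes (or demes within a
#'   group) merge; `Inf` for a pure island model.
#' @param Ne_ancestral Haploid size of the ancestral deme (defaults to `Ne`).
#' @param group_split Optional integer vector of group labels (one per deme);
#'   requires `group_split_time`.
#' @param group_split_time Generations ago at which the group-ancestral demes
#'   merge (> `split_time`).
#' @param expansion `NULL` or [sudden_expansion()].
#' @param ts_tv_ratio Transition:transversion ratio of the mutation process.
#' @param indel_rate Per-site per-generation single-base deletion rate
#'   (emitted as gap characters).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 14,
                       samples_per_pop = c(rep(11L, 13), 10L),
                       seq_length = 16576,
                       per_site_mu = 2e-8,
                       Ne = 5e4,
                       migration_rate = 0,
                       split_time = 6e3,
                       Ne_ancestral = NULL,
                       group_split = NULL,
                       group_split_time = NULL,
                       expansion = NULL,
                       ts_tv_ratio = 7.6,
                       indel_rate = 0,
                       seed = 1L) {
  stopifnot(
    n_populations >= 1, seq_length >= 1, per_site_mu >= 0, Ne > 0,
    migration_rate >= 0, ts_tv_ratio > 0, indel_rate >= 0
  )
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_populations)
  if (any(samples_per_pop < 1L)) stop("all sample counts must be >= 1", call. = FALSE)
  if (is.null(Ne_ancestral)) Ne_ancestral <- Ne
  if (!is.null(expansion)) {
    stopifnot(inherits(expansion, "sudden_expansion"))
    if (n_populations != 1L) {
      stop("sudden-expansion simulations use a single population", call. = FALSE)
    }
  }
  if (!is.null(group_split)) {
    group_split <- as.integer(group_split)
    stopifnot(length(group_split) == n_populations, !is.null(group_split_time))
    if (group_split_time <= split_time) {
      stop("group_split_time must exceed split_time", call. = FALSE)
    }
  }
  if (n_populations > 1L && migration_rate == 0 && !is.finite(split_time)) {
    stop("isolated demes never coalesce: set migration_rate > 0 or a finite split_time",
      call. = FALSE)
  }
  structure(
    list(
      n_populations = as.integer(n_populations),
      samples_per_pop = samples_per_pop,
      seq_length = as.integer(seq_length),
      per_site_mu = per_site_mu,
      Ne = Ne,
      migration_rate = migration_rate,
      split_time = split_time,
      Ne_ancestral = Ne_ancestral,
      group_split = group_split,
      group_split_time = group_split_time,
      expansion = expansion,
      ts_tv_ratio = ts_tv_ratio,
      indel_rate = indel_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Sudden-expansion demography
#'
#' @param tau Expansion time in mutational units of pairwise differences
#'   (`tau = 2 u t`).
#' @param theta0,theta1 Pre- and post-expansion scaled sizes (`theta = 2 N u`),
#'   `theta0 <= theta1`.
#' @return An object of class `sudden_expansion`.
#' @export
sudden_expansion <- function(tau, theta0 = 0.5, theta1 = 1000) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 > 0, theta0 <= theta1)
  structure(list(tau = tau, theta0 = theta0, theta1 = theta1),
    class = "sudden_expansion")
}

# Piecewise-constant deme sizes and merge schedule implied by a config.
sim_epochs <- function(config) {
  u <- config$per_site_mu * config$seq_length
  if (!is.null(config$expansion)) {
    ex <- config$expansion
    if (u <= 0) stop("expansion simulations need per_site_mu > 0", call. = FALSE)
    t_exp <- ex$tau / (2 * u)
    list(
      sizes = c(recent = ex$theta1 / (2 * u), ancient = max(ex$theta0 / (2 * u), 1e-6)),
      change_time = t_exp, split_time = Inf, group_split_time = Inf
    )
  } else {
    list(
      sizes = NULL, change_time = Inf,
      split_time = config$split_time,
      group_split_time = if (is.null(config$group_split_time)) Inf else config$group_split_time
    )
  }
}

#' Simulate a structured-coalescent genealogy
#'
#' Simulates one genealogy over all samples under the demography in `config`.
#' Branch lengths are in generations; tips are labelled
#' `POP<p>_<i>` and carry their deme of origin.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genealogy`: `tree` (an [ape::phylo]),
#'   `samples` (tibble `sample_id`, `population`), `tmrca` (generations), and
#'   `config`.
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  np <- config$n_populations
  n <- sum(config$samples_per_pop)
  pop_names <- paste0("POP", formatC(seq_len(np), width = 2, flag = "0"))
  deme <- rep(seq_len(np), config$samples_per_pop)
  tip_labels <- unlist(lapply(seq_len(np), function(p) {
    paste0(pop_names[p], "_", formatC(seq_len(config$samples_per_pop[p]),
      width = 3, flag = "0"))
  }))
  samples <- tibble::tibble(sample_id = tip_labels, population = pop_names[deme])
  if (n == 1L) stop("need at least 2 samples in total", call. = FALSE)

  ep <- sim_epochs(config)
  deme_size <- function(t) {
    if (!is.null(ep$sizes)) {
      if (t < ep$change_time) ep$sizes[["recent"]] else ep$sizes[["ancient"]]
    } else {
      config$Ne
    }
  }
  # lineage state
  lin_deme <- deme
  lin_nwk <- tip_labels
  lin_age <- rep(0, n)
  t <- 0
  merged_within <- FALSE
  merged_all <- is.null(config$group_split) && np == 1L
  group_of <- if (is.null(config$group_split)) rep(1L, np) else config$group_split

  boundaries <- sort(unique(c(
    if (is.finite(ep$change_time)) ep$change_time,
    if (is.finite(ep$split_time)) ep$split_time,
    if (is.finite(ep$group_split_time)) ep$group_split_time
  )))

  repeat {
    k <- length(lin_deme)
    if (k == 1L) break
    tab <- tabulate(lin_deme, nbins = np)
    size_now <- if (!is.null(ep$sizes)) {
      deme_size(t)
    } else if (is.finite(ep$split_time) && t >= ep$split_time) {
      config$Ne_ancestral # surviving demes are ancestral demes after the merge
    } else {
      config$Ne
    }
    coal_rate <- ifelse(tab >= 2, choose(tab, 2) / size_now, 0)
    mig_on <- config$migration_rate > 0 && t < ep$split_time && np > 1L
    mig_rate <- if (mig_on) k * config$migration_rate else 0
    total <- sum(coal_rate) + mig_rate
    nb <- boundaries[boundaries > t]
    dt <- if (total > 0) stats::rexp(1, total) else Inf
    if (length(nb) > 0 && t + dt > nb[1]) {
      t <- nb[1]
      # apply merges at this boundary
      if (is.finite(ep$split_time) && t >= ep$split_time && !merged_within) {
        if (is.null(config$group_split)) {
          lin_deme[] <- 1L
          merged_all <- TRUE
        } else {
          # merge demes within each group into the group's first deme
          for (g in unique(group_of)) {
            target <- which(group_of == g)[1]
            lin_deme[group_of[lin_deme] == g] <- target
          }
        }
        merged_within <- TRUE
      }
      if (is.finite(ep$group_split_time) && t >= ep$group_split_time && !merged_all) {
        lin_deme[] <- 1L
        merged_all <- TRUE
      }
      next
    }
    if (!is.finite(dt)) {
      stop("no events possible: demographic configuration leaves lineages isolated",
        call. = FALSE)
    }
    t <- t + dt
    if (stats::runif(1) < sum(coal_rate) / total) {
      d <- sample.int(np, 1L, prob = coal_rate)
      idx <- which(lin_deme == d)
      pair <- sample(idx, 2L)
      i <- pair[1]; j <- pair[2]
      nwk <- sprintf("(%s:%.10g,%s:%.10g)", lin_nwk[i], t - lin_age[i],
        lin_nwk[j], t - lin_age[j])
      lin_nwk[i] <- nwk
      lin_age[i] <- t
      lin_deme <- lin_deme[-j]; lin_nwk <- lin_nwk[-j]; lin_age <- lin_age[-j]
    } else {
      i <- sample.int(k, 1L)
      lin_deme[i] <- sample(setdiff(seq_len(np), lin_deme[i]), 1L)
    }
  }
  tree <- ape::read.tree(text = paste0(lin_nwk[1], ";"))
  structure(
    list(tree = tree, samples = samples, tmrca = t, config = config),
    class = "sim_genealogy"
  )
}

#' Evolve sequences along a genealogy
#'
#' Finite-sites mutation: the number of substitutions on each branch is
#' Poisson with mean `per_site_mu * seq_length * branch_length`; each
#' substitution hits a uniform site and is a transition with probability
#' `ts_tv_ratio / (ts_tv_ratio + 1)`, otherwise one of the two transversions
#' at random. Multiple hits at a site are possible. Optional single-base
#' deletions (rate `indel_rate` per site per generation) become gap
#' characters inherited by all descendants.
#'
#' @param genealogy A [simulate_genealogy()] result.
#' @param config The same [sim_config()] (for mutation parameters and seed).
#' @return A list of class `sim_alignment`: `alignment` (`DNAbin` matrix),
#'   `n_substitutions`, `n_transitions`, `n_transversions`, `n_indels`.
#' @export
mutate_sequences <- function(genealogy, config = genealogy$config) {
  stopifnot(inherits(genealogy, "sim_genealogy"))
  set.seed(derive_seed(config$seed, 2L))
  tree <- genealogy$tree
  L <- config$seq_length
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  p_ts <- config$ts_tv_ratio / (config$ts_tv_ratio + 1)
  # transversion targets for each base 1=A 2=C 3=G 4=T
  tv_targets <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
  ts_target <- c(3L, 4L, 1L, 2L)
  n_sub <- n_ts <- n_tv <- n_ind <- 0L
  # process edges parent-before-child
  done <- rep(FALSE, nrow(tree$edge))
  while (!all(done)) {
    ready <- which(!done & !vapply(tree$edge[, 1], function(p) is.null(seqs[[p]]), logical(1)))
    if (length(ready) == 0L) stop("tree traversal failed", call. = FALSE)
    for (e in ready) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      s <- seqs[[par]]
      nm <- stats::rpois(1L, config$per_site_mu * L * len)
      if (nm > 0L) {
        sites <- sample.int(L, nm, replace = TRUE)
        for (site in sites) {
          cur <- s[site]
          if (cur == 5L) next # deleted sites stay deleted
          n_sub <- n_sub + 1L
          if (stats::runif(1) < p_ts) {
            s[site] <- ts_target[cur]
            n_ts <- n_ts + 1L
          } else {
            s[site] <- sample(tv_targets[[cur]], 1L)
            n_tv <- n_tv + 1L
          }
        }
      }
      if (config$indel_rate > 0) {
        ni <- stats::rpois(1L, config$indel_rate * L * len)
        if (ni > 0L) {
          sites <- sample.int(L, ni, replace = TRUE)
          s[sites] <- 5L
          n_ind <- n_ind + ni
        }
      }
      seqs[[child]] <- s
      done[e] <- TRUE
    }
  }
  chars <- c("A", "C", "G", "T", "-")
  m <- matrix("", nrow = ntip, ncol = L, dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip)) m[i, ] <- chars[seqs[[i]]]
  structure(
    list(
      alignment = ape::as.DNAbin(m),
      n_substitutions = n_sub, n_transitions = n_ts, n_transversions = n_tv,
      n_indels = n_ind
    ),
    class = "sim_alignment"
  )
}

# Expected fixation index implied by a config (low-mutation approximation
# from mean coalescence times; recorded as truth for monotonicity checks).
expected_phist <- function(config) {
  np <- config$n_populations
  if (np == 1L) return(0)
  if (config$migration_rate > 0 && !is.finite(config$split_time)) {
    d <- np
    Nm <- config$Ne * config$migration_rate
    return(1 / (1 + 2 * Nm * (d / (d - 1))^2))
  }
  # split model: Slatkin-style from expected coalescence times
  Tw <- config$Ne
  Tb <- config$split_time + config$Ne_ancestral
  n_pairs_within <- sum(choose(config$samples_per_pop, 2))
  n <- sum(config$samples_per_pop)
  n_pairs_total <- choose(n, 2)
  Tbar <- (n_pairs_within * Tw + (n_pairs_total - n_pairs_within) * Tb) / n_pairs_total
  (Tbar - Tw) / Tbar
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_genealogy()] and [mutate_sequences()], writes the FASTA
#' alignment, the sample-to-population table, deterministic population
#' coordinates (an arc along a model coastline), and a JSON truth sidecar
#' carrying the generating parameters, the true genealogy (newick), the true
#' TMRCA, group labels, the expansion `tau` (if any), and the
#' expected between-population fixation index.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing). `NULL` returns the
#'   objects without writing files.
#' @return A list of class `sim_dataset`: `alignment`, `samples`,
#'   `coordinates`, `truth`, `genealogy`, and (when written) `paths`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  gen <- simulate_genealogy(config)
  mut <- mutate_sequences(gen, config)
  np <- config$n_populations
  pops <- unique(gen$samples$population)
  # coastline-like arc, deterministic in the number of populations
  i <- seq_len(np)
  coords <- tibble::tibble(
    population = pops,
    lat = 44 + 1.6 * i + 1.2 * sin(i / 2),
    lon = -62 + 2.4 * i + 0.8 * cos(i / 3)
  )
  truth <- list(
    seed = config$seed,
    n_populations = np,
    samples_per_pop = config$samples_per_pop,
    seq_length = config$seq_length,
    tmrca_generations = gen$tmrca,
    true_tree = ape::write.tree(gen$tree),
    group_labels = if (is.null(config$group_split)) rep(1L, np) else config$group_split,
    tau_true = if (is.null(config$expansion)) NULL else config$expansion$tau,
    expected_phist = expected_phist(config),
    n_substitutions = mut$n_substitutions,
    n_transitions = mut$n_transitions,
    n_transversions = mut$n_transversions
  )
  out <- structure(
    list(
      alignment = mut$alignment, samples = gen$samples, coordinates = coords,
      truth = truth, genealogy = gen
    ),
    class = "sim_dataset"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "alignment.fasta"),
      populations = file.path(dir, "populations.tsv"),
      coordinates = file.path(dir, "coordinates.tsv"),
      truth = file.path(dir, "truth.json")
    )
    write_alignment(mut$alignment, paths$fasta)
    utils::write.table(gen$samples, paths$populations,
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(coords, paths$coordinates,
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Simulate a microarray intensity table for an alignment
#'
#' Emits four-channel hybridization intensities for both strands at every
#' position of the selected sequences: the true base's channel has mean 100,
#' the other channels mean 10, with Gaussian noise of standard deviation
#' `noise_sd` (negative draws truncated at 0). With `noise_sd = 0` every
#' position is recovered as a strong call; increasing noise pushes positions
#' under the dS/N thresholds.
#'
#' @param aln Alignment without gaps at the emitted positions.
#' @param noise_sd Noise standard deviation on the intensity scale.
#' @param seed Integer seed.
#' @param samples Sample ids (default: first sequence).
#' @param reference Reference sequence as a character vector (default: first
#'   sequence of the alignment).
#' @return A tibble with columns `sample_id`, `position`, `strand`, `I_A`,
#'   `I_C`, `I_G`, `I_T`, `ref`.
#' @export
generate_intensity_table <- function(aln, noise_sd = 0, seed = 1L,
                                     samples = NULL, reference = NULL) {
  m <- aln_chars(aln)
  if (is.null(samples)) samples <- rownames(m)[1]
  if (is.null(reference)) reference <- m[1, ]
  set.seed(derive_seed(seed, 3L))
  rows <- list()
  for (sid in samples) {
    s <- m[sid, ]
    if (any(!s %in% BASES)) {
      stop("alignment contains gaps/ambiguities at emitted positions", call. = FALSE)
    }
    L <- length(s)
    for (strand in c("forward", "reverse")) {
      mean_mat <- matrix(10, nrow = L, ncol = 4)
      mean_mat[cbind(seq_len(L), match(s, BASES))] <- 100
      noise <- matrix(stats::rnorm(L * 4, 0, noise_sd), nrow = L)
      inten <- pmax(mean_mat + noise, 0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, position = seq_len(L), strand = strand,
        I_A = inten[, 1], I_C = inten[, 2], I_G = inten[, 3], I_T = inten[, 4],
        ref = reference
      )
    }
  }
  dplyr::bind_rows(rows)
}
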