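# Spatially constrained search over population groupings maximizing the
# among-group variance component (Phi-CT).

#' Build a geographic neighbor graph for populations
#'
#' Delaunay-derived adjacency on locally projected coordinates: an edge joins
#' two populations whenever they share a Delaunay triangle (empty-circumcircle
#' test on all triples). With fewer than 4 populations the complete graph is
#' returned; collinear configurations degrade to the path graph along the
#' line. Duplicate coordinates are jittered deterministically with a warning.
#'
#' @param coordinates Data frame with `population`, `lat`, `lon` (decimal
#'   degrees).
#' @return An [igraph::graph] with vertex names = population names.
#' @export
build_neighbor_graph <- function(coordinates) {
  stopifnot(all(c("population", "lat", "lon") %in% names(coordinates)))
  n <- nrow(coordinates)
  if (n < 2) stop("need at least 2 populations", call. = FALSE)
  pops <- as.character(coordinates$population)
  # local equirectangular projection
  lat0 <- mean(coordinates$lat)
  x <- coordinates$lon * cos(lat0 * pi / 180)
  y <- coordinates$lat
  pts <- cbind(x, y)
  dup <- duplicated(round(pts, 9))
  if (any(dup)) {
    warning("duplicate coordinates jittered")
    idx <- which(dup)
    pts[idx, ] <- pts[idx, ] + 1e-6 * seq_along(idx)
  }
  adj <- matrix(FALSE, n, n, dimnames = list(pops, pops))
  if (n <= 3) {
    adj[] <- TRUE
  } else {
    # collinearity check
    areas <- utils::combn(n, 3, function(tr) {
      abs(det(cbind(pts[tr[2:3], 1] - pts[tr[1], 1], pts[tr[2:3], 2] - pts[tr[1], 2])))
    })
    if (max(areas) < 1e-9) {
      # path graph along the dominant direction
      ord <- order(pts[, which.max(apply(pts, 2, stats::var))])
      for (i in seq_len(n - 1)) adj[ord[i], ord[i + 1]] <- adj[ord[i + 1], ord[i]] <- TRUE
    } else {
      combs <- utils::combn(n, 3)
      for (c_i in seq_len(ncol(combs))) {
        tr <- combs[, c_i]
        cc <- circumcircle(pts[tr[1], ], pts[tr[2], ], pts[tr[3], ])
        if (is.null(cc)) next
        others <- setdiff(seq_len(n), tr)
        d2 <- (pts[others, 1] - cc$x)^2 + (pts[others, 2] - cc$y)^2
        if (all(d2 > cc$r2 * (1 + 1e-9))) {
          adj[tr[1], tr[2]] <- adj[tr[2], tr[1]] <- TRUE
          adj[tr[1], tr[3]] <- adj[tr[3], tr[1]] <- TRUE
          adj[tr[2], tr[3]] <- adj[tr[3], tr[2]] <- TRUE
        }
      }
      # degenerate fallback: ensure connectivity by linking nearest neighbors
      if (!all(rowSums(adj) > 0)) {
        for (i in which(rowSums(adj) == 0)) {
          d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
          d2[i] <- Inf
          j <- which.min(d2)
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  }
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
    (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
  uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
    (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
  list(x = ux, y = uy, r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
}

# Aggregate pair-sum machinery: Phi-CT for a grouping from per-population
# aggregates, avoiding a full n x n pass per proposal.
samova_precompute <- function(d2, pop) {
  pop <- droplevels(factor(pop))
  W <- pair_sums_by(d2, pop) # ordered-pair sums between pops; diag = 2*within
  sizes <- as.vector(table(pop))
  names(sizes) <- levels(pop)
  list(W = W, sizes = sizes, pops = levels(pop), N = sum(sizes),
    ss_total = sum(d2) / (2 * sum(sizes)),
    ss_wp = sum(diag(W) / 2 / sizes))
}

# Phi-CT (and friends) given group index per population.
phi_ct_of_grouping <- function(pre, g_idx) {
  G <- max(g_idx)
  P <- length(pre$pops)
  N <- pre$N
  Ng <- as.vector(tapply(pre$sizes, g_idx, sum))
  if (length(Ng) < G || any(Ng == 0)) return(NULL)
  # within-group pair sums from aggregates
  ss_wg <- 0
  for (g in seq_len(G)) {
    idx <- which(g_idx == g)
    ss_wg <- ss_wg + sum(pre$W[idx, idx]) / 2 / Ng[g]
  }
  ss_ag <- pre$ss_total - ss_wg
  ss_ap <- ss_wg - pre$ss_wp
  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P
  sigma_c <- pre$ss_wp / df_wp
  sum_n2_by_grp <- tapply(pre$sizes^2, g_idx, sum)
  n1 <- if (df_ap > 0) (N - sum(sum_n2_by_grp / Ng)) / df_ap else NA
  n2 <- (sum(sum_n2_by_grp / Ng) - sum(pre$sizes^2) / N) / df_ag
  n3 <- (N - sum(Ng^2) / N) / df_ag
  sigma_b <- if (df_ap > 0) (ss_ap / df_ap - sigma_c) / n1 else 0
  sigma_a <- (ss_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  sigma_a / (sigma_a + sigma_b + sigma_c)
}

# Random contiguity-respecting K-partition grown from K seed populations.
random_contiguous_partition <- function(adj, K) {
  n <- nrow(adj)
  g <- rep(NA_integer_, n)
  seeds <- sample.int(n, K)
  g[seeds] <- seq_len(K)
  while (anyNA(g)) {
    frontier <- which(!is.na(g))
    grew <- FALSE
    for (v in sample(frontier)) {
      nb <- which(adj[v, ] & is.na(g))
      if (length(nb) > 0) {
        u <- if (length(nb) == 1) nb else sample(nb, 1)
        g[u] <- g[v]
        grew <- TRUE
        break
      }
    }
    if (!grew) {
      # disconnected leftover: attach to a random group
      v <- which(is.na(g))[1]
      g[v] <- sample.int(K, 1)
    }
  }
  g
}

#' SAMOVA: spatial search for population groupings maximizing Phi-CT
#'
#' Simulated annealing over geographically contiguous K-partitions of
#' populations. Each run starts from a random contiguity-respecting
#' partition; a proposal moves one border population to an adjacent group
#' (groups must stay non-empty), is accepted when it increases Phi-CT and
#' otherwise with probability `exp(delta / T)` under geometric cooling
#' (`T0 = 0.1`, ratio 0.9 per 100 steps). The best grouping over `n_runs`
#' independent runs is returned, with a p-value from permuting populations
#' among groups.
#'
#' @inheritParams amova
#' @param coordinates Population coordinates (`population`, `lat`, `lon`);
#'   ignored when `spatial = FALSE`.
#' @param K Number of groups (2 <= K <= number of populations).
#' @param n_runs Independent annealing runs.
#' @param n_steps Proposals per run.
#' @param spatial Enforce geographic contiguity through the neighbor graph.
#' @param t0,cooling Annealing temperature schedule (geometric, applied every
#'   100 steps).
#' @return An object of class `samova_fit`: `K`, `grouping` (tibble
#'   `population`, `group`), `phi_ct`, `p_value`, `trace` (best-so-far per
#'   run), `n_runs`, `n_steps`, `n_perm`, `seed`.
#' @export
samova_search <- function(dist, assignment, coordinates = NULL, K = 2,
                          n_runs = 10, n_steps = 2000, n_perm = 999,
                          seed = 1L, spatial = TRUE,
                          t0 = 0.1, cooling = 0.9) {
  da <- align_dist_assignment(dist, assignment)
  pre <- samova_precompute(da$mat, da$pop)
  P <- length(pre$pops)
  if (K < 2 || K > P) stop("K must be in [2, number of populations]", call. = FALSE)
  adj <- if (spatial) {
    if (is.null(coordinates)) stop("spatial search needs coordinates", call. = FALSE)
    gr <- build_neighbor_graph(coordinates)
    am <- as.matrix(igraph::as_adjacency_matrix(gr))
    am <- am[pre$pops, pre$pops] > 0
    am
  } else {
    matrix(TRUE, P, P, dimnames = list(pre$pops, pre$pops))
  }
  diag(adj) <- FALSE
  set.seed(derive_seed(seed, 6L))
  best_phi <- -Inf
  best_g <- NULL
  trace <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    g <- random_contiguous_partition(adj, K)
    phi <- phi_ct_of_grouping(pre, g)
    run_best_phi <- phi
    run_best_g <- g
    temp <- t0
    hist_phi <- numeric(0)
    for (step in seq_len(n_steps)) {
      if (step %% 100 == 0) temp <- temp * cooling
      # candidate: border population adjacent to a different group
      cand <- which(vapply(seq_len(P), function(v) {
        any(adj[v, ] & g != g[v]) && sum(g == g[v]) > 1L
      }, logical(1)))
      if (length(cand) == 0) break
      v <- if (length(cand) == 1) cand else sample(cand, 1)
      target_groups <- unique(g[adj[v, ] & g != g[v]])
      tg <- if (length(target_groups) == 1) target_groups else sample(target_groups, 1)
      g2 <- g
      g2[v] <- tg
      phi2 <- phi_ct_of_grouping(pre, g2)
      if (is.null(phi2)) next
      delta <- phi2 - phi
      if (delta > 0 || stats::runif(1) < exp(delta / temp)) {
        g <- g2
        phi <- phi2
        if (phi > run_best_phi) {
          run_best_phi <- phi
          run_best_g <- g
        }
      }
      hist_phi <- c(hist_phi, run_best_phi)
    }
    trace[[run]] <- tibble::tibble(run = run, step = seq_along(hist_phi),
      best_phi_ct = hist_phi)
    if (run_best_phi > best_phi) {
      best_phi <- run_best_phi
      best_g <- run_best_g
    }
  }
  # permutation p-value: populations permuted among groups (sizes fixed)
  null_phi <- replicate(n_perm, {
    val <- phi_ct_of_grouping(pre, sample(best_g))
    if (is.null(val)) NA_real_ else val
  })
  null_phi <- null_phi[!is.na(null_phi)]
  p <- perm_pvalue(sum(null_phi >= best_phi), length(null_phi))
  out <- list(
    K = K,
    grouping = tibble::tibble(population = pre$pops, group = best_g),
    phi_ct = best_phi,
    p_value = p,
    trace = dplyr::bind_rows(trace),
    n_runs = n_runs, n_steps = n_steps, n_perm = n_perm, seed = seed,
    spatial = spatial
  )
  class(out) <- "samova_fit"
  out
}

#' @export
print.samova_fit <- function(x, ...) {
  cat(sprintf("SAMOVA K = %d: Phi-CT = %.4f (p = %.4g; %d runs x %d steps)\n",
    x$K, x$phi_ct, x$p_value, x$n_runs, x$n_steps))
  print(x$grouping, ...)
  invisible(x)
}

#' Run SAMOVA over a range of K
#'
#' @inheritParams samova_search
#' @param k_range Integer vector of K values.
#' @return A tibble with one row per K: `K`, `phi_ct`, `p_value`, and the
#'   grouping as a list column `grouping`.
#' @export
samova_scan <- function(dist, assignment, coordinates = NULL,
                        k_range = 2:4, n_runs = 10, n_steps = 2000,
                        n_perm = 999, seed = 1L, spatial = TRUE) {
  rows <- lapply(k_range, function(K) {
    fit <- samova_search(dist, assignment, coordinates, K = K,
      n_runs = n_runs, n_steps = n_steps, n_perm = n_perm,
      seed = derive_seed(seed, 200L + K), spatial = spatial)
    tibble::tibble(K = K, phi_ct = fit$phi_ct, p_value = fit$p_value,
      grouping = list(fit$grouping))
  })
  dplyr::bind_rows(rows)
}
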