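# AMOVA variance decomposition and permutation inference.
#
# Distances enter as pairwise counts of nucleotide differences; following the
# molecular-variance framework these counts play the role of squared
# Euclidean distances between individuals, so sums of squares are computed
# directly from pair sums.

# Sum of delta^2 over pairs within each subset defined by factor f.
pair_sums_by <- function(d2, f) {
  B <- rowsum(d2, f)
  G <- rowsum(t(B), f)
  (G + t(G)) / 2 # symmetric; diagonal entries are 2 * within-sums
}

# Two-level decomposition: among / within populations.
amova_two_level <- function(d2, pop) {
  N <- nrow(d2)
  sizes <- as.vector(table(pop))
  P <- length(sizes)
  S <- pair_sums_by(d2, pop)
  ss_total <- sum(d2) / (2 * N)
  ss_within <- sum(diag(S) / 2 / sizes)
  ss_among <- ss_total - ss_within
  df_among <- P - 1
  df_within <- N - P
  sigma_w <- ss_within / df_within
  n_prime <- (N - sum(sizes^2) / N) / df_among
  sigma_a <- (ss_among / df_among - sigma_w) / n_prime
  phi_st <- sigma_a / (sigma_a + sigma_w)
  list(
    ss = c(among = ss_among, within = ss_within, total = ss_total),
    df = c(among = df_among, within = df_within),
    sigma = c(among = sigma_a, within = sigma_w),
    phi_st = phi_st
  )
}

# Three-level decomposition: among groups / among populations within groups /
# within populations.
amova_three_level <- function(d2, pop, grp_of_pop) {
  N <- nrow(d2)
  pop <- droplevels(factor(pop))
  grp <- factor(unname(grp_of_pop[as.character(pop)]))
  sizes <- as.vector(table(pop))
  names(sizes) <- levels(pop)
  P <- nlevels(pop)
  G <- nlevels(grp)
  Ng <- as.vector(tapply(sizes, grp_of_pop[levels(pop)], sum))
  S_pop <- pair_sums_by(d2, pop)
  S_grp <- pair_sums_by(d2, grp)
  ss_total <- sum(d2) / (2 * N)
  ss_wp <- sum(diag(S_pop) / 2 / sizes)
  ss_wg <- sum(diag(S_grp) / 2 / Ng)
  ss_ag <- ss_total - ss_wg
  ss_ap <- ss_wg - ss_wp
  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P
  sigma_c <- ss_wp / df_wp
  grp_idx <- grp_of_pop[levels(pop)]
  sum_n2_by_grp <- tapply(sizes^2, grp_idx, sum)
  Ng_by <- tapply(sizes, grp_idx, sum)
  n2 <- (sum(sum_n2_by_grp / Ng_by) - sum(sizes^2) / N) / df_ag
  n3 <- (N - sum(Ng_by^2) / N) / df_ag
  sigma_b <- if (df_ap > 0) {
    n1 <- (N - sum(sum_n2_by_grp / Ng_by)) / df_ap
    (ss_ap / df_ap - sigma_c) / n1
  } else {
    0 # singleton groups: no among-population-within-group level
  }
  sigma_a <- (ss_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(
    ss = c(among_groups = ss_ag, among_pops_within_groups = ss_ap,
      within_pops = ss_wp, total = ss_total),
    df = c(among_groups = df_ag, among_pops_within_groups = df_ap, within_pops = df_wp),
    sigma = c(among_groups = sigma_a, among_pops_within_groups = sigma_b,
      within_pops = sigma_c),
    phi_ct = sigma_a / tot,
    phi_sc = sigma_b / (sigma_b + sigma_c),
    phi_st = (sigma_a + sigma_b) / tot
  )
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical decomposition of molecular variance from a matrix of pairwise
#' nucleotide differences, with permutation p-values. Without `groups` a
#' two-level analysis (among/within populations) yields Phi-ST, with
#' significance from permuting individuals among populations. With `groups` a
#' three-level analysis yields Phi-CT (groups; populations permuted among
#' groups), Phi-SC (individuals permuted among populations within groups) and
#' Phi-ST (individuals permuted among all populations).
#'
#' @param dist Square matrix (or `dist`) of pairwise nucleotide differences,
#'   treated as squared distances.
#' @param assignment Sample-to-population assignment (data frame
#'   `sample_id`, `population`, or named vector).
#' @param groups Optional named vector or two-column data frame
#'   (`population`, `group`) mapping populations to groups.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @return An object of class `amova_fit`: `table` (tibble with source, df,
#'   SS, variance component, percent of variation), `phi` (named vector),
#'   `p_values`, `n_perm`, `seed`, `levels`.
#' @export
amova <- function(dist, assignment, groups = NULL, n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 1)
  da <- align_dist_assignment(dist, assignment)
  d2 <- da$mat
  pop <- da$pop
  if (any(table(pop) < 2)) {
    warning("population(s) with a single sample: ",
      paste(names(which(table(pop) < 2)), collapse = ", "))
  }
  set.seed(derive_seed(seed, 4L))
  if (is.null(groups)) {
    obs <- amova_two_level(d2, pop)
    null_phi <- replicate(n_perm, amova_two_level(d2, sample(pop))$phi_st)
    p_st <- perm_pvalue(sum(null_phi >= obs$phi_st), n_perm)
    tot <- sum(obs$sigma)
    tab <- tibble::tibble(
      source = c("among populations", "within populations", "total"),
      df = unname(c(obs$df, sum(obs$df))),
      SS = unname(obs$ss),
      sigma2 = unname(c(obs$sigma, tot)),
      percent = unname(100 * c(obs$sigma, tot) / tot)
    )
    out <- list(
      levels = 2L, table = tab,
      phi = c(phi_st = unname(obs$phi_st)),
      p_values = c(phi_st = p_st),
      n_perm = n_perm, seed = seed
    )
  } else {
    grp_of_pop <- as_group_map(groups)
    pops <- levels(pop)
    missing <- setdiff(pops, names(grp_of_pop))
    if (length(missing) > 0) {
      stop("populations without group: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    grp_of_pop <- grp_of_pop[pops]
    obs <- amova_three_level(d2, pop, grp_of_pop)
    pop_chr <- as.character(pop)
    # Phi-CT null: permute whole populations among groups (keep group sizes
    # in populations)
    null_ct <- replicate(n_perm, {
      perm_map <- stats::setNames(sample(unname(grp_of_pop)), pops)
      amova_three_level(d2, pop, perm_map)$phi_ct
    })
    # Phi-SC null: permute individuals among populations within groups
    null_sc <- replicate(n_perm, {
      new_pop <- pop_chr
      for (g in unique(grp_of_pop)) {
        idx <- which(grp_of_pop[pop_chr] == g)
        new_pop[idx] <- sample(pop_chr[idx])
      }
      amova_three_level(d2, factor(new_pop), grp_of_pop)$phi_sc
    })
    # Phi-ST null: permute individuals among all populations
    null_st <- replicate(n_perm, {
      amova_three_level(d2, sample(pop), grp_of_pop)$phi_st
    })
    tot <- sum(obs$sigma)
    tab <- tibble::tibble(
      source = c("among groups", "among populations within groups",
        "within populations", "total"),
      df = unname(c(obs$df, sum(obs$df))),
      SS = unname(obs$ss),
      sigma2 = unname(c(obs$sigma, tot)),
      percent = unname(100 * c(obs$sigma, tot) / tot)
    )
    out <- list(
      levels = 3L, table = tab,
      phi = c(phi_ct = unname(obs$phi_ct), phi_sc = unname(obs$phi_sc),
        phi_st = unname(obs$phi_st)),
      p_values = c(
        phi_ct = perm_pvalue(sum(null_ct >= obs$phi_ct), n_perm),
        phi_sc = perm_pvalue(sum(null_sc >= obs$phi_sc), n_perm),
        phi_st = perm_pvalue(sum(null_st >= obs$phi_st), n_perm)
      ),
      n_perm = n_perm, seed = seed
    )
  }
  class(out) <- "amova_fit"
  out
}

as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("population", "group") %in% names(groups)))
    stats::setNames(as.character(groups$group), as.character(groups$population))
  } else if (!is.null(names(groups))) {
    stats::setNames(as.character(groups), names(groups))
  } else {
    stop("`groups` must be a named vector or a (population, group) data frame",
      call. = FALSE)
  }
}

#' @export
print.amova_fit <- function(x, ...) {
  cat("AMOVA (", x$levels, "-level), ", x$n_perm, " permutations\n", sep = "")
  print(x$table, ...)
  for (nm in names(x$phi)) {
    cat(sprintf("  %s = %.4f (p = %.4g)\n", nm, x$phi[[nm]], x$p_values[[nm]]))
  }
  invisible(x)
}

#' Pairwise Phi-ST matrix with permutation p-values
#'
#' Each cell is the two-level AMOVA Phi-ST restricted to that population
#' pair; p-values come from permuting individuals between the two
#' populations. A modified false-discovery-rate critical level
#' [fdr_critical()] for the family of all pairwise tests is attached.
#' Populations below `min_pop_n` samples are excluded (reported in
#' `excluded`).
#'
#' @inheritParams amova
#' @param alpha Family-wise alpha for the FDR critical level.
#' @param min_pop_n Minimum population sample size to enter comparisons.
#' @param clamp_negative Clamp negative Phi estimates to 0 in the rendered
#'   matrix (estimates are always retained unclamped in `phi`).
#' @return An object of class `phist_matrix`: `phi` (matrix), `p` (matrix),
#'   `m` (number of tests), `p_crit`, `alpha`, `excluded`, `n_perm`, `seed`.
#' @export
pairwise_phist <- function(dist, assignment, n_perm = 999, seed = 1L,
                           alpha = 0.05, min_pop_n = 3, clamp_negative = FALSE) {
  da <- align_dist_assignment(dist, assignment)
  sizes <- table(da$pop)
  keep_pops <- names(sizes)[sizes >= min_pop_n]
  excluded <- setdiff(names(sizes), keep_pops)
  if (length(keep_pops) < 2) stop("need at least two populations", call. = FALSE)
  k <- length(keep_pops)
  phi <- matrix(0, k, k, dimnames = list(keep_pops, keep_pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(keep_pops, keep_pops))
  diag(pmat) <- 1
  pair_seed <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ids <- da$ids[da$pop %in% c(keep_pops[i], keep_pops[j])]
      sub <- da$mat[ids, ids]
      f <- droplevels(da$pop[match(ids, da$ids)])
      obs <- amova_two_level(sub, f)
      pair_seed <- pair_seed + 1L
      set.seed(derive_seed(seed, 100L + pair_seed))
      null_phi <- replicate(n_perm, amova_two_level(sub, sample(f))$phi_st)
      phi[i, j] <- phi[j, i] <- obs$phi_st
      pmat[i, j] <- pmat[j, i] <- perm_pvalue(sum(null_phi >= obs$phi_st), n_perm)
    }
  }
  m <- k * (k - 1) / 2
  out <- list(
    phi = if (clamp_negative) pmax(phi, 0) else phi,
    p = pmat, m = m,
    p_crit = fdr_critical(alpha, m), alpha = alpha,
    excluded = excluded, n_perm = n_perm, seed = seed
  )
  class(out) <- "phist_matrix"
  out
}

#' @export
print.phist_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Phi-ST (", x$m, " tests, p_crit = ", signif(x$p_crit, 3),
    ", ", x$n_perm, " permutations)\n", sep = "")
  print(round(x$phi, digits))
  if (length(x$excluded)) cat("excluded populations:", x$excluded, "\n")
  invisible(x)
}

#' Modified false-discovery-rate critical significance level
#'
#' The fixed critical level `alpha / sum(1/i, i = 1..m)` for `m` dependent
#' tests; a test is significant when its p-value is at or below this level.
#'
#' @param alpha Family alpha (0 < alpha < 1).
#' @param m Number of tests (>= 1).
#' @return The critical p-value.
#' @export
fdr_critical <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / sum(1 / seq_len(m))
}

#' Great-circle distance
#'
#' Haversine great-circle distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in kilometers.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates outside [-90, 90] x [-180, 180]", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371) # km
}

#' Geographic distance matrix from population coordinates
#'
#' @param coordinates A data frame with columns `population`, `lat`, `lon`.
#' @return A symmetric matrix of great-circle distances in km.
#' @export
geo_distance_matrix <- function(coordinates) {
  stopifnot(all(c("population", "lat", "lon") %in% names(coordinates)))
  n <- nrow(coordinates)
  m <- matrix(0, n, n, dimnames = list(coordinates$population, coordinates$population))
  for (i in seq_len(n)) {
    m[i, ] <- great_circle_distance(
      coordinates$lat[i], coordinates$lon[i], coordinates$lat, coordinates$lon)
  }
  m
}

#' Mantel test of isolation by distance
#'
#' Correlates linearized genetic distance `phi / (1 - phi)` with geographic
#' distance over population pairs, with significance from row/column
#' permutations (one-tailed, `r >= observed`). Cells with `phi = 1` are
#' excluded with a warning (their linearized value is infinite).
#'
#' @param phi A `phist_matrix` or a symmetric genetic-distance matrix.
#' @param geo Symmetric geographic distance matrix (same population order).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param linearize Apply the `phi/(1-phi)` transform (default TRUE).
#' @return An object of class `mantel_fit`: `r`, `p`, `r_squared`, `n_perm`,
#'   `seed`, `n_items`.
#' @export
mantel_ibd <- function(phi, geo, n_perm = 10000, seed = 1L, linearize = TRUE) {
  g <- if (inherits(phi, "phist_matrix")) phi$phi else as.matrix(phi)
  geo <- as.matrix(geo)
  if (!is.null(rownames(g)) && !is.null(rownames(geo))) {
    common <- intersect(rownames(g), rownames(geo))
    g <- g[common, common]
    geo <- geo[common, common]
  }
  if (!all(dim(g) == dim(geo))) stop("non-conformable matrices", call. = FALSE)
  if (linearize) {
    ones <- g >= 1 & row(g) != col(g)
    if (any(ones)) {
      warning(sum(ones) / 2, " pair(s) with phi >= 1 excluded (infinite linearized distance)")
      g[ones] <- NA
    }
    g <- g / (1 - g)
  }
  off <- g[upper.tri(g)]
  if (stats::sd(off, na.rm = TRUE) == 0 || all(is.na(off))) {
    stop("degenerate genetic matrix: correlation undefined", call. = FALSE)
  }
  set.seed(derive_seed(seed, 5L))
  fit <- vegan::mantel(stats::as.dist(g), stats::as.dist(geo),
    method = "pearson", permutations = n_perm, na.rm = TRUE)
  out <- list(
    r = unname(fit$statistic), p = fit$signif, r_squared = unname(fit$statistic)^2,
    n_perm = n_perm, seed = seed, n_items = nrow(g)
  )
  class(out) <- "mantel_fit"
  out
}

#' @export
print.mantel_fit <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f (R^2 = %.4f), p = %.4g (%d permutations)\n",
    x$r, x$r_squared, x$p, x$n_perm))
  invisible(x)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling (double-centering + eigendecomposition) of a
#' symmetric distance matrix. Percent variance per axis uses non-negative
#' eigenvalues only.
#'
#' @param dist Symmetric distance matrix (or `dist`).
#' @param n_axes Number of axes to return.
#' @return An object of class `pcoa_fit`: `coordinates` (tibble with `item`
#'   and `Axis1..k`), `percent_variance`, `eigenvalues`.
#' @export
pcoa_dist <- function(dist, n_axes = 3) {
  m <- as.matrix(dist)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(m)
  n_axes <- min(n_axes, n - 1)
  if (all(m == 0)) {
    coords <- matrix(0, n, n_axes)
    ev <- rep(0, n - 1)
  } else {
    sc <- stats::cmdscale(m, k = n_axes, eig = TRUE)
    coords <- sc$points
    if (ncol(coords) < n_axes) {
      coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
    }
    ev <- sc$eig
  }
  pos <- ev[ev > 1e-12]
  pct <- if (length(pos)) 100 * ev[seq_len(n_axes)] / sum(pos) else rep(0, n_axes)
  pct[ev[seq_len(n_axes)] <= 1e-12] <- 0
  items <- rownames(m)
  if (is.null(items)) items <- paste0("item", seq_len(n))
  ctbl <- tibble::as_tibble(as.data.frame(coords))
  names(ctbl) <- paste0("Axis", seq_len(n_axes))
  out <- list(
    coordinates = dplyr::bind_cols(tibble::tibble(item = items), ctbl),
    percent_variance = pct,
    eigenvalues = ev
  )
  class(out) <- "pcoa_fit"
  out
}

#' Contingency chi-square heterogeneity test
#'
#' Pearson chi-square test of a counts table (e.g. haplogroup-by-population),
#' with zero marginal rows/columns dropped with a warning.
#'
#' @param counts Non-negative integer matrix or table.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
contingency_chisq <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers", call. = FALSE)
  rz <- rowSums(m) == 0
  cz <- colSums(m) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " empty row(s) and ", sum(cz), " empty column(s)")
    m <- m[!rz, !cz, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) stop("table must be at least 2 x 2 after dropping", call. = FALSE)
  fit <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value
  )
}
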