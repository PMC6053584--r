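#' Haplotype diversity
#'
#' Nei's unbiased haplotype (gene) diversity
#' \eqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} from haplotype
#' frequencies \eqn{p_i}.
#'
#' @param x A `haplotype_table` from [collapse_haplotypes()], or a numeric
#'   vector of haplotype counts.
#' @param population Optional population name to restrict to (for a
#'   `haplotype_table`).
#' @return Haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(x, population = NULL) {
  counts <- if (inherits(x, "haplotype_table")) {
    tbl <- x$counts
    if (!is.null(population)) tbl <- tbl[tbl$population %in% population, ]
    tapply(tbl$n, tbl$haplotype_id, sum)
  } else {
    as.numeric(x)
  }
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity undefined for n < 2", call. = FALSE)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity
#'
#' Mean number of pairwise differences per analyzed site over all unordered
#' sample pairs. With `deletion = "pairwise"` (default) each pair is compared
#' over the sites where both sequences carry an unambiguous base; with
#' `"complete"` all sites containing any gap or ambiguity in any sequence are
#' removed first.
#'
#' @param aln Alignment (`DNAbin` or character matrix).
#' @param samples Optional sample ids to restrict to.
#' @param exclude Optional positions to skip.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return Nucleotide diversity per site (>= 0).
#' @export
nucleotide_diversity <- function(aln, samples = NULL, exclude = NULL,
                                 deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- aln_chars(aln)
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  keep <- keep_positions(ncol(m), exclude)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("nucleotide diversity undefined for n < 2", call. = FALSE)
  if (deletion == "complete") {
    ok <- apply(m, 2, function(col) all(col %in% BASES))
    m <- m[, ok, drop = FALSE]
  }
  cnt <- pair_difference_counts(m)
  ratios <- cnt$diff / cnt$valid
  ratios[cnt$valid == 0] <- NA
  mean(ratios[upper.tri(ratios)], na.rm = TRUE)
}

# Pairwise counts of differing and jointly-valid (both unambiguous base)
# sites, computed by one-hot cross products.
pair_difference_counts <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  valid_ind <- matrix(m %in% BASES, nrow = n)
  match_mat <- matrix(0, n, n)
  for (b in BASES) {
    X <- matrix(as.numeric(m == b), nrow = n)
    match_mat <- match_mat + tcrossprod(X)
  }
  V <- matrix(as.numeric(valid_ind), nrow = n)
  valid_mat <- tcrossprod(V)
  diff_mat <- valid_mat - match_mat
  dimnames(diff_mat) <- dimnames(valid_mat) <- list(rownames(m), rownames(m))
  list(diff = diff_mat, valid = valid_mat)
}

#' Per-population diversity table
#'
#' Convenience summary mirroring a standard mitogenome survey table: sample
#' size, number of haplotypes, haplotype diversity and nucleotide diversity
#' per population, plus a pooled row.
#'
#' @param aln Alignment.
#' @param assignment Sample-to-population assignment.
#' @param exclude Optional positions to skip.
#' @return A tibble with columns `population`, `n`, `h`, `H_d`, `pi`.
#' @export
diversity_table <- function(aln, assignment, exclude = NULL) {
  m <- aln_chars(aln)
  asg <- as_assignment(assignment)
  haps <- collapse_haplotypes(m, asg, exclude = exclude)
  pops <- c(sort(unique(asg$population)), "(all)")
  rows <- lapply(pops, function(p) {
    ids <- if (p == "(all)") asg$sample_id else asg$sample_id[asg$population == p]
    n <- length(ids)
    hsub <- haps$assignment[haps$assignment$sample_id %in% ids, ]
    h <- length(unique(hsub$haplotype_id))
    hd <- if (n >= 2) haplotype_diversity(table(hsub$haplotype_id)) else NA_real_
    pi <- if (n >= 2) nucleotide_diversity(m, samples = ids, exclude = exclude) else NA_real_
    tibble::tibble(population = p, n = n, h = h, H_d = hd, pi = pi)
  })
  dplyr::bind_rows(rows)
}

#' Mismatch distribution
#'
#' Histogram of the number of differing sites over all unordered sequence
#' pairs (pairwise deletion of gaps and ambiguities).
#'
#' @param aln Alignment, or a precomputed difference matrix
#'   (samples x samples, absolute counts).
#' @param samples Optional sample ids to restrict to.
#' @param exclude Optional positions to skip.
#' @return An object of class `mismatch`: list with `histogram` (tibble `k`,
#'   `count`, covering `0:max`), `n`, `n_pairs`, `mean_diff`.
#' @export
mismatch_distribution <- function(aln, samples = NULL, exclude = NULL) {
  if (is.matrix(aln) && is.numeric(aln)) {
    d <- aln
    if (!is.null(samples)) d <- d[samples, samples, drop = FALSE]
  } else {
    m <- aln_chars(aln)
    if (!is.null(samples)) m <- m[samples, , drop = FALSE]
    keep <- keep_positions(ncol(m), exclude)
    d <- pair_difference_counts(m[, keep, drop = FALSE])$diff
  }
  n <- nrow(d)
  if (n < 2) stop("mismatch distribution needs n >= 2", call. = FALSE)
  diffs <- round(d[upper.tri(d)])
  kmax <- max(diffs)
  counts <- tabulate(diffs + 1L, nbins = kmax + 1L)
  structure(
    list(
      histogram = tibble::tibble(k = 0:kmax, count = counts),
      n = n, n_pairs = length(diffs), mean_diff = mean(diffs)
    ),
    class = "mismatch"
  )
}

#' Expected mismatch probabilities under sudden expansion
#'
#' Probability that a random sequence pair differs at `k` sites under a
#' two-epoch coalescent: scaled size `theta1` more recently than `tau` (in
#' units of pairwise differences, i.e. time scaled by twice the per-genome
#' per-generation mutation rate) and `theta0` earlier. At `tau = 0` this is
#' the geometric equilibrium distribution for `theta0`; for large `theta1`
#' and small `theta0` it approaches the Poisson wave with mean `tau`.
#'
#' @param k Integer vector of difference classes.
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta0,theta1 Scaled sizes before/after the expansion.
#' @return Numeric vector of probabilities.
#' @export
expected_mismatch <- function(k, tau, theta0, theta1) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 > 0)
  k <- as.integer(k)
  a <- 1 + 1 / theta1
  recent <- (1 / theta1) * a^(-(k + 1)) * stats::pgamma(a * tau, shape = k + 1)
  theta0 <- max(theta0, 1e-12)
  b <- 1 + 1 / theta0
  # log-scale for the ancient-epoch term: e^{tau(1/theta0 - 1/theta1)} can be huge
  log_anc <- tau / theta0 - tau / theta1 - log(theta0) - (k + 1) * log(b) +
    stats::pgamma(b * tau, shape = k + 1, lower.tail = FALSE, log.p = TRUE)
  ancient <- exp(log_anc)
  ancient[!is.finite(ancient)] <- 0
  recent + ancient
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Bounded least squares of the observed relative mismatch frequencies
#' against [expected_mismatch()] over `(tau, theta0, theta1)`, with
#' `theta0 >= 0` and `theta0 <= theta1`. Several starting points are tried
#' and the best sum of squared deviations (SSD) is kept.
#'
#' @param mismatch A [mismatch_distribution()] result.
#' @return An object of class `expansion_fit`: list with `tau_hat`, `theta0`,
#'   `theta1`, `ssd`, `degenerate` flag, and the observed histogram.
#' @export
fit_sudden_expansion <- function(mismatch) {
  stopifnot(inherits(mismatch, "mismatch"))
  hist <- mismatch$histogram
  obs <- hist$count / sum(hist$count)
  kk <- hist$k
  if (max(kk[obs > 0]) == 0) {
    out <- list(tau_hat = 0, theta0 = 0, theta1 = 0, ssd = 0,
      degenerate = TRUE, histogram = hist)
    class(out) <- "expansion_fit"
    return(out)
  }
  mbar <- mismatch$mean_diff
  ssd_of <- function(par) {
    tau <- par[1]; th0 <- par[2]; th1 <- th0 + par[3]
    sum((obs - expected_mismatch(kk, tau, th0, th1))^2)
  }
  starts <- list(
    c(mbar, 0.5, 2 * mbar + 10),
    c(mbar / 2, 1, 5 * mbar + 10),
    c(max(kk[which.max(obs)], 0.5), 0.1, 10 * mbar + 10)
  )
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, ssd_of, method = "L-BFGS-B",
      lower = c(0, 0, 1e-6), upper = c(5 * max(kk) + 10, 1e4, 1e6)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("sudden-expansion fit failed", call. = FALSE)
  out <- list(
    tau_hat = best$par[1],
    theta0 = best$par[2],
    theta1 = best$par[2] + best$par[3],
    ssd = best$value,
    degenerate = FALSE,
    histogram = hist
  )
  class(out) <- "expansion_fit"
  out
}

#' Molecular-clock parameters from an outgroup calibration
#'
#' The two-lineage divergence rate is the observed mean genetic distance to
#' the calibration point divided by the calibration age; the one-lineage rate
#' is half of it. With a genome length the per-genome per-lineage mutation
#' rate and the mean waiting time between substitutions on the genome are
#' also reported.
#'
#' @param mean_distance Mean genetic distance in substitutions/site between
#'   the two sides of the calibrated split.
#' @param calibration_age Age of the split in years.
#' @param genome_length Genome length in bp (default 16576).
#' @return An object of class `clock`: `divergence_rate` (subs/site/year,
#'   two-lineage), `lineage_rate`, `u_genome` (mutations/genome/year, one
#'   lineage), `substitution_interval_years`, `genome_length`,
#'   `calibration_age`, `mean_distance`.
#' @export
divergence_rate <- function(mean_distance, calibration_age, genome_length = 16576) {
  if (calibration_age <= 0 || genome_length <= 0 || mean_distance < 0) {
    stop("mean_distance must be >= 0 and ages/lengths > 0", call. = FALSE)
  }
  rate <- mean_distance / calibration_age
  structure(
    list(
      divergence_rate = rate,
      lineage_rate = rate / 2,
      u_genome = rate / 2 * genome_length,
      substitution_interval_years = if (rate > 0) 1 / (rate * genome_length) else Inf,
      genome_length = genome_length,
      calibration_age = calibration_age,
      mean_distance = mean_distance
    ),
    class = "clock"
  )
}

#' @export
print.clock <- function(x, ...) {
  cat(sprintf(
    "Clock: divergence rate %.3g subs/site/year (lineage rate %.3g), calibrated at %.3g years\n",
    x$divergence_rate, x$lineage_rate, x$calibration_age))
  invisible(x)
}

#' Time since expansion from tau
#'
#' Converts a fitted mismatch `tau` to years via `t = tau / (2 u)`, where
#' `u` is the one-lineage per-genome mutation rate implied by the clock.
#'
#' @param tau Expansion parameter in units of pairwise differences, or an
#'   `expansion_fit`.
#' @param clock A [divergence_rate()] result.
#' @return Time since expansion in years.
#' @export
expansion_time <- function(tau, clock) {
  if (inherits(tau, "expansion_fit")) tau <- tau$tau_hat
  stopifnot(inherits(clock, "clock"), tau >= 0)
  if (clock$u_genome <= 0) stop("clock rate is zero", call. = FALSE)
  tau / (2 * clock$u_genome)
}
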