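test_that("haplotype diversity matches the unbiased formula", {
  # n = 4, counts (2, 1, 1): 4/3 * (1 - (0.25 + 0.0625 + 0.0625)) = 0.8333
  expect_equal(haplotype_diversity(c(2, 1, 1)), 4 / 3 * (1 - 0.375))
  expect_equal(haplotype_diversity(rep(1, 10)), 1)
  expect_equal(haplotype_diversity(c(5)), 0)
  expect_error(haplotype_diversity(c(1)), "n < 2")
  # enumeration oracle on random count vectors
  set.seed(1)
  for (i in 1:20) {
    counts <- rmultinom(1, sample(5:40, 1), prob = runif(sample(2:6, 1)))[, 1]
    counts <- counts[counts > 0]
    if (sum(counts) < 2) next
    n <- sum(counts)
    acc <- 0
    for (a in seq_along(counts)) acc <- acc + (counts[a] / n)^2
    expect_equal(haplotype_diversity(counts), n / (n - 1) * (1 - acc))
  }
})

test_that("nucleotide diversity equals the mean per-pair rate", {
  m <- rbind(s1 = strsplit("AAAAAAAAAA", "")[[1]],
             s2 = strsplit("AAGAAAAAAT", "")[[1]])
  expect_equal(nucleotide_diversity(m), 0.2)
  expect_equal(nucleotide_diversity(m[c(2, 1), ]), 0.2) # order invariance
  m_id <- m[c(1, 1), ]
  rownames(m_id) <- c("a", "b")
  expect_equal(nucleotide_diversity(m_id), 0)
  # brute-force oracle with gaps and ambiguities, pairwise deletion
  for (seed in 1:5) {
    r <- random_alignment(8, 60, seed, p_gap = 0.05, p_amb = 0.02)
    d <- oracle_pair_diffs(r)
    valid <- matrix(0, 8, 8)
    for (i in 1:7) {
      for (j in (i + 1):8) {
        ok <- r[i, ] %in% c("A", "C", "G", "T") & r[j, ] %in% c("A", "C", "G", "T")
        valid[i, j] <- sum(ok)
      }
    }
    want <- mean((d[upper.tri(d)]) / valid[upper.tri(valid)])
    expect_equal(nucleotide_diversity(r), want)
  }
})

test_that("diversity table reports per-population and pooled rows", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = c(5, 4),
    seq_length = 500, per_site_mu = 2e-6, Ne = 1000, split_time = 5000, seed = 31)
  ds <- generate_dataset(cfg)
  tbl <- diversity_table(ds$alignment, ds$samples)
  expect_identical(tbl$population, c("POP01", "POP02", "(all)"))
  expect_equal(tbl$n, c(5, 4, 9))
  expect_true(all(tbl$h <= tbl$n))
  expect_true(all(tbl$H_d >= 0 & tbl$H_d <= 1))
  expect_true(all(tbl$pi >= 0))
})

test_that("mismatch histograms count pairs correctly", {
  m <- rbind(a = c("A", "A", "A"), b = c("T", "A", "A"), c = c("T", "G", "A"))
  mm <- mismatch_distribution(m)
  # pairwise diffs: ab = 1, bc = 1, ac = 2
  expect_equal(mm$histogram$count[mm$histogram$k == 1], 2)
  expect_equal(mm$histogram$count[mm$histogram$k == 2], 1)
  expect_equal(sum(mm$histogram$count), choose(3, 2))
  id <- matrix("A", 4, 5, dimnames = list(letters[1:4], NULL))
  mm_id <- mismatch_distribution(id)
  expect_equal(mm_id$histogram$count, 6)
  expect_equal(mm_id$histogram$k, 0)
})

test_that("expected mismatch curve has the right limits", {
  k <- 0:80
  # tau = 0 reduces to the geometric equilibrium for theta0
  th <- 4.2
  expect_equal(expected_mismatch(k, 0, th, 10), th^k / (th + 1)^(k + 1))
  # large theta1, tiny theta0: Poisson wave with mean tau
  p <- expected_mismatch(0:300, 12, 1e-4, 1e5)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_equal(sum(0:300 * p), 12, tolerance = 0.01)
  expect_equal(p[13], dpois(12, 12), tolerance = 1e-3)
})

test_that("sudden-expansion fits separate expansion from constant size", {
  cfg_exp <- sim_config(n_populations = 1, samples_per_pop = 30, seq_length = 5000,
    per_site_mu = 1e-6, expansion = sudden_expansion(20, 0.5, 2000), seed = 41)
  mm_exp <- mismatch_distribution(difference_matrix(generate_dataset(cfg_exp)$alignment))
  fit_exp <- fit_sudden_expansion(mm_exp)
  expect_lt(abs(fit_exp$tau_hat - 20) / 20, 0.35)
  expect_false(fit_exp$degenerate)
  # all-identical input collapses to tau = 0
  id <- matrix("A", 5, 50, dimnames = list(letters[1:5], NULL))
  fit0 <- fit_sudden_expansion(mismatch_distribution(id))
  expect_true(fit0$degenerate)
  expect_equal(fit0$tau_hat, 0)
  # a constant-size coalescent is fit worse by the expansion curve than the
  # expansion data at comparable diversity
  cfg_const <- sim_config(n_populations = 1, samples_per_pop = 30, seq_length = 5000,
    per_site_mu = 1e-6, Ne = 2e6 / 2 / (1e-6 * 5000), seed = 41)
  mm_const <- mismatch_distribution(difference_matrix(generate_dataset(cfg_const)$alignment))
  fit_const <- fit_sudden_expansion(mm_const)
  expect_gt(fit_const$ssd, fit_exp$ssd)
})

test_that("clock arithmetic reproduces the calibration identities", {
  clk <- divergence_rate(0.039, 3.8e6, 16576)
  expect_equal(signif(clk$divergence_rate, 3), 1.03e-8)
  expect_equal(clk$lineage_rate, clk$divergence_rate / 2)
  expect_equal(divergence_rate(0, 3.8e6)$divergence_rate, 0)
  # doubling the calibration age halves the rate
  expect_equal(divergence_rate(0.039, 7.6e6)$divergence_rate,
    clk$divergence_rate / 2)
  expect_error(divergence_rate(0.039, -1), "> 0")
})

test_that("expansion time is linear in tau and inverts tau = 2 u t", {
  clk <- divergence_rate(0.039, 3.8e6, 16576)
  t1 <- expansion_time(10, clk)
  expect_equal(expansion_time(20, clk), 2 * t1)
  expect_equal(expansion_time(0, clk), 0)
  # round trip: for any t, tau = 2 u t maps back to t
  for (t in c(1e3, 5e4, 1.37e5)) {
    tau <- 2 * clk$u_genome * t
    expect_equal(expansion_time(tau, clk), t)
  }
  clk0 <- divergence_rate(0, 3.8e6)
  expect_error(expansion_time(5, clk0), "zero")
})
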