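test_that("fixed seeds give byte-identical datasets", {
  cfg <- sim_config(n_populations = 3, samples_per_pop = 4, seq_length = 300,
    per_site_mu = 1e-6, Ne = 1000, split_time = 5000, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  for (f in c("alignment.fasta", "populations.tsv", "coordinates.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = f)
  }
  # and the dataset reloads through the standard reader
  aln <- read_alignment(file.path(d1, "alignment.fasta"))
  expect_equal(nrow(as.matrix(aln)), 12)
  expect_equal(ncol(as.matrix(aln)), 300)
})

test_that("a two-sample coalescent has a single internal node", {
  cfg <- sim_config(n_populations = 1, samples_per_pop = 2, seq_length = 10,
    per_site_mu = 0, Ne = 100, seed = 2)
  gen <- simulate_genealogy(cfg)
  expect_equal(length(gen$tree$tip.label), 2)
  expect_equal(gen$tree$Nnode, 1)
  expect_gt(gen$tmrca, 0)
})

test_that("old splits without migration give reciprocal monophyly", {
  n_mono <- 0
  for (s in 1:100) {
    cfg <- sim_config(n_populations = 2, samples_per_pop = 3, seq_length = 10,
      per_site_mu = 0, Ne = 100, split_time = 1e5, seed = s)
    gen <- simulate_genealogy(cfg)
    tips1 <- gen$samples$sample_id[gen$samples$population == "POP01"]
    tips2 <- gen$samples$sample_id[gen$samples$population == "POP02"]
    if (ape::is.monophyletic(gen$tree, tips1) &&
      ape::is.monophyletic(gen$tree, tips2)) {
      n_mono <- n_mono + 1
    }
  }
  # split at 1000 * Ne generations: within-deme coalescence essentially always
  # completes before the merge
  expect_equal(n_mono, 100)
})

test_that("high migration scrambles labels like a random permutation", {
  # standardized deviation of the observed parsimony length from its
  # permutation null, averaged over independent genealogies, should sit
  # within ~2 standard errors of zero
  z <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(n_populations = 2, samples_per_pop = 8, seq_length = 10,
      per_site_mu = 0, Ne = 50, migration_rate = 0.2, split_time = Inf, seed = s)
    gen <- simulate_genealogy(cfg)
    states <- setNames(gen$samples$population, gen$samples$sample_id)
    L_obs <- fitch_length(gen$tree, states)
    set.seed(1000 + s)
    null <- vapply(1:200, function(i) {
      s2 <- states
      s2[] <- sample(unname(states))
      fitch_length(gen$tree, s2)
    }, integer(1))
    z[s] <- (L_obs - mean(null)) / stats::sd(null)
  }
  expect_lt(abs(mean(z)), 2 / sqrt(20))
})

test_that("mutation counts follow the branch-length expectation", {
  cfg <- sim_config(n_populations = 1, samples_per_pop = 2, seq_length = 2000,
    per_site_mu = 0, Ne = 500, seed = 3)
  gen <- simulate_genealogy(cfg)
  # zero rate: identical sequences
  aln0 <- mutate_sequences(gen, cfg)
  m0 <- mitophylogeo:::aln_chars(aln0$alignment)
  expect_identical(m0[1, ], m0[2, ])
  # expected pairwise differences ~ mu * L * path length between the two tips
  mu <- 5e-6
  path_len <- sum(gen$tree$edge.length)
  expected <- mu * 2000 * path_len
  diffs <- vapply(1:40, function(k) {
    cfg_k <- sim_config(n_populations = 1, samples_per_pop = 2, seq_length = 2000,
      per_site_mu = mu, Ne = 500, seed = 3000 + k)
    mk <- mitophylogeo:::aln_chars(mutate_sequences(gen, cfg_k)$alignment)
    sum(mk[1, ] != mk[2, ])
  }, numeric(1))
  # Poisson mean check within ~3 standard errors (finite-sites multiple hits
  # shave a little off; keep divergence low enough to ignore)
  se <- sqrt(expected / 40)
  expect_lt(abs(mean(diffs) - expected), 3 * se + 0.05 * expected)
})

test_that("transition bias matches ts_tv_ratio", {
  cfg <- sim_config(n_populations = 1, samples_per_pop = 30, seq_length = 5000,
    per_site_mu = 2e-5, Ne = 2000, ts_tv_ratio = 8, seed = 4)
  gen <- simulate_genealogy(cfg)
  mut <- mutate_sequences(gen, cfg)
  expect_gte(mut$n_substitutions, 1000)
  frac <- mut$n_transitions / mut$n_substitutions
  p <- 8 / 9
  se <- sqrt(p * (1 - p) / mut$n_substitutions)
  expect_lt(abs(frac - p), 4 * se)
})

test_that("indels appear as inherited gap characters", {
  cfg <- sim_config(n_populations = 1, samples_per_pop = 10, seq_length = 1000,
    per_site_mu = 1e-6, Ne = 2000, indel_rate = 2e-7, seed = 6)
  ds <- generate_dataset(cfg)
  m <- mitophylogeo:::aln_chars(ds$alignment)
  expect_true(any(m == "-"))
  cls <- classify_sites(m)
  expect_gte(cls$n_indel_sites, 1)
})

test_that("panmictic truth gives a non-significant Phi-ST", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = 8, seq_length = 2000,
    per_site_mu = 5e-7, Ne = 2000, migration_rate = 0.05, split_time = Inf, seed = 8)
  ds <- generate_dataset(cfg)
  expect_lt(ds$truth$expected_phist, 0.02)
  d <- difference_matrix(ds$alignment)
  fit <- amova(d, ds$samples, n_perm = 499, seed = 1)
  expect_gt(fit$p_values[["phi_st"]], 0.05)
  expect_lt(abs(fit$phi[["phi_st"]]), 0.2)
})

test_that("pairwise Phi-ST rises with divergence time", {
  phis <- vapply(c(2e3, 2e4, 2e5), function(Tsplit) {
    cfg <- sim_config(n_populations = 2, samples_per_pop = 8, seq_length = 4000,
      per_site_mu = 5e-7, Ne = 2e4, split_time = Tsplit, seed = 77)
    ds <- generate_dataset(cfg)
    d <- difference_matrix(ds$alignment)
    mitophylogeo:::amova_two_level(d, factor(ds$samples$population))$phi_st
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("intensity tables encode the true base with controllable noise", {
  m <- random_alignment(1, 200, seed = 9)
  tbl0 <- generate_intensity_table(m, noise_sd = 0, seed = 1)
  calls0 <- call_bases(tbl0)
  expect_identical(calls0$base, unname(m[1, ]))
  expect_true(all(calls0$status == "strong"))
  # large noise drives a detectable fraction of positions under dS/N 0.10
  tbl_noisy <- generate_intensity_table(m, noise_sd = 60, seed = 2)
  calls_noisy <- call_bases(tbl_noisy)
  expect_gt(sum(calls_noisy$excluded), 0)
  expect_true(any(pmin(calls_noisy$dsn_forward, calls_noisy$dsn_reverse) < 0.10))
})
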