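make_labels <- function(n) paste0("s", seq_len(n))

test_that("two-level AMOVA matches the first-principles oracle", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    npop <- sample(2:3, 1)
    pop <- sample(paste0("P", seq_len(npop)), n, replace = TRUE)
    while (length(unique(pop)) < npop || any(table(pop) < 2)) {
      pop <- sample(paste0("P", seq_len(npop)), n, replace = TRUE)
    }
    d2 <- matrix(0, n, n, dimnames = list(make_labels(n), make_labels(n)))
    vals <- sample(0:20, n * (n - 1) / 2, replace = TRUE)
    d2[upper.tri(d2)] <- vals
    d2 <- d2 + t(d2)
    asg <- tibble::tibble(sample_id = make_labels(n), population = pop)
    got <- mitophylogeo:::amova_two_level(d2, factor(pop))
    want <- oracle_amova2(d2, pop)
    expect_equal(got$ss[["among"]], want$ss_among, tolerance = 1e-10)
    expect_equal(got$ss[["within"]], want$ss_within, tolerance = 1e-10)
    expect_equal(unname(got$sigma["among"]), want$sigma_a, tolerance = 1e-10)
    expect_equal(unname(got$sigma["within"]), want$sigma_w, tolerance = 1e-10)
    expect_equal(got$phi_st, want$phi_st, tolerance = 1e-10)
  }
})

test_that("AMOVA sums of squares agree with classical ANOVA on 1-D embeddings", {
  # for points on a line with delta^2 = (x_i - x_j)^2 the molecular sums of
  # squares equal the classical treatment/error sums of squares
  set.seed(7)
  x <- rnorm(12)
  pop <- rep(c("A", "B", "C"), each = 4)
  d2 <- outer(x, x, function(a, b) (a - b)^2)
  dimnames(d2) <- list(make_labels(12), make_labels(12))
  got <- mitophylogeo:::amova_two_level(d2, factor(pop))
  fit <- stats::aov(x ~ pop)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(got$ss[["among"]], ss[1], tolerance = 1e-10)
  expect_equal(got$ss[["within"]], ss[2], tolerance = 1e-10)
})

test_that("three-level AMOVA percent variation sums to 100", {
  cfg <- sim_config(n_populations = 4, samples_per_pop = 5, seq_length = 1000,
    per_site_mu = 1e-6, Ne = 2000, split_time = 5000,
    group_split = c(1, 1, 2, 2), group_split_time = 5e4, seed = 13)
  ds <- generate_dataset(cfg)
  d <- difference_matrix(ds$alignment)
  grp <- setNames(c("G1", "G1", "G2", "G2"), paste0("POP0", 1:4))
  fit <- amova(d, ds$samples, groups = grp, n_perm = 99, seed = 1)
  expect_equal(fit$table$percent[fit$table$source == "total"], 100)
  expect_equal(sum(fit$table$percent[1:3]), 100, tolerance = 1e-8)
  expect_true(all(abs(fit$phi) <= 1))
  expect_true(all(fit$p_values >= 1 / 100 & fit$p_values <= 1))
  # deep group split: most variation among groups
  expect_gt(fit$phi[["phi_ct"]], 0.5)
})

test_that("degenerate population structures give the boundary Phi values", {
  # identical multisets of sequences in both populations
  m <- rbind(a1 = c("A", "A", "T"), a2 = c("A", "G", "T"),
             b1 = c("A", "A", "T"), b2 = c("A", "G", "T"))
  asg <- tibble::tibble(sample_id = rownames(m),
    population = c("A", "A", "B", "B"))
  d <- difference_matrix(m)
  fit <- amova(d, asg, n_perm = 99, seed = 1)
  expect_lt(fit$phi[["phi_st"]], 0.05) # estimate at or below zero
  expect_gt(fit$p_values[["phi_st"]], 0.3)
  # two populations fixed for distinct haplotypes: Phi-ST = 1
  m2 <- rbind(a1 = c("A", "A"), a2 = c("A", "A"),
              b1 = c("T", "G"), b2 = c("T", "G"))
  asg2 <- tibble::tibble(sample_id = rownames(m2),
    population = c("A", "A", "B", "B"))
  fit2 <- amova(difference_matrix(m2), asg2, n_perm = 99, seed = 1)
  expect_equal(fit2$phi[["phi_st"]], 1)
})

test_that("pairwise Phi-ST equals a two-population AMOVA and is symmetric", {
  cfg <- sim_config(n_populations = 3, samples_per_pop = 5, seq_length = 1000,
    per_site_mu = 1e-6, Ne = 2000, split_time = 2e4, seed = 17)
  ds <- generate_dataset(cfg)
  d <- difference_matrix(ds$alignment)
  pw <- pairwise_phist(d, ds$samples, n_perm = 99, seed = 3)
  expect_true(isSymmetric(pw$phi))
  expect_true(all(diag(pw$phi) == 0))
  for (pair in list(c("POP01", "POP02"), c("POP02", "POP03"))) {
    ids <- ds$samples$sample_id[ds$samples$population %in% pair]
    sub_asg <- ds$samples[ds$samples$sample_id %in% ids, ]
    full <- amova(d[ids, ids], sub_asg, n_perm = 9, seed = 1)
    expect_equal(pw$phi[pair[1], pair[2]], unname(full$phi["phi_st"]),
      tolerance = 1e-12)
  }
  # populations under the size threshold are excluded
  asg_small <- ds$samples
  asg_small$population[asg_small$sample_id == "POP03_001"] <- "TINY"
  pw2 <- pairwise_phist(d, asg_small, n_perm = 9, seed = 1, min_pop_n = 3)
  expect_true("TINY" %in% pw2$excluded)
  expect_false("TINY" %in% rownames(pw2$phi))
})

test_that("modified FDR critical level follows alpha / sum(1/i)", {
  expect_equal(round(fdr_critical(0.05, 78), 4), 0.0101)
  expect_equal(round(fdr_critical(0.05, 36), 3), 0.012)
  expect_equal(fdr_critical(0.05, 1), 0.05)
  crit <- vapply(1:60, fdr_critical, numeric(1), alpha = 0.05)
  expect_true(all(diff(crit) < 0))
})

test_that("great-circle distances use a 6371 km sphere", {
  expect_equal(great_circle_distance(47, -52, 47, -52), 0)
  expect_equal(great_circle_distance(0, 0, 90, 0), 2 * pi * 6371 / 4,
    tolerance = 1e-6)
  expect_equal(great_circle_distance(47.5, -52.7, 60.4, 5.3),
    great_circle_distance(60.4, 5.3, 47.5, -52.7))
  expect_error(great_circle_distance(95, 0, 0, 0), "coordinates")
  coords <- tibble::tibble(population = c("a", "b", "c"),
    lat = c(47, 54, 60), lon = c(-52, -57, 5))
  gm <- geo_distance_matrix(coords)
  expect_true(isSymmetric(gm))
  expect_equal(diag(gm), rep(0, 3), ignore_attr = TRUE)
})

test_that("Mantel test recovers a perfect linear relationship", {
  set.seed(11)
  phi <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  vals <- runif(15, 0.05, 0.5)
  phi[upper.tri(phi)] <- vals
  phi <- phi + t(phi)
  geo <- 100 * phi / (1 - phi) # exactly proportional to the linearized values
  fit <- mantel_ibd(phi, geo, n_perm = 999, seed = 2)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  expect_lt(fit$p, 0.05)
  expect_equal(fit$r_squared, fit$r^2)
  # constant genetic matrix: undefined correlation
  expect_error(
    mantel_ibd(matrix(0, 6, 6, dimnames = dimnames(phi)), geo, n_perm = 99),
    "degenerate")
  # phi = 1 cells are excluded with a warning
  phi1 <- phi
  phi1[1, 2] <- phi1[2, 1] <- 1
  expect_warning(mantel_ibd(phi1, geo, n_perm = 99, seed = 1), "excluded")
})

test_that("PCoA reproduces exact configurations", {
  # points on a line: first axis carries ~all variance
  x <- seq(0, 10, length.out = 8)
  d <- as.matrix(stats::dist(cbind(x, 0)))
  fit <- pcoa_dist(d, n_axes = 3)
  expect_gt(fit$percent_variance[1], 99.99)
  expect_true(all(diff(fit$percent_variance) <= 1e-8))
  # zero matrix: all coordinates zero
  z <- pcoa_dist(matrix(0, 5, 5), n_axes = 2)
  expect_true(all(as.matrix(z$coordinates[, -1]) == 0))
  # planar configuration recovered up to rotation/reflection
  set.seed(3)
  pts <- matrix(rnorm(20), ncol = 2)
  fitp <- pcoa_dist(as.matrix(stats::dist(pts)), n_axes = 2)
  proc <- vegan::procrustes(pts, as.matrix(fitp$coordinates[, -1]))
  expect_lt(sum(proc$Yrot - proc$X)^2, 1e-8)
  expect_lt(proc$ss, 1e-8)
  expect_error(pcoa_dist(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("contingency chi-square matches hand computation", {
  # independence: X^2 = 0
  tbl <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(contingency_chisq(tbl)$statistic, 0)
  got <- contingency_chisq(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(got$statistic, 20)
  expect_equal(got$df, 1)
  expect_warning(
    res <- contingency_chisq(rbind(c(5, 5), c(0, 0), c(2, 8))), "dropping")
  expect_equal(res$df, 1)
  expect_error(contingency_chisq(matrix(c(1.5, 1, 1, 1), 2, 2)), "integers")
})
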