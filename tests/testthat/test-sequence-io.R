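test_that("FASTA round-trip normalizes case and U->T", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "acgu-", ">s2", "ACGTN"), path)
  aln <- read_alignment(path)
  m <- mitophylogeo:::aln_chars(aln)
  expect_identical(unname(m["s1", ]), c("A", "C", "G", "T", "-"))
  expect_identical(unname(m["s2", ]), c("A", "C", "G", "T", "N"))
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_identical(readLines(out), c(">s1", "ACGT-", ">s2", "ACGTN"))
})

test_that("ragged or duplicated FASTA records are rejected", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), path)
  expect_error(read_alignment(path), "ragged")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), path)
  expect_error(read_alignment(path), "duplicate")
})

test_that("base calling follows the dS/N decision rules", {
  # dS/N = (100 - 10) / 120 = 0.75 on both strands: strong call
  q <- c(100, 10, 5, 5)
  res <- call_base(q, q, reference = "A")
  expect_equal(res$dsn_forward, 0.75)
  expect_identical(res$base, "A")
  expect_identical(res$status, "strong")

  # 0.10 <= dS/N < 0.13 accepted only in agreement with the reference
  weak <- c(30, 19, 26, 25) # dS/N = 4/100... construct exact 0.11
  weak <- c(36.5, 25.5, 19, 19) # (36.5-25.5)/100 = 0.11
  res_ref <- call_base(weak, weak, reference = "A")
  expect_identical(res_ref$status, "weak_ref")
  expect_identical(res_ref$base, "A")
  res_nonref <- call_base(weak, weak, reference = "G")
  expect_identical(res_nonref$status, "ambiguous")
  expect_identical(res_nonref$base, "N")

  # strand disagreement is ambiguous regardless of dS/N
  fwd <- c(100, 5, 5, 5)
  rev <- c(5, 5, 100, 5)
  expect_identical(call_base(fwd, rev, reference = "A")$status, "ambiguous")

  # all-zero intensities are ambiguous, not an error
  expect_identical(call_base(c(0, 0, 0, 0), q, reference = "A")$status, "ambiguous")
  # below 0.10 on one strand is ambiguous even in reference agreement
  low <- c(28, 19, 27, 26) # dS/N = 0.01
  expect_identical(call_base(low, low, reference = "A")$status, "ambiguous")
})

test_that("call_bases flags ambiguous positions for exclusion", {
  tbl <- generate_intensity_table(
    matrix(c("A", "C", "G", "T"), nrow = 1, dimnames = list("s1", NULL)),
    noise_sd = 0)
  calls <- call_bases(tbl)
  expect_identical(calls$base, c("A", "C", "G", "T"))
  expect_true(all(calls$status == "strong"))
  expect_false(any(calls$excluded))
  # inject strand discordance at position 2
  tbl2 <- tbl
  i <- which(tbl2$position == 2 & tbl2$strand == "reverse")
  tbl2[i, c("I_A", "I_C", "I_G", "I_T")] <- list(100, 10, 10, 10)
  calls2 <- call_bases(tbl2)
  expect_true(calls2$excluded[calls2$position == 2])
})

test_that("site classification matches hand counts", {
  m0 <- matrix("A", nrow = 4, ncol = 5)
  expect_true(all(classify_sites(m0)[1, ] == 0))

  m1 <- matrix("A", nrow = 4, ncol = 3)
  m1[, 2] <- c("A", "A", "G", "G") # informative transition
  m1[, 3] <- c("A", "A", "A", "T") # singleton transversion
  got <- classify_sites(m1)
  expect_equal(got$n_variable, 2)
  expect_equal(got$n_parsimony_informative, 1)
  expect_equal(got$n_singleton, 1)
  expect_equal(got$n_transitions, 1)
  expect_equal(got$n_transversions, 1)
})

test_that("site classification equals the per-column oracle on random alignments", {
  for (seed in 1:6) {
    m <- random_alignment(10, 100, seed, p_gap = 0.02, p_amb = 0.01)
    got <- classify_sites(m)
    want <- oracle_classify_sites(m)
    expect_equal(unlist(got[1, ]), want, ignore_attr = TRUE)
    # substitution-site accounting identity
    expect_equal(got$n_variable, got$n_parsimony_informative + got$n_singleton)
  }
})

test_that("haplotype collapsing partitions samples by sequence identity", {
  set.seed(42)
  base <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  m <- matrix(rep(base, 18), nrow = 18, byrow = TRUE,
    dimnames = list(paste0("s", 1:18), NULL))
  # three shared haplotypes of 7, 5 and 2 samples; remaining 4 unique
  m[8:12, 3] <- ifelse(base[3] == "T", "A", "T")
  m[13:14, 7] <- ifelse(base[7] == "G", "A", "G")
  for (k in 15:18) m[k, k] <- ifelse(base[k] == "C", "A", "C")
  ht <- collapse_haplotypes(m)
  expect_equal(ht$n_haplotypes, 7)
  expect_equal(sum(ht$counts$n), 18)
  # partition property: same haplotype iff identical sequences
  key <- apply(m, 1, paste, collapse = "")
  hap <- setNames(ht$assignment$haplotype_id, ht$assignment$sample_id)
  for (i in 1:17) {
    for (j in (i + 1):18) {
      expect_identical(unname(key[i] == key[j]),
        hap[[paste0("s", i)]] == hap[[paste0("s", j)]])
    }
  }
})

test_that("haplotype identity ignores excluded and ambiguous positions", {
  m <- rbind(
    s1 = c("A", "C", "G", "T", "A"),
    s2 = c("A", "C", "G", "T", "G"),
    s3 = c("A", "N", "G", "T", "A")
  )
  # position 5 excluded: s1 == s2; position 2 carries an ambiguity so it is
  # masked for identity, making s3 identical to s1 as well
  ht <- collapse_haplotypes(m, exclude = 5)
  expect_equal(ht$n_haplotypes, 1)
  ht2 <- collapse_haplotypes(m)
  expect_equal(ht2$n_haplotypes, 2)
  expect_true(all(unique(table(ht2$assignment$haplotype_id)) %in% c(1, 2)))
})

test_that("tandem-repeat collapsing removes duplicate units and maps coordinates", {
  unit <- c("A", "C", "G", "T", "A")
  seqv <- c("T", "T", unit, unit, "G", "G")
  m <- matrix(seqv, nrow = 1, dimnames = list("s1", NULL))
  res <- collapse_tandem_repeats(m, data.frame(start = 3, end = 7))
  expect_equal(ncol(res$alignment), length(seqv) - 5)
  expect_equal(res$removed, 8:12)
  # a single-unit sequence is unchanged
  m1 <- matrix(c("T", unit, "G"), nrow = 1, dimnames = list("s1", NULL))
  res1 <- collapse_tandem_repeats(m1, data.frame(start = 2, end = 6))
  expect_equal(ncol(res1$alignment), 7)
  expect_equal(length(res1$removed), 0)
  # coordinate map round-trips positions outside regions
  outside <- c(1, 2, 13, 14)
  for (p in outside) {
    newp <- res$position_map[p]
    expect_false(is.na(newp))
    expect_identical(res$alignment[1, newp], m[1, p])
  }
  expect_error(collapse_tandem_repeats(m, data.frame(start = 10, end = 30)),
    "outside")
})
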