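# Independent oracles used across the suite. Each re-derives the quantity it
# checks by a different route than the package implementation.

# Naive per-column site classification by explicit case analysis.
oracle_classify_sites <- function(m) {
  bases <- c("A", "C", "G", "T")
  purines <- c("A", "G")
  res <- c(n_variable = 0, n_parsimony_informative = 0, n_singleton = 0,
    n_transitions = 0, n_transversions = 0, n_indel_sites = 0, n_multiallelic = 0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(!col %in% c(bases, "-"))) next
    b <- col[col %in% bases]
    if (any(col == "-") && length(b) > 0) res["n_indel_sites"] <- res["n_indel_sites"] + 1
    tab <- table(b)
    if (length(tab) >= 2) {
      res["n_variable"] <- res["n_variable"] + 1
      if (sum(tab >= 2) >= 2) {
        res["n_parsimony_informative"] <- res["n_parsimony_informative"] + 1
      } else {
        res["n_singleton"] <- res["n_singleton"] + 1
      }
      if (length(tab) >= 3) res["n_multiallelic"] <- res["n_multiallelic"] + 1
      st <- names(tab)
      for (a_i in seq_along(st)) {
        for (b_i in seq_along(st)) {
          if (a_i < b_i) {
            same_class <- (st[a_i] %in% purines) == (st[b_i] %in% purines)
            if (same_class) {
              res["n_transitions"] <- res["n_transitions"] + 1
            } else {
              res["n_transversions"] <- res["n_transversions"] + 1
            }
          }
        }
      }
    }
  }
  res
}

# Per-pair difference counting by explicit looping.
oracle_pair_diffs <- function(m) {
  bases <- c("A", "C", "G", "T")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] %in% bases & m[j, ] %in% bases
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
    }
  }
  d
}

# Two-level molecular ANOVA from first principles: explicit pair sums and the
# textbook expected-mean-square coefficients, all by plain loops.
oracle_amova2 <- function(d2, pop) {
  pop <- as.character(pop)
  pops <- unique(pop)
  N <- nrow(d2)
  P <- length(pops)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / N
  ss_within <- 0
  sizes <- numeric(P)
  for (k in seq_len(P)) {
    idx <- which(pop == pops[k])
    sizes[k] <- length(idx)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) {
        for (b in (a + 1):length(idx)) s <- s + d2[idx[a], idx[b]]
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  ss_among <- ss_total - ss_within
  sigma_w <- ss_within / (N - P)
  n_prime <- (N - sum(sizes^2) / N) / (P - 1)
  sigma_a <- (ss_among / (P - 1) - sigma_w) / n_prime
  list(ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
    sigma_a = sigma_a, sigma_w = sigma_w,
    phi_st = sigma_a / (sigma_a + sigma_w))
}

# Unit-cost Sankoff dynamic programming over a (possibly multifurcating)
# tree; exact minimum parsimony length.
oracle_sankoff <- function(tree, tip_states) {
  tip_states <- tip_states[tree$tip.label]
  states <- sort(unique(as.character(tip_states)))
  S <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cost <- matrix(Inf, nnode, S)
  for (i in seq_len(ntip)) cost[i, match(tip_states[i], states)] <- 0
  post <- ape::reorder.phylo(tree, "postorder")$edge
  parents <- rev(unique(rev(post[, 1])))
  kids_of <- split(post[, 2], post[, 1])
  for (p in parents) {
    kids <- kids_of[[as.character(p)]]
    for (s in seq_len(S)) {
      tot <- 0
      for (k in kids) {
        best <- Inf
        for (t in seq_len(S)) {
          v <- cost[k, t] + (s != t)
          if (v < best) best <- v
        }
        tot <- tot + best
      }
      cost[p, s] <- tot
    }
  }
  min(cost[ntip + 1L, ])
}

# Closed-form probability of parsimony under the Jukes-Cantor/Poisson model:
# the conditional single-hit and zero-hit terms evaluated from the analytic
# series sums rather than the truncated recursion.
oracle_parsimony_probability <- function(j, m) {
  if (j == 0) return(1)
  p <- j / m
  if (p >= 0.75) return(0)
  lambda <- -0.75 * log(1 - 4 * p / 3)
  p_diff <- 0.75 * (1 - exp(-4 * lambda / 3)) # = p by construction
  p_same <- 1 - p_diff
  r1 <- lambda * exp(-lambda) * 0.75 * (1 - (-1 / 3)) / p_diff
  s0 <- exp(-lambda) / p_same
  r1^j * s0^(m - j)
}

# Random additive distance matrix from a random tree with strictly positive
# branch lengths; returns both.
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, dist = stats::cophenetic(tr))
}

# Random alignment with optional gaps/ambiguities.
random_alignment <- function(n, L, seed, p_gap = 0, p_amb = 0) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), n * L, replace = TRUE)
  if (p_gap > 0) chars[stats::runif(n * L) < p_gap] <- "-"
  if (p_amb > 0) chars[stats::runif(n * L) < p_amb] <- "N"
  matrix(chars, nrow = n, dimnames = list(paste0("s", seq_len(n)), NULL))
}
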