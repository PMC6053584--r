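# Internal helpers shared across modules.

# Uppercase character matrix view of an alignment. Accepts a DNAbin matrix,
# a DNAbin list of equal-length sequences, or a character matrix.
aln_chars <- function(aln) {
  if (inherits(aln, "DNAbin")) {
    m <- toupper(as.character(as.matrix(aln)))
  } else if (is.matrix(aln) && is.character(aln)) {
    m <- toupper(aln)
  } else {
    stop("`aln` must be a DNAbin object or a character matrix", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

# Positions (columns) retained after removing excluded ones.
keep_positions <- function(n_sites, exclude = NULL) {
  if (is.null(exclude) || length(exclude) == 0L) return(seq_len(n_sites))
  exclude <- as.integer(exclude)
  if (any(exclude < 1L | exclude > n_sites)) {
    stop("excluded positions outside [1, ", n_sites, "]", call. = FALSE)
  }
  setdiff(seq_len(n_sites), exclude)
}

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

# Deterministic child-seed derivation so stages can be rerun in isolation.
# Keeps results inside 32-bit integer range.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# Standard unbiased permutation p-value.
perm_pvalue <- function(n_as_extreme, n_perm) (n_as_extreme + 1) / (n_perm + 1)

# Coerce a sample -> population assignment to a canonical tibble.
as_assignment <- function(assignment) {
  if (is.data.frame(assignment)) {
    stopifnot(all(c("sample_id", "population") %in% names(assignment)))
    out <- tibble::tibble(
      sample_id = as.character(assignment$sample_id),
      population = as.character(assignment$population)
    )
  } else if (!is.null(names(assignment))) {
    out <- tibble::tibble(
      sample_id = names(assignment),
      population = as.character(assignment)
    )
  } else {
    stop("`assignment` must be a data frame (sample_id, population) or a named vector",
      call. = FALSE)
  }
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in assignment", call. = FALSE)
  out
}

# Match a distance matrix to an assignment; returns list(mat, pop factor).
align_dist_assignment <- function(dist, assignment) {
  mat <- as.matrix(dist)
  asg <- as_assignment(assignment)
  ids <- rownames(mat)
  if (is.null(ids)) {
    if (nrow(mat) != nrow(asg)) stop("unnamed distance matrix size mismatch", call. = FALSE)
    ids <- asg$sample_id
    dimnames(mat) <- list(ids, ids)
  }
  missing <- setdiff(ids, asg$sample_id)
  if (length(missing) > 0) {
    stop("samples without population assignment: ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  asg <- asg[match(ids, asg$sample_id), ]
  list(mat = mat, pop = factor(asg$population), ids = ids)
}
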