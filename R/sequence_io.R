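#' Read a FASTA alignment
#'
#' Reads an aligned FASTA file into an [ape::DNAbin] matrix. Sequences are
#' uppercased and `U` is converted to `T`; all records must have equal length
#' and unique identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAbin` matrix (samples x positions).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path, call. = FALSE)
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1L) {
    stop("alignment has ragged sequence lengths (", paste(unique(lens), collapse = ", "),
      ")", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  ape::as.DNAbin(m)
}

#' Write an alignment to FASTA
#'
#' @param aln A `DNAbin` matrix or character matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  m <- aln_chars(aln)
  lines <- character(2L * nrow(m))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(m))
  lines[c(FALSE, TRUE)] <- apply(m, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# dS/N of a four-channel intensity quartet: difference between the two
# highest signals divided by the sum of all four.
dsn_ratio <- function(intensities) {
  s <- sum(intensities)
  if (s <= 0) return(0)
  srt <- sort(intensities, decreasing = TRUE)
  (srt[1] - srt[2]) / s
}

#' Call a base from two-strand microarray intensities
#'
#' The presumptive call on each strand is the channel with the highest signal;
#' confidence is the differential signal-to-noise ratio dS/N = (difference of
#' the two highest intensities) / (sum of all four). Calls agreeing on both
#' strands with dS/N >= `strong` on both are `"strong"`; calls with
#' `weak` <= dS/N < `strong` are accepted only when they equal the reference
#' (`"weak_ref"`); strand disagreement or dS/N < `weak` yields `"ambiguous"`
#' and the position should be excluded downstream.
#'
#' @param forward,reverse Numeric vectors of four intensities, in channel
#'   order A, C, G, T, for the two strands.
#' @param reference Reference base at the position (`"A"`, `"C"`, `"G"`, `"T"`).
#' @param strong,weak dS/N thresholds (defaults 0.13 and 0.10).
#' @return A list with `base` (called base, or `"N"` when ambiguous),
#'   `status` (`"strong"`, `"weak_ref"` or `"ambiguous"`), and the per-strand
#'   dS/N values `dsn_forward`, `dsn_reverse`.
#' @export
call_base <- function(forward, reverse, reference,
                      strong = 0.13, weak = 0.10) {
  stopifnot(length(forward) == 4L, length(reverse) == 4L)
  if (any(forward < 0) || any(reverse < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  fwd_call <- BASES[which.max(forward)]
  rev_call <- BASES[which.max(reverse)]
  dsn_f <- dsn_ratio(forward)
  dsn_r <- dsn_ratio(reverse)
  out <- function(base, status) {
    list(base = base, status = status, dsn_forward = dsn_f, dsn_reverse = dsn_r)
  }
  if (sum(forward) == 0 || sum(reverse) == 0) return(out("N", "ambiguous"))
  if (fwd_call != rev_call) return(out("N", "ambiguous"))
  lo <- min(dsn_f, dsn_r)
  if (lo >= strong) return(out(fwd_call, "strong"))
  if (lo >= weak && identical(fwd_call, reference)) return(out(fwd_call, "weak_ref"))
  out("N", "ambiguous")
}

#' Call bases for a table of intensity quartets
#'
#' Tidy wrapper over [call_base()] for a long intensity table with one row per
#' position per strand.
#'
#' @param intensities A data frame with columns `position`, `strand`
#'   (`"forward"`/`"reverse"`), `I_A`, `I_C`, `I_G`, `I_T`, and `ref`. An
#'   optional `sample_id` column is carried through (calls are made per
#'   sample).
#' @inheritParams call_base
#' @return A tibble with one row per position (per sample): `position`,
#'   `base`, `status`, `dsn_forward`, `dsn_reverse`, `excluded` (TRUE for
#'   ambiguous calls).
#' @export
call_bases <- function(intensities, strong = 0.13, weak = 0.10) {
  req <- c("position", "strand", "I_A", "I_C", "I_G", "I_T", "ref")
  stopifnot(all(req %in% names(intensities)))
  tbl <- tibble::as_tibble(intensities)
  if (!"sample_id" %in% names(tbl)) tbl$sample_id <- "sample1"
  keys <- dplyr::distinct(tbl, .data$sample_id, .data$position)
  res <- purrr::pmap(keys, function(sample_id, position) {
    rows <- tbl[tbl$sample_id == sample_id & tbl$position == position, ]
    fwd <- rows[rows$strand == "forward", ]
    rev <- rows[rows$strand == "reverse", ]
    if (nrow(fwd) != 1L || nrow(rev) != 1L) {
      stop("position ", position, " needs exactly one row per strand", call. = FALSE)
    }
    cb <- call_base(
      as.numeric(fwd[1, c("I_A", "I_C", "I_G", "I_T")]),
      as.numeric(rev[1, c("I_A", "I_C", "I_G", "I_T")]),
      reference = fwd$ref[1], strong = strong, weak = weak
    )
    tibble::tibble(
      sample_id = sample_id, position = position,
      base = cb$base, status = cb$status,
      dsn_forward = cb$dsn_forward, dsn_reverse = cb$dsn_reverse,
      excluded = cb$status == "ambiguous"
    )
  })
  dplyr::bind_rows(res)
}

#' Classify variable sites in an alignment
#'
#' Per-column classification of substitution variation. A site is variable
#' when at least two nucleotide states occur; parsimony informative when at
#' least two states each occur in two or more sequences; otherwise a
#' singleton. Every unordered pair of observed bases at a site is tallied as a
#' transition (A/G, C/T) or transversion, so multiallelic sites contribute
#' several changes but one variable site. Columns containing any ambiguity
#' character are excluded entirely; columns where the only variation is
#' gap-versus-base are counted as indel sites, not substitution sites.
#'
#' @param aln A `DNAbin` or character matrix alignment.
#' @param exclude Optional integer vector of 1-based positions to skip.
#' @return A one-row tibble with counts `n_variable`,
#'   `n_parsimony_informative`, `n_singleton`, `n_transitions`,
#'   `n_transversions`, `n_indel_sites`, `n_multiallelic`.
#' @export
classify_sites <- function(aln, exclude = NULL) {
  m <- aln_chars(aln)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty alignment", call. = FALSE)
  keep <- keep_positions(ncol(m), exclude)
  n_variable <- n_informative <- n_singleton <- 0L
  n_ts <- n_tv <- n_indel <- n_multi <- 0L
  for (j in keep) {
    col <- m[, j]
    if (any(!col %in% c(BASES, "-"))) next # ambiguity: site excluded
    has_gap <- any(col == "-")
    bases <- col[col != "-"]
    if (has_gap && length(bases) > 0L) n_indel <- n_indel + 1L
    if (length(bases) < 2L) next
    tab <- table(bases)
    states <- names(tab)
    if (length(states) < 2L) next
    n_variable <- n_variable + 1L
    if (sum(tab >= 2L) >= 2L) n_informative <- n_informative + 1L else
      n_singleton <- n_singleton + 1L
    if (length(states) >= 3L) n_multi <- n_multi + 1L
    prs <- utils::combn(states, 2L)
    for (k in seq_len(ncol(prs))) {
      if (is_transition(prs[1, k], prs[2, k])) n_ts <- n_ts + 1L else n_tv <- n_tv + 1L
    }
  }
  tibble::tibble(
    n_variable = n_variable,
    n_parsimony_informative = n_informative,
    n_singleton = n_singleton,
    n_transitions = n_ts,
    n_transversions = n_tv,
    n_indel_sites = n_indel,
    n_multiallelic = n_multi
  )
}

#' Collapse identical sequences into haplotypes
#'
#' Two samples share a haplotype iff their sequences are identical over all
#' non-excluded positions (columns containing ambiguity characters are also
#' ignored for identity, mirroring the exclusion of unresolvable positions).
#'
#' @param aln Alignment (`DNAbin` or character matrix).
#' @param assignment Sample to population assignment (data frame with
#'   `sample_id`, `population`, or named vector). Optional; a single
#'   population is assumed when missing.
#' @param exclude Optional positions to ignore.
#' @return An object of class `haplotype_table`: a list with `assignment`
#'   (tibble `sample_id`, `population`, `haplotype_id`), `counts` (tibble
#'   `haplotype_id`, `population`, `n`), `representatives` (named vector of a
#'   representative sample per haplotype), `n_samples` and `n_haplotypes`,
#'   plus the representative sequences in `sequences`.
#' @export
collapse_haplotypes <- function(aln, assignment = NULL, exclude = NULL) {
  m <- aln_chars(aln)
  keep <- keep_positions(ncol(m), exclude)
  sub <- m[, keep, drop = FALSE]
  ambiguous_col <- apply(sub, 2, function(col) any(!col %in% c(BASES, "-")))
  sub <- sub[, !ambiguous_col, drop = FALSE]
  key <- apply(sub, 1, paste, collapse = "")
  first <- !duplicated(key)
  hap_of_key <- stats::setNames(
    paste0("H", formatC(seq_len(sum(first)), width = 3, flag = "0")),
    key[first]
  )
  hap <- unname(hap_of_key[key])
  if (is.null(assignment)) {
    assignment <- tibble::tibble(sample_id = rownames(m), population = "all")
  }
  asg <- as_assignment(assignment)
  asg <- asg[match(rownames(m), asg$sample_id), ]
  if (anyNA(asg$sample_id)) stop("assignment missing some samples", call. = FALSE)
  asg$haplotype_id <- hap
  counts <- dplyr::count(asg, .data$haplotype_id, .data$population, name = "n")
  structure(
    list(
      assignment = tibble::as_tibble(asg),
      counts = counts,
      representatives = stats::setNames(rownames(m)[first], hap[first]),
      sequences = m[first, , drop = FALSE],
      n_samples = nrow(m),
      n_haplotypes = sum(first)
    ),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table:", x$n_haplotypes, "haplotypes among", x$n_samples,
    "samples\n")
  print(x$counts, ...)
  invisible(x)
}

#' Collapse tandem-repeat arrays to a single repeat unit
#'
#' Given 1-based inclusive spans each covering one repeat unit, adjacent
#' blocks of the same width immediately downstream of a span are removed when,
#' in every sequence, the block is identical to that sequence's first unit or
#' is entirely gaps. Coordinates outside the removed blocks are preserved via
#' the returned position map.
#'
#' @param aln Alignment (`DNAbin` or character matrix).
#' @param repeat_regions A data frame with columns `start`, `end` (1-based,
#'   inclusive), one row per repeat region.
#' @return A list with `alignment` (collapsed character-matrix alignment),
#'   `position_map` (integer vector: old position -> new position, `NA` for
#'   removed columns), and `removed` (integer vector of removed old
#'   positions).
#' @export
collapse_tandem_repeats <- function(aln, repeat_regions) {
  m <- aln_chars(aln)
  L <- ncol(m)
  stopifnot(is.data.frame(repeat_regions), all(c("start", "end") %in% names(repeat_regions)))
  drop <- integer(0)
  for (i in seq_len(nrow(repeat_regions))) {
    s <- as.integer(repeat_regions$start[i])
    e <- as.integer(repeat_regions$end[i])
    if (s < 1L || e > L || s > e) {
      stop("repeat region ", s, "-", e, " outside alignment [1, ", L, "]",
        call. = FALSE)
    }
    u <- e - s + 1L
    unit <- m[, s:e, drop = FALSE]
    nxt <- e + 1L
    while (nxt + u - 1L <= L) {
      block <- m[, nxt:(nxt + u - 1L), drop = FALSE]
      same <- vapply(seq_len(nrow(m)), function(r) {
        all(block[r, ] == unit[r, ]) || all(block[r, ] == "-")
      }, logical(1))
      if (!all(same)) break
      drop <- c(drop, nxt:(nxt + u - 1L))
      nxt <- nxt + u
    }
  }
  drop <- sort(unique(drop))
  keep <- setdiff(seq_len(L), drop)
  pos_map <- rep(NA_integer_, L)
  pos_map[keep] <- seq_along(keep)
  list(
    alignment = m[, keep, drop = FALSE],
    position_map = pos_map,
    removed = drop
  )
}
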