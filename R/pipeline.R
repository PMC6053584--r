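#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()]. Either
#' point `fasta`/`populations`/`coordinates` at input files, or set
#' `synthetic` to a [sim_config()] to generate the inputs.
#'
#' @param fasta,populations,coordinates Input paths (FASTA alignment; TSV
#'   with `sample_id`, `population`; TSV with `population`, `lat`, `lon`).
#' @param synthetic Optional [sim_config()]; overrides the input paths.
#' @param out_dir Output directory for the report bundle.
#' @param n_perm_amova,n_perm_pairwise,n_perm_mantel Permutation counts.
#' @param samova_k K values for the SAMOVA scan (`NULL` disables).
#' @param samova_runs,samova_steps SAMOVA annealing effort.
#' @param bootstrap_reps NJ bootstrap replicates (0 disables).
#' @param outgroup Optional outgroup sample id for rooting/dating.
#' @param calibration_age_years Root calibration age (used with `outgroup`).
#' @param genome_length_bp Genome length for clock arithmetic (default: the
#'   alignment length).
#' @param mean_root_distance Mean per-site distance to the calibration point;
#'   when `NULL` and an outgroup is given it is measured from the data.
#' @param network_confidence Statistical-parsimony connection confidence.
#' @param mc_models Named list of [partition_model()]s (`NULL` disables).
#' @param mc_n_rand Randomizations for the Monte Carlo test.
#' @param alpha Family alpha for the pairwise FDR critical level.
#' @param min_pop_n Minimum population size entering pairwise comparisons.
#' @param seed Master seed; per-stage seeds are derived from it and recorded.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, populations = NULL, coordinates = NULL,
                            synthetic = NULL, out_dir = tempfile("mitophylogeo_"),
                            n_perm_amova = 1000, n_perm_pairwise = 500,
                            n_perm_mantel = 10000,
                            samova_k = 2:3, samova_runs = 5, samova_steps = 1000,
                            bootstrap_reps = 100,
                            outgroup = NULL, calibration_age_years = 3.8e6,
                            genome_length_bp = NULL, mean_root_distance = NULL,
                            network_confidence = 0.90,
                            mc_models = NULL, mc_n_rand = 1000,
                            alpha = 0.05, min_pop_n = 3, seed = 1L) {
  if (is.null(synthetic)) {
    if (is.null(fasta) || is.null(populations)) {
      stop("provide `fasta` and `populations` paths, or a `synthetic` sim_config",
        call. = FALSE)
    }
    for (p in c(fasta, populations, coordinates)) {
      if (!is.null(p) && !file.exists(p)) stop("input not found: ", p, call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly to [pipeline_config()] arguments; a
#' `synthetic:` block maps to [sim_config()] and `mc_models:` to named
#' population lists, one per partition.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(sim_config, y$synthetic)
  if (!is.null(y$mc_models)) {
    y$mc_models <- lapply(y$mc_models, function(m) do.call(partition_model, m))
  }
  do.call(pipeline_config, y)
}

#' Run the full phylogeography pipeline
#'
#' Executes every stage on real or synthetic data and writes a diff-able
#' report bundle (TSV + JSON + newick) to `config$out_dir`: site
#' classification, per-population diversity, AMOVA, pairwise Phi-ST with the
#' FDR critical level, Mantel isolation-by-distance, PCoA, SAMOVA per K, the
#' NJ tree with bootstrap and (optionally) clock-dated node ages, the
#' haplotype network, the mismatch distribution with sudden-expansion fit,
#' and the Monte Carlo partition tests. A structured log records per-stage
#' seeds and replicate counts.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @return A list of class `pipeline_result` with every stage's object and
#'   `paths` of the written reports.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_lines <- c(
    paste0("mitophylogeo pipeline ", format(utils::packageVersion("mitophylogeo"))),
    paste0("seed: ", config$seed)
  )
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sim_dir <- file.path(config$out_dir, "synthetic")
    ds <- generate_dataset(config$synthetic, dir = sim_dir)
    aln <- ds$alignment
    asg <- ds$samples
    coords <- ds$coordinates
    note("input: synthetic dataset (generator seed ", config$synthetic$seed, ")")
    paths$synthetic <- ds$paths
  } else {
    aln <- read_alignment(config$fasta)
    asg <- tibble::as_tibble(utils::read.delim(config$populations,
      colClasses = "character"))
    if (!all(c("sample_id", "population") %in% names(asg))) {
      stop("population map needs columns sample_id, population", call. = FALSE)
    }
    coords <- if (!is.null(config$coordinates)) {
      tibble::as_tibble(utils::read.delim(config$coordinates))
    } else {
      NULL
    }
    note("input: ", config$fasta, " (", nrow(as.matrix(aln)), " sequences)")
  }
  ingroup_ids <- setdiff(as_assignment(asg)$sample_id, config$outgroup)
  L_bp <- if (is.null(config$genome_length_bp)) ncol(aln_chars(aln)) else config$genome_length_bp

  # --- site classification & diversity -------------------------------------
  sites <- classify_sites(aln)
  paths$sites <- file.path(config$out_dir, "site_classification.json")
  jsonlite::write_json(as.list(sites), paths$sites, auto_unbox = TRUE, digits = NA)
  div <- diversity_table(aln, asg)
  paths$diversity <- write_tsv_report(div, config$out_dir, "diversity.tsv")
  note("site classification + diversity written")

  haps <- collapse_haplotypes(aln, asg)
  dmat <- difference_matrix(aln)
  dmat_in <- dmat[ingroup_ids, ingroup_ids]
  asg_in <- asg[asg$sample_id %in% ingroup_ids, ]

  # --- AMOVA & pairwise ----------------------------------------------------
  seed_amova <- derive_seed(config$seed, 11L)
  fit_amova <- amova(dmat_in, asg_in, n_perm = config$n_perm_amova, seed = seed_amova)
  paths$amova <- write_tsv_report(tidy(fit_amova), config$out_dir, "amova.tsv")
  note("amova: ", config$n_perm_amova, " permutations, seed ", seed_amova)

  seed_pw <- derive_seed(config$seed, 12L)
  pw <- pairwise_phist(dmat_in, asg_in, n_perm = config$n_perm_pairwise,
    seed = seed_pw, alpha = config$alpha, min_pop_n = config$min_pop_n)
  paths$pairwise <- write_tsv_report(tidy(pw), config$out_dir, "pairwise_phist.tsv")
  note("pairwise phi-st: ", config$n_perm_pairwise, " permutations, seed ", seed_pw,
    ", p_crit = ", signif(pw$p_crit, 3))

  # --- Mantel + PCoA -------------------------------------------------------
  fit_mantel <- NULL
  if (!is.null(coords) && length(unique(asg_in$population)) >= 4) {
    geo <- geo_distance_matrix(coords)
    seed_mantel <- derive_seed(config$seed, 13L)
    fit_mantel <- try(mantel_ibd(pw, geo, n_perm = config$n_perm_mantel,
      seed = seed_mantel), silent = TRUE)
    if (inherits(fit_mantel, "try-error")) {
      note("mantel: skipped (", attr(fit_mantel, "condition")$message, ")")
      fit_mantel <- NULL
    } else {
      paths$mantel <- file.path(config$out_dir, "mantel.json")
      jsonlite::write_json(glance(fit_mantel), paths$mantel,
        auto_unbox = TRUE, digits = NA)
      note("mantel: ", config$n_perm_mantel, " permutations, seed ", seed_mantel)
    }
  }
  fit_pcoa <- pcoa_dist(dmat_in, n_axes = 3)
  paths$pcoa <- write_tsv_report(fit_pcoa$coordinates, config$out_dir, "pcoa.tsv")

  # --- SAMOVA --------------------------------------------------------------
  samova_tbl <- NULL
  if (!is.null(config$samova_k) && !is.null(coords)) {
    seed_sam <- derive_seed(config$seed, 14L)
    samova_tbl <- samova_scan(dmat_in, asg_in, coords,
      k_range = config$samova_k, n_runs = config$samova_runs,
      n_steps = config$samova_steps, n_perm = config$n_perm_pairwise,
      seed = seed_sam)
    flat <- samova_tbl |>
      dplyr::mutate(grouping = purrr::map_chr(.data$grouping, function(g) {
        paste(paste0(g$population, ":", g$group), collapse = ",")
      }))
    paths$samova <- write_tsv_report(flat, config$out_dir, "samova.tsv")
    note("samova: K in {", paste(config$samova_k, collapse = ","), "}, ",
      config$samova_runs, " runs x ", config$samova_steps, " steps, seed ", seed_sam)
  }

  # --- tree, bootstrap, clock ----------------------------------------------
  tree <- nj_tree(dmat)
  if (config$bootstrap_reps > 0) {
    seed_bs <- derive_seed(config$seed, 15L)
    tree <- bootstrap_support(aln, n_reps = config$bootstrap_reps, seed = seed_bs)
    note("bootstrap: ", config$bootstrap_reps, " replicates, seed ", seed_bs)
  }
  dated <- NULL
  if (!is.null(config$outgroup) && config$outgroup %in% tree$tip.label) {
    per_site <- difference_matrix(aln, per_site = TRUE)
    rooted <- root_with_outgroup(nj_tree(per_site), config$outgroup)
    mean_dist <- if (is.null(config$mean_root_distance)) {
      mean(per_site[config$outgroup, setdiff(rownames(per_site), config$outgroup)])
    } else {
      config$mean_root_distance
    }
    clk <- divergence_rate(mean_dist, config$calibration_age_years, L_bp)
    dated <- clock_node_ages(rooted, config$calibration_age_years,
      outgroup = config$outgroup)
    paths$node_ages <- write_tsv_report(dated$ages, config$out_dir, "node_ages.tsv")
    note("clock: divergence rate ", signif(clk$divergence_rate, 3),
      " subs/site/year; ingroup TMRCA ", signif(dated$ingroup_tmrca, 4), " years")
  }
  paths$tree <- file.path(config$out_dir, "nj_tree.nwk")
  ape::write.tree(tree, paths$tree)

  # --- haplotype network ---------------------------------------------------
  lim <- connection_limit(L_bp, config$network_confidence)
  net <- build_network(haps, lim)
  paths$network <- file.path(config$out_dir, "network_edges.tsv")
  write_network(net, edgelist = paths$network,
    graphml = file.path(config$out_dir, "network.graphml"))
  note("network: limit ", lim$max_steps, " steps at ",
    100 * config$network_confidence, "% confidence")

  # --- mismatch & expansion ------------------------------------------------
  mm <- mismatch_distribution(dmat_in)
  fit_exp <- fit_sudden_expansion(mm)
  exp_report <- glance(fit_exp)
  if (!is.null(config$outgroup) && !is.null(dated)) {
    exp_report$t_years <- expansion_time(fit_exp, clk)
  }
  paths$mismatch <- write_tsv_report(mm$histogram, config$out_dir, "mismatch.tsv")
  paths$expansion <- file.path(config$out_dir, "expansion_fit.json")
  jsonlite::write_json(exp_report, paths$expansion, auto_unbox = TRUE, digits = NA)
  note("mismatch: tau_hat = ", signif(fit_exp$tau_hat, 4))

  # --- Monte Carlo tests ---------------------------------------------------
  mc_tbl <- NULL
  if (!is.null(config$mc_models)) {
    seed_mc <- derive_seed(config$seed, 16L)
    mc_tree <- if (length(ingroup_ids) < length(tree$tip.label)) {
      ape::keep.tip(tree, ingroup_ids)
    } else {
      tree
    }
    mc_tbl <- mc_phylogeo_table(mc_tree, asg_in, config$mc_models,
      n_rand = config$mc_n_rand, seed = seed_mc)
    paths$montecarlo <- write_tsv_report(mc_tbl, config$out_dir, "montecarlo.tsv")
    note("monte carlo: ", config$mc_n_rand, " randomizations, seed ", seed_mc)
  }

  paths$log <- file.path(config$out_dir, "pipeline.log")
  writeLines(log_lines, paths$log)
  out <- list(
    sites = sites, diversity = div, haplotypes = haps, amova = fit_amova,
    pairwise = pw, mantel = fit_mantel, pcoa = fit_pcoa, samova = samova_tbl,
    tree = tree, dated = dated, network = net, mismatch = mm,
    expansion = fit_exp, montecarlo = mc_tbl,
    paths = paths, config = config, log = log_lines
  )
  class(out) <- "pipeline_result"
  out
}

write_tsv_report <- function(tbl, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("mitophylogeo pipeline result\n")
  cat(paste0("  ", x$log), sep = "\n")
  invisible(x)
}
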