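# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.amova_fit <- function(x, ...) {
  # variance table with the Phi statistics (and their p-values) appended
  dplyr::bind_rows(
    dplyr::mutate(x$table, p_value = NA_real_),
    tibble::tibble(
      source = paste0("Phi (", names(x$phi), ")"),
      df = NA_integer_, SS = NA_real_,
      sigma2 = unname(x$phi),
      percent = NA_real_,
      p_value = unname(x$p_values[names(x$phi)])
    )
  )
}

#' @export
glance.amova_fit <- function(x, ...) {
  tibble::tibble(
    levels = x$levels,
    phi_st = unname(x$phi["phi_st"]),
    phi_ct = if ("phi_ct" %in% names(x$phi)) unname(x$phi["phi_ct"]) else NA_real_,
    phi_sc = if ("phi_sc" %in% names(x$phi)) unname(x$phi["phi_sc"]) else NA_real_,
    p_phi_st = unname(x$p_values["phi_st"]),
    pct_within = x$table$percent[x$table$source == "within populations"],
    n_perm = x$n_perm, seed = x$seed
  )
}

#' @export
tidy.phist_matrix <- function(x, ...) {
  pops <- rownames(x$phi)
  idx <- which(upper.tri(x$phi), arr.ind = TRUE)
  tibble::tibble(
    pop1 = pops[idx[, 1]], pop2 = pops[idx[, 2]],
    phi_st = x$phi[idx], p_value = x$p[idx],
    significant = x$p[idx] <= x$p_crit
  )
}

#' @export
glance.phist_matrix <- function(x, ...) {
  tibble::tibble(m = x$m, p_crit = x$p_crit, alpha = x$alpha,
    n_significant = sum(x$p[upper.tri(x$p)] <= x$p_crit),
    n_perm = x$n_perm, seed = x$seed)
}

#' @export
glance.mantel_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r_squared, p_value = x$p,
    n_items = x$n_items, n_perm = x$n_perm, seed = x$seed)
}

#' @export
tidy.pcoa_fit <- function(x, ...) x$coordinates

#' @export
glance.pcoa_fit <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$percent_variance),
    percent_variance = x$percent_variance)
}

#' @export
tidy.expansion_fit <- function(x, ...) {
  dplyr::mutate(x$histogram,
    observed = .data$count / sum(.data$count),
    expected = if (x$degenerate) as.numeric(.data$k == 0) else
      expected_mismatch(.data$k, x$tau_hat, x$theta0, x$theta1))
}

#' @export
glance.expansion_fit <- function(x, ...) {
  tibble::tibble(tau_hat = x$tau_hat, theta0 = x$theta0, theta1 = x$theta1,
    ssd = x$ssd, degenerate = x$degenerate)
}

#' @export
tidy.samova_fit <- function(x, ...) x$grouping

#' @export
glance.samova_fit <- function(x, ...) {
  tibble::tibble(K = x$K, phi_ct = x$phi_ct, p_value = x$p_value,
    n_runs = x$n_runs, n_steps = x$n_steps, n_perm = x$n_perm, seed = x$seed)
}

#' @export
tidy.mc_test <- function(x, ...) {
  tibble::tibble(L = as.integer(names(table(x$null_lengths))),
    count = as.integer(table(x$null_lengths)))
}

#' @export
glance.mc_test <- function(x, ...) {
  tibble::tibble(model = if (is.null(x$model_id)) NA_character_ else x$model_id,
    n = x$n_included, L_obs = x$L_obs, C_percent = x$C_percent,
    stars = x$stars, n_rand = x$n_rand, seed = x$seed)
}

#' @export
tidy.haplotype_table <- function(x, ...) x$counts

#' @export
tidy.haplotype_network <- function(x, ...) x$joins

#' Plot a mismatch distribution with its sudden-expansion fit
#'
#' @param object An `expansion_fit` (or `mismatch`) object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expansion_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "firebrick") +
    ggplot2::labs(x = "pairwise differences", y = "relative frequency",
      title = sprintf("Sudden-expansion fit: tau = %.2f", object$tau_hat)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mismatch <- function(object, ...) {
  d <- object$histogram
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "pairwise differences", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot the first two principal coordinates
#'
#' @param object A `pcoa_fit`.
#' @param colour Optional vector (or named vector by item) used to colour
#'   points, e.g. population labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_fit <- function(object, colour = NULL, ...) {
  d <- object$coordinates
  if (!is.null(colour)) {
    d$group <- if (!is.null(names(colour))) colour[d$item] else colour
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", object$percent_variance[1]),
      y = sprintf("Axis 2 (%.1f%%)", object$percent_variance[2])) +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Plot a pairwise Phi-ST matrix as a heat map
#'
#' @param object A `phist_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phist_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pop1, y = .data$pop2,
    fill = .data$phi_st)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", "")), size = 5) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Phi-ST") +
    ggplot2::theme_minimal()
}
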