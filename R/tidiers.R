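#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_point geom_col geom_hline geom_errorbar labs facet_wrap
#'   theme_minimal coord_flip geom_abline
#' @export
ggplot2::autoplot

#' Tidy a PLS fit into a long loading table
#'
#' @param x a `pls_fit`.
#' @param matrix which quantity to return: `"x_loadings"` (default),
#'   `"x_weights"`, `"y_loadings"`, or `"beta"`.
#' @param ... unused.
#' @return tibble in long format: term, component (or outcome for beta),
#'   value.
#' @export
tidy.pls_fit <- function(x, matrix = c("x_loadings", "x_weights",
                                       "y_loadings", "beta"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  out <- tibble::as_tibble(m, rownames = "term")
  tidyr::pivot_longer(out, -"term",
                      names_to = if (matrix == "beta") "outcome" else "component",
                      values_to = "value")
}

#' One-row summary of a PLS fit
#' @param x a `pls_fit`.
#' @param ... unused.
#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n = unname(x$dims["n"]), p = unname(x$dims["p"]), q = unname(x$dims["q"]),
    variance_explained_y = x$total_variance_explained)
}

#' @export
tidy.pls_permutation <- function(x, ...) {
  tibble::tibble(statistic = x$null_distribution)
}

#' @export
glance.pls_permutation <- function(x, ...) {
  tibble::tibble(observed = x$observed_statistic, p.value = x$p_value,
                 n_perm = x$n_perm)
}

#' @export
tidy.pls_bootstrap <- function(x, ...) {
  z <- tibble::as_tibble(x$z_ratio, rownames = "term")
  out <- tidyr::pivot_longer(z, -"term", names_to = "component",
                             values_to = "z_ratio")
  dplyr::mutate(out, significant = abs(.data$z_ratio) > x$z_threshold)
}

#' @export
tidy.harmonization_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    return(tibble::tibble(site = x$sites, mean_location = 0, mean_scale = 1))
  }
  tibble::tibble(
    site = x$sites,
    n = x$site_n,
    mean_location = rowMeans(x$gamma_star),
    mean_scale = rowMeans(sqrt(x$delta_star)))
}

#' @export
tidy.loso_result <- function(x, ...) x$by_site

#' @export
glance.loso_result <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$by_site),
                 mean_r = mean(x$by_site$r, na.rm = TRUE),
                 min_r = min(x$by_site$r, na.rm = TRUE),
                 max_r = max(x$by_site$r, na.rm = TRUE))
}

#' @export
tidy.prediction_run <- function(x, ...) x$stability

#' @export
glance.prediction_run <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter, mean_auc = x$mean_auc,
                 auc_lo = x$auc_interval[1], auc_hi = x$auc_interval[2])
}

#' Permutation-null histogram with the observed statistic
#' @param object a `pls_permutation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pls_permutation <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$statistic)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed_statistic, colour = "red") +
    labs(x = "Y-variance explained under permutation", y = "count",
         title = sprintf("Permutation test: p = %.4g (n = %d)",
                         object$p_value, object$n_perm)) +
    theme_minimal()
}

#' Bootstrap-ratio plot per component
#' @param object a `pls_bootstrap`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pls_bootstrap <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$term, y = .data$z_ratio,
                           colour = .data$significant)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = c(-1, 1) * object$z_threshold, linetype = 2) +
    facet_wrap(~component) +
    labs(x = NULL, y = "bootstrap ratio (Z)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Held-out AUC distribution across iterations
#' @param object a `prediction_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.prediction_run <- function(object, ...) {
  ggplot(object$iterations, aes(x = .data$holdout_auc)) +
    geom_histogram(bins = 20, fill = "steelblue", colour = "grey30") +
    geom_vline(xintercept = object$mean_auc, colour = "red") +
    labs(x = "held-out AUC", y = "iterations",
         title = sprintf("mean AUC = %.3f", object$mean_auc)) +
    theme_minimal()
}

#' Per-site held-out correlation plot
#' @param object a `loso_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.loso_result <- function(object, ...) {
  ggplot(object$by_site, aes(x = .data$site, y = .data$r)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0) +
    labs(x = "held-out site", y = "predicted vs observed composite r") +
    theme_minimal()
}

#' Stability-frequency plot for an elastic-net run
#' @param run a `prediction_run`.
#' @param threshold stability threshold line (default 0.95).
#' @param top_n show the `top_n` most stable features.
#' @return a ggplot.
#' @export
plot_stability <- function(run, threshold = 0.95, top_n = 30) {
  stopifnot(inherits(run, "prediction_run"))
  d <- head(run$stability, top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot(d, aes(x = .data$feature, y = .data$frequency)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    coord_flip() +
    labs(x = NULL, y = "selection frequency") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
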