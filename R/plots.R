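#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile geom_text
#'   geom_pointrange geom_line labs scale_fill_gradient coord_flip theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a model posterior as a bar chart
#'
#' @param object a `model_posterior`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.model_posterior <- function(object, ...) {
  ggplot(object, aes(x = .data$model, y = .data$posterior)) +
    geom_col(fill = "steelblue") +
    labs(x = "model", y = "posterior probability",
         title = "ABC model posterior") +
    theme_minimal()
}

#' Plot an ABC confusion matrix as a heat map
#'
#' @param object an `abc_confusion`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.abc_confusion <- function(object, ...) {
  df <- tidy.abc_confusion(object)
  ggplot(df, aes(x = .data$assigned, y = .data$true, fill = .data$proportion)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$proportion)), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = "assigned model", y = "generating model",
         title = "Model-choice confusion matrix (hard assignment)") +
    theme_minimal()
}

#' Plot D statistics as points with jackknife intervals
#'
#' @param object a `dstat_result` (rows may be stacked with
#'   `dplyr::bind_rows()`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dstat_result <- function(object, ...) {
  df <- dplyr::mutate(object,
                      quad = paste0("(", .data$W, ",", .data$X, ";",
                                    .data$Y, ",", .data$Z, ")"))
  ggplot(df, aes(x = .data$quad, y = .data$D,
                 ymin = .data$D - 2 * .data$SE, ymax = .data$D + 2 * .data$SE)) +
    geom_pointrange() +
    coord_flip() +
    labs(x = NULL, y = "D (+/- 2 SE)", title = "Patterson's D") +
    theme_minimal()
}

#' Plot posterior densities of adjusted parameters
#'
#' @param object a `parameter_posterior`.
#' @param parameters optional subset of parameter names.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.parameter_posterior <- function(object, parameters = NULL, ...) {
  df <- tidyr::pivot_longer(object$samples, dplyr::everything(),
                            names_to = "parameter", values_to = "value")
  if (!is.null(parameters)) df <- dplyr::filter(df, .data$parameter %in% parameters)
  df$weight <- rep(object$weights, each = ncol(object$samples))[seq_len(nrow(df))]
  ggplot(df, aes(x = .data$value, weight = .data$weight)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    labs(x = NULL, y = "posterior density") +
    theme_minimal()
}

#' Marginal SFS bar plot for one population
#'
#' @param sfs a `joint_sfs`.
#' @param pop population code to marginalize onto.
#' @return a ggplot.
#' @export
plot_sfs_marginal <- function(sfs, pop) {
  m <- marginalize_sfs(sfs, pop)
  df <- tibble::tibble(derived = seq_along(as.vector(m$counts)) - 1,
                       count = as.vector(m$counts))
  ggplot(df, aes(x = factor(.data$derived), y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(x = paste0("derived-allele count (", pop, ")"), y = "SNPs") +
    theme_minimal()
}
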