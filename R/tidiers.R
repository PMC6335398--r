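#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training log of a summary network
#'
#' @param x a `summary_net`.
#' @param ... unused.
#' @return tibble with one row per epoch (`epoch`, `train_loss`, `val_loss`).
#' @export
tidy.summary_net <- function(x, ...) x$log

#' One-row summary of a trained network
#'
#' @param x a `summary_net`.
#' @param ... unused.
#' @return tibble with the architecture, epochs trained and held-out metric.
#' @export
glance.summary_net <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      head = x$head,
      n_input = nrow(x$weights$W1),
      hidden1 = x$hidden[1], hidden2 = x$hidden[2],
      n_output = ncol(x$weights$W3),
      epochs = if (nrow(x$log)) max(x$log$epoch) else 0L,
      best_val_loss = if (nrow(x$log)) min(x$log$val_loss) else NA_real_
    ),
    tibble::as_tibble(as.list(x$metric))
  )
}

#' Tidy an adjusted parameter posterior
#'
#' @param x a `parameter_posterior`.
#' @param ... passed to [posterior_summary()] (e.g. `level`).
#' @return tibble with `parameter`, `mean`, `ci_lower`, `ci_upper`.
#' @export
tidy.parameter_posterior <- function(x, ...) posterior_summary(x, ...)

#' Tidy an ABC confusion matrix
#'
#' @param x an `abc_confusion`.
#' @param ... unused.
#' @return tibble with `true`, `assigned`, `proportion` and per-row
#'   `mean_true_posterior`.
#' @export
tidy.abc_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$confusion,
                                        responseName = "proportion")) |>
    dplyr::mutate(mean_true_posterior = x$mean_true_posterior[.data$true])
}
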