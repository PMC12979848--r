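#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evolution trajectory
#'
#' One row per output time with the scalar diagnostics of the state: trace,
#' purity, l1 coherence and smallest eigenvalue.
#'
#' @param x a [evolve()] result.
#' @param ... unused.
#' @return A tibble with columns `time`, `trace`, `purity`, `coherence`,
#'   `min_eigenvalue`.
#' @export
tidy.qpin_evolution <- function(x, ...) {
  tibble::tibble(
    time = x$times,
    trace = vapply(x$states, function(s) Re(sum(diag(s$matrix))), numeric(1)),
    purity = vapply(x$states, purity, numeric(1)),
    coherence = vapply(x$states, l1_coherence, numeric(1)),
    min_eigenvalue = vapply(
      x$states,
      function(s) min(herm_eigenvalues(s$matrix)), numeric(1)
    )
  )
}

#' @rdname tidy.qpin_evolution
#' @export
glance.qpin_evolution <- function(x, ...) {
  tibble::tibble(
    n_times = length(x$times), t_max = max(x$times),
    dim = x$space$total_dim, method = x$method,
    trace_drift = x$trace_drift, min_eigenvalue = x$min_eigenvalue
  )
}

#' @rdname tidy.qpin_evolution
#' @param object a [evolve()] result.
#' @export
autoplot.qpin_evolution <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("purity", "coherence"),
      names_to = "quantity", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$value,
    colour = .data$quantity
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time", y = NULL,
      title = "Open-system trajectory diagnostics"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a variational fit
#'
#' `tidy()` returns one row per parameter; `glance()` a one-row model
#' summary; `autoplot()` the loss-component trace.
#'
#' @param x,object a [train_vqe()] fit.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.vqe_fit <- function(x, ...) {
  tibble::tibble(parameter = seq_along(x$theta), value = x$theta)
}

#' @rdname tidy.vqe_fit
#' @export
glance.vqe_fit <- function(x, ...) {
  tibble::tibble(
    n_params = length(x$theta), iterations = nrow(x$trace),
    energy = x$energy, total_loss = x$loss$total,
    coherence = x$loss$coherence, sparsity = x$loss$sparsity
  )
}

#' @rdname tidy.vqe_fit
#' @export
autoplot.vqe_fit <- function(object, ...) {
  df <- object$trace |>
    tidyr::pivot_longer(-"iter", names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$iter, y = .data$value,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "iteration", y = "loss",
      title = "Variational training trace"
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve plot for labeled predictions
#'
#' @param predictions tibble from [score_all_pairs()] with an added 0/1
#'   `label` column (or any data frame with `p_interaction` and `label`).
#' @return A ggplot.
#' @export
plot_roc <- function(predictions) {
  stopifnot(all(c("p_interaction", "label") %in% names(predictions)))
  curve <- roc_curve(predictions$p_interaction, predictions$label)
  auc <- roc_auc(predictions$p_interaction, predictions$label)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = "Interaction prediction ROC",
      subtitle = sprintf("AUC = %.3f", auc)
    ) +
    ggplot2::theme_minimal()
}
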