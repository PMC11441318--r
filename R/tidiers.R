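#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pre-trained model into its per-step training log
#'
#' @param x An `mtdp_model`.
#' @param ... Unused.
#' @return The per-step training log as a tibble (`step`, `epoch`, `lr`,
#'   `l_mlm`, `l_distill`, `l_total`, and policy columns when present).
#' @method tidy mtdp_model
#' @export
tidy.mtdp_model <- function(x, ...) tibble::as_tibble(x$log)

#' One-row summary of a pre-trained model
#'
#' @param x An `mtdp_model`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs, steps, final losses.
#' @method glance mtdp_model
#' @export
glance.mtdp_model <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(
    n_parameters = count_parameters(x$student_config),
    num_layers = x$student_config$num_layers,
    hidden_dim = x$student_config$hidden_dim,
    epochs = x$epochs_done, steps = x$steps_done,
    l_mlm = last$l_mlm, l_distill = last$l_distill, l_total = last$l_total)
}

#' Tidy cross-validation results
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return The per-fold tibble (`fold`, `metric`, `value`, `n_test`).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("fold", "metric", "value", "n_test")])
}

#' Summarize cross-validation results
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A one-row tibble: metric name, fold count, mean, sd, min, max.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(metric = x$metric[1], k = nrow(x),
                 mean = mean(x$value), sd = stats::sd(x$value),
                 min = min(x$value), max = max(x$value))
}

#' One-row summary of a fitted head
#'
#' @param x An `mlp_head`.
#' @param ... Unused.
#' @return A one-row tibble: task kind, hidden width, epochs trained, final
#'   training loss.
#' @method glance mlp_head
#' @export
glance.mlp_head <- function(x, ...) {
  tibble::tibble(task_kind = x$task_kind, hidden = x$hidden,
                 epochs = x$epochs, train_loss = x$train_loss)
}

#' Training-curve plot for a pre-trained model
#'
#' Loss components against optimizer step; when the adaptive policy was
#' active, a second panel shows the evolving mean teacher weights.
#'
#' @param object An `mtdp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtdp_model
#' @export
autoplot.mtdp_model <- function(object, ...) {
  log <- object$log
  long <- tidyr::pivot_longer(
    log[c("step", "l_mlm", "l_distill", "l_total")],
    cols = -"step", names_to = "loss", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "optimizer step", y = "loss",
                  title = "Distillation pre-training") +
    ggplot2::theme_minimal()
}

#' Box plot of per-fold cross-validation metrics
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = df$metric[1],
                  title = sprintf("%d-fold cross-validation", max(df$fold))) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
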