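#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

#' Tidy a design result
#'
#' Returns the per-update trajectory as a tibble: one row per run and update
#' with the train loss, the test loss at logging points, and the mean entropy
#' parameter gamma (fast methods).
#'
#' @param x an `fsp_design_result`.
#' @param ... unused.
#' @return A tibble with columns `run`, `step`, `train_loss`, `test_loss`,
#'   `gamma_mean`, `gamma_grad_mean`.
#' @method tidy fsp_design_result
#' @export
tidy.fsp_design_result <- function(x, ...) {
  tibble::as_tibble(x$trajectory)
}

#' Summarize a design result
#'
#' One row per design: method, runs, updates, the final train loss averaged
#' over runs, the final K x S test loss, and the best argmax-sequence score.
#'
#' @param x an `fsp_design_result`.
#' @param oracle optionally, the oracle to score argmax sequences with
#'   (defaults to reporting `NA` for the best score if absent).
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance fsp_design_result
#' @export
glance.fsp_design_result <- function(x, oracle = NULL, ...) {
  tr <- x$trajectory
  last <- tr[tr$step == max(tr$step), ]
  best <- NA_real_
  if (!is.null(oracle)) {
    best <- max(vapply(x$runs, function(r) oracle$predict(r$argmax_sequence),
                       numeric(1)))
  }
  tibble::tibble(
    method = x$config$method,
    runs = x$config$runs,
    updates = x$config$updates,
    mean_final_train_loss = mean(last$train_loss),
    final_test_loss = x$final_test_loss,
    best_argmax_score = best
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot design loss trajectories
#'
#' Train-loss trajectories per run (thin lines) with test-loss logging points
#' overlaid.
#'
#' @param object an `fsp_design_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fsp_design_result
#' @export
autoplot.fsp_design_result <- function(object, ...) {
  tr <- tibble::as_tibble(object$trajectory)
  te <- tr[!is.na(tr$test_loss), ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$train_loss,
                                   group = .data$run)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_point(data = te,
                        ggplot2::aes(y = .data$test_loss, colour = "test loss"),
                        size = 0.8) +
    ggplot2::labs(x = "update", y = "loss",
                  title = sprintf("%s on %s", object$config$method,
                                  object$oracle_name),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a PSSM as a per-position probability profile
#'
#' A tile heatmap of the position probability matrix (positions by channels).
#' Sequence-logo rendering is left to downstream tools.
#'
#' @param pssm an N x M row-stochastic matrix.
#' @param alph an [alphabet()].
#' @return A ggplot object.
#' @export
plot_pssm <- function(pssm, alph) {
  df <- tibble::tibble(
    position = rep(seq_len(nrow(pssm)), times = ncol(pssm)),
    symbol = rep(unclass(alph), each = nrow(pssm)),
    probability = as.numeric(pssm)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$symbol,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
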