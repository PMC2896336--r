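#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree plot of variable-importance scores
#'
#' Scores against rank for the top `k` SNPs, with a vertical line at the
#' elbow cutoff (see [elbow_cutoff()]).
#'
#' @param object A `snp_vi` tibble.
#' @param k Number of top-ranked SNPs shown.
#' @param mark_elbow Draw the elbow/default cutoff line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snp_vi
#' @export
autoplot.snp_vi <- function(object, k = 100, mark_elbow = TRUE, ...) {
  top <- object[order(object$rank), ][seq_len(min(k, nrow(object))), ]
  p <- ggplot2::ggplot(top, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "VI rank", y = "permutation importance",
                  title = "Variable-importance scree plot")
  if (mark_elbow && nrow(top) >= 3) {
    cut <- elbow_cutoff(top$score)
    p <- p + ggplot2::geom_vline(xintercept = cut, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Out-of-bag error trajectory of a forest
#'
#' @param object A `snp_forest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snp_forest
#' @export
autoplot.snp_forest <- function(object, ...) {
  df <- tibble::tibble(tree = seq_len(object$ntree),
                       oob_error = object$oob_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tree, y = .data$oob_error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trees grown", y = "OOB error (balanced)",
                  title = sprintf("OOB error trajectory (mtry = %d)",
                                  object$mtry))
}

#' OOB trajectories across tuned mtry candidates
#'
#' @param object An `snp_tuning`.
#' @param ... Unused.
#' @return A ggplot object, one line per candidate.
#' @method autoplot snp_tuning
#' @export
autoplot.snp_tuning <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$trajectories), function(m) {
    tibble::tibble(mtry = m, tree = seq_along(object$trajectories[[m]]),
                   oob_error = object$trajectories[[m]])
  }))
  df$mtry <- factor(df$mtry, levels = names(object$trajectories))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tree, y = .data$oob_error,
                                   colour = .data$mtry)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trees grown", y = "OOB error (balanced)",
                  colour = "mtry",
                  title = "Error-rate convergence across mtry")
}

#' OOB error across sparsity-pruning iterations
#'
#' @param object A `prune_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prune_trace
#' @export
autoplot.prune_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$oob_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$final), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "pruning iteration", y = "OOB error (balanced)",
                  title = "Sparsity-pruning trace")
}

#' @importFrom rlang .data
NULL
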