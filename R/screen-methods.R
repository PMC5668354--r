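#' Tidiers for screen hit calls
#'
#' [tidy()] returns the per-gene hit table (or the per-round summaries with
#' `per_round = TRUE`); [glance()] a one-row screen summary.
#'
#' @param x A `screen_hits` object from [call_hits()].
#' @param per_round Return the gene x round summary table instead.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.screen_hits <- function(x, per_round = FALSE, ...) {
  if (per_round) {
    return(as_tibble(attr(x, "rounds")))
  }
  out <- x
  attributes(out)[c("rounds", "thresholds")] <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  as_tibble(out)
}

#' @rdname tidy.screen_hits
#' @export
glance.screen_hits <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(n_genes = nrow(x),
         n_hits = sum(x$is_primary_hit),
         n_down = sum(x$is_primary_hit & x$direction == "down", na.rm = TRUE),
         n_up = sum(x$is_primary_hit & x$direction == "up", na.rm = TRUE),
         n_ambiguous = sum(x$ambiguous),
         alpha = th$alpha,
         effect_gate = th$effect_gate_force,
         min_cells = th$min_cells,
         success_threshold = th$success_threshold)
}

#' @export
print.screen_hits <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<screen_hits> %d genes; %d primary hits (%d down, %d up)\n",
              g$n_genes, g$n_hits, g$n_down, g$n_up))
  print(tidy(x), ...)
  invisible(x)
}

#' Ranked relative-force overview of a screen
#'
#' Genes ordered by their mean relative equilibrium rounding force, hits
#' highlighted, with the control level and the effect gates drawn as
#' reference lines — the classic ranked-overview figure of an RNAi
#' mechanophenotyping screen.
#'
#' @param object A `screen_hits` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_hits <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- dplyr::arrange(tidy(object), .data$mean_relative)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mean_relative)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "blue") +
    ggplot2::geom_hline(yintercept = c(1 - th$effect_gate_force,
                                       1 + th$effect_gate_force),
                        linetype = "dotted", colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_primary_hit),
                        size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey40"),
                                 name = "primary hit") +
    ggplot2::labs(x = "genes ranked by relative force",
                  y = "relative equilibrium rounding force") +
    ggplot2::theme_minimal()
}

#' Plot a force trace
#'
#' Time course of the rounding force with annotated mitotic events (vertical
#' lines) and, optionally, the extracted equilibrium force.
#'
#' @param object A [force_trace()].
#' @param equilibrium Optional result of [extract_equilibrium_force()] to draw
#'   as a horizontal dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_trace <- function(object, equilibrium = NULL, ...) {
  df <- tibble(t_s = object$t_s, F_nN = object$F_N * 1e9)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$F_nN)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "rounding force (nN)") +
    ggplot2::theme_minimal()
  ann <- attr(object, "annotations")
  if (!is.null(ann)) {
    p <- p + ggplot2::geom_vline(xintercept = unname(ann),
                                 linetype = "dotted", colour = "grey30") +
      ggplot2::annotate("text", x = unname(ann), y = max(df$F_nN),
                        label = names(ann), angle = 90, vjust = -0.3,
                        size = 2.8, colour = "grey30")
  }
  if (!is.null(equilibrium)) {
    p <- p + ggplot2::geom_hline(yintercept = equilibrium$F_eq_N * 1e9,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @rdname autoplot.force_trace
#' @param trace A [force_trace()].
#' @export
plot_force_trace <- function(trace, equilibrium = NULL) {
  autoplot.force_trace(trace, equilibrium = equilibrium)
}
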