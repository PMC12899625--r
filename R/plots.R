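#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a nearest-neighbor step profile
#'
#' Column plot of the per-step stack free energy along the duplex core, with
#' the energy-valley window shaded. Less negative columns mark locally
#' unstable steps.
#'
#' @param object A `thermo_profile`.
#' @param valley_window Positional window to shade (default `9:14`;
#'   `NULL` to omit).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.thermo_profile <- function(object, valley_window = 9:14, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$dg))
  if (!is.null(valley_window)) {
    steps <- seq(min(valley_window), max(valley_window) - 1L)
    p <- p + ggplot2::annotate("rect", xmin = min(steps) - 0.5,
                               xmax = max(steps) + 0.5,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "orange")
  }
  p + ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = sprintf("dinucleotide step (%s strand core)",
                              attr(object, "strand")),
                  y = expression(Delta * G[37] ~ "(kcal/mol)"),
                  title = sprintf("Step profile, total %.2f kcal/mol",
                                  attr(object, "total_dg"))) +
    ggplot2::theme_minimal()
}

#' Plot a scorecard
#'
#' Horizontal bars of points awarded per criterion; unevaluated criteria are
#' greyed out.
#'
#' @param object A `sirna_scorecard`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sirna_scorecard <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$criterion <- factor(df$criterion, levels = rev(df$criterion))
  df$status <- dplyr::case_when(!df$evaluated ~ "not evaluated",
                                df$passed ~ "passed",
                                TRUE ~ "failed")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$criterion,
                                   fill = .data$status)) +
    ggplot2::geom_col(alpha = 0.9) +
    ggplot2::scale_fill_manual(values = c(passed = "forestgreen",
                                          failed = "firebrick",
                                          `not evaluated` = "grey70")) +
    ggplot2::labs(x = "criterion weight (points)", y = NULL,
                  title = sprintf("Score %d / %d (selectable: %s)",
                                  attr(object, "total"),
                                  attr(object, "max_points"),
                                  attr(object, "selectable"))) +
    ggplot2::theme_minimal()
}

#' Plot a fold result as an arc diagram
#'
#' Base pairs of the MFE structure drawn as arcs over the sequence axis;
#' target-site positions can be highlighted to visualise accessibility.
#'
#' @param object A `fold_result`.
#' @param site Optional integer positions (window coordinates) to highlight.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fold_result <- function(object, site = NULL, ...) {
  pairs <- fold_pairs(object)
  n <- nchar(object$seq)
  base <- tibble::tibble(pos = seq_len(n), paired = object$paired)
  p <- ggplot2::ggplot(base, ggplot2::aes(x = .data$pos, y = 0))
  if (!is.null(site)) {
    p <- p + ggplot2::annotate("rect", xmin = min(site) - 0.5,
                               xmax = max(site) + 0.5, ymin = -0.08,
                               ymax = 0.08, fill = "orange", alpha = 0.3)
  }
  if (nrow(pairs) > 0) {
    p <- p + ggplot2::geom_curve(
      data = pairs,
      ggplot2::aes(x = .data$i, xend = .data$j, y = 0, yend = 0),
      curvature = -0.5, linewidth = 0.3, colour = "steelblue")
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = .data$paired), size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "window position", y = NULL,
                  title = sprintf("MFE %.2f kcal/mol", object$mfe)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Score distribution of a candidate table
#'
#' Histogram of total scores with the selection threshold marked.
#'
#' @param scored Tibble from [score_candidates()] or [design_pipeline()].
#' @param threshold Selection threshold (default from the table's
#'   attributes, falling back to 10).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scored, threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- attr(scored, "selection_threshold") %||% 10
  }
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$score_total)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = threshold + 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "total score", y = "candidates") +
    ggplot2::theme_minimal()
}
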