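#' Plot a confusion matrix as a heat map
#'
#' Tiles the (optionally row-normalized) confusion matrix with the true
#' class on the y axis, mirroring how per-joint 3x3 and fused 27x27
#' matrices are usually displayed.
#'
#' @param object `emg_confusion` matrix.
#' @param normalize Row-normalize before plotting (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_confusion <- function(object, normalize = TRUE, ...) {
  m <- if (normalize) suppressWarnings(normalize_confusion(object)) else as.matrix(object)
  df <- tibble::as_tibble(as.table(as.matrix(m)), .name_repair = "minimal")
  names(df) <- c("true", "predicted", "value")
  lev <- rownames(m)
  df$true <- factor(df$true, levels = rev(lev))
  df$predicted <- factor(df$predicted, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "#2166ac",
      name = if (normalize) "proportion" else "count"
    ) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot real-time protocol results
#'
#' Motion completion rate per class, colored by the class's DoF count,
#' with the overall MCR as a dashed reference line.
#'
#' @param object `emg_rt` tibble from [run_realtime_protocol()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_rt <- function(object, ...) {
  per_class <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$class, .data$dof),
    mcr = 100 * mean(.data$completed), .groups = "drop"
  )
  per_class$class <- factor(per_class$class, levels = motion_classes()$code)
  ggplot2::ggplot(per_class, ggplot2::aes(x = .data$class, y = .data$mcr,
                                          fill = factor(.data$dof))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = motion_completion_rate(object),
                        linetype = "dashed") +
    ggplot2::labs(x = "motion class", y = "motion completion rate (%)",
                  fill = "DoF") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
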