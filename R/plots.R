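#' Plot condition-average time courses
#'
#' Mean +/- SEM BOLD time course per region and condition, the standard
#' display for trial-averaged responses.
#'
#' @param object A `timecourse_summary` from [condition_average()].
#' @param ... Unused.
#' @return A ggplot object (one facet per region).
#' @export
autoplot.timecourse_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$offset_s, y = .data$mean,
                               colour = .data$condition, fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~region_id, scales = "free_y") +
    ggplot2::labs(x = "time from stimulus onset (s)", y = "BOLD signal (a.u.)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot region-wise paired permutation results
#'
#' Mean paired difference per region with the FWE-significant regions
#' highlighted.
#'
#' @param object A `paired_perm` from [paired_signflip()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paired_perm <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- tibble::as_tibble(object)
  df$significant <- df$p_fwe <= alpha
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$region_id),
                                   y = .data$mean_diff,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70")) +
    ggplot2::labs(x = "region", y = "mean paired difference (a.u.)",
                  fill = sprintf("p[FWE] <= %.2g", alpha)) +
    ggplot2::theme_minimal()
}
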