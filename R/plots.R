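#' Plot predicted BMI trajectories
#'
#' The population fixed curve (thick line) with a sample of subject-level
#' curves (fixed + BLUP), on the BMI scale.
#'
#' @param fit A converged [fit_lmm()] object.
#' @param table The modelling tibble.
#' @param n_subjects Number of subject curves to draw (default 20).
#' @param range,step Prediction grid, as in [predict_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(fit, table, n_subjects = 20,
                              range = c(2 / 52, 17), step = 0.01) {
  b <- blups(fit, table)
  take <- b[seq_len(min(n_subjects, nrow(b))), ]
  curves <- purrr::map_dfr(seq_len(nrow(take)), function(k) {
    tr <- predict_trajectory(fit, take[k, ], range = range, step = step)
    tr$iid <- take$iid[k]
    tr
  })
  pop <- predict_trajectory(fit, NULL, range = range, step = step)
  ggplot2::ggplot(curves, ggplot2::aes(.data$age, exp(.data$log_bmi),
                                       group = .data$iid)) +
    ggplot2::geom_line(alpha = 0.3, colour = "grey40") +
    ggplot2::geom_line(data = pop, ggplot2::aes(group = NULL),
                       linewidth = 1.2, colour = "#2166AC") +
    ggplot2::labs(x = "Age (years)", y = expression(BMI ~ (kg / m^2)),
                  title = "Predicted BMI trajectories") +
    ggplot2::theme_minimal()
}

#' Manhattan plot of meta-analysis results
#'
#' Basic Manhattan: -log10(p) by position, chromosomes alternating shade,
#' with the genome-wide significance line at 5e-8.
#'
#' @param meta Meta-analysis tibble (from [ivw_meta()] or
#'   [post_meta_filters()]`$kept`).
#' @param p_threshold Significance line (default 5e-8).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(meta, p_threshold = 5e-8) {
  x <- meta[order(suppressWarnings(as.numeric(meta$chrom)), meta$pos), ]
  x$chrom_f <- factor(x$chrom, levels = unique(x$chrom))
  offsets <- c(0, cumsum(tapply(x$pos, x$chrom_f, max)))
  x$cum_pos <- x$pos + offsets[as.integer(x$chrom_f)]
  ggplot2::ggplot(x, ggplot2::aes(.data$cum_pos, -log10(.data$p),
                                  colour = (as.integer(.data$chrom_f) %% 2) == 0)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(values = c("grey30", "#4393C3")) +
    ggplot2::labs(x = "Genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' QQ plot of association p-values
#'
#' Observed versus expected -log10(p) with the identity line; the genomic
#' inflation factor is shown in the subtitle.
#'
#' @param p Vector of p-values.
#' @return A ggplot object.
#' @export
plot_qq <- function(p) {
  p <- sort(p[is.finite(p)])
  df <- tibble::tibble(expected = -log10(stats::ppoints(length(p))),
                       observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8, colour = "#B2182B") +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = sprintf("lambda[gc] = %.3f", lambda_gc(p))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a fitted trajectory model
#'
#' @param object A [fit_lmm()] object.
#' @param table The modelling tibble.
#' @param ... Passed to [plot_trajectories()].
#' @return A ggplot object.
#' @export
autoplot.traj_lmm <- function(object, table, ...) {
  plot_trajectories(object, table, ...)
}
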