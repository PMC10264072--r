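# Figure helpers mirroring the field's standard displays: phase-shift
# scatter with binned means, per-class probability curves, and the
# swallow-onset phase histogram.

#' Phase-shift (reset) scatter with binned means
#'
#' @param samples Phase-sample table from [phase_samples()].
#' @param n_bins Bins for the overlaid means.
#' @return A ggplot object.
#' @export
plot_reset_curve <- function(samples, n_bins = 10) {
  curves <- do.call(rbind, lapply(unique(samples$group), function(g) {
    s <- samples[samples$group == g, , drop = FALSE]
    cbind(group = g, bin_curve(s$respiratory_phase, s$phase_shift, n_bins))
  }))
  ggplot2::ggplot(samples,
                  ggplot2::aes(x = .data$respiratory_phase,
                               y = .data$phase_shift,
                               colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_pointrange(
      data = curves[is.finite(curves$mean), ],
      ggplot2::aes(x = .data$center, y = .data$mean,
                   ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      inherit.aes = FALSE, colour = "black", size = 0.3
    ) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "respiratory phase", y = "phase shift") +
    ggplot2::theme_classic()
}

#' Phase-resolved behavior probability curves
#'
#' @param prob Long table from [probability_curves()].
#' @return A ggplot object.
#' @export
plot_probability_curves <- function(prob) {
  ggplot2::ggplot(prob[is.finite(prob$probability), ],
                  ggplot2::aes(x = .data$center, y = .data$probability,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "respiratory phase", y = "probability") +
    ggplot2::theme_classic()
}

#' Swallow-onset phase histogram
#'
#' @param timing Output of [swallow_timing()].
#' @return A ggplot object.
#' @export
plot_swallow_histogram <- function(timing) {
  ggplot2::ggplot(timing$histogram,
                  ggplot2::aes(x = .data$center, y = .data$count)) +
    ggplot2::geom_col(width = 0.09, fill = "grey30") +
    ggplot2::labs(x = "swallow onset phase", y = "swallows") +
    ggplot2::theme_classic()
}
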