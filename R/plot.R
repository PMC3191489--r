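# Figure-style plots: interval histograms with fitted densities, and
# discriminability (power) curves.

#' Interval histogram with fitted d-step densities
#'
#' Density-scaled histogram of the measured intervals (180-s bins by
#' default) overlaid with the fitted hypoexponential densities for each
#' d up to `max_d`.
#'
#' @param object A `step_selection` from [select_model()].
#' @param binwidth Histogram bin width (seconds).
#' @param max_d Largest d whose fitted density is drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot step_selection
#' @export
autoplot.step_selection <- function(object, binwidth = 180,
                                    max_d = min(3L, length(object$fits)), ...) {
  x <- object$intervals
  grid <- seq(0, max(x) * 1.05, length.out = 400)
  curves <- list_rbind(map(object$fits[seq_len(max_d)], function(f) {
    tibble(d = factor(f$d), x = grid, density = dhypoexp(grid, f$mu))
  }))
  ggplot(tibble(interval_s = x), aes(x = .data$interval_s)) +
    geom_histogram(aes(y = after_stat(density)), binwidth = binwidth,
                   boundary = 0, fill = "grey80", colour = "grey40") +
    geom_line(data = curves,
              aes(x = .data$x, y = .data$density, linetype = .data$d),
              linewidth = 0.7) +
    labs(x = "interval between consecutive RNA productions (s)",
         y = "density", linetype = "steps d") +
    theme_bw()
}

#' Power curve of the equal-duration test across separation ratios
#'
#' @param object A `discriminability_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discriminability_curve
#' @export
autoplot.discriminability_curve <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot(object, aes(x = .data$ratio, y = .data$rejection_fraction)) +
    geom_hline(yintercept = alpha, linetype = "dashed", colour = "grey50") +
    geom_line() +
    geom_point() +
    labs(x = "step-duration ratio (longer / shorter)",
         y = "fraction rejecting equal durations") +
    theme_bw()
}
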