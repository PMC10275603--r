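#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the fitness trajectory of a run
#'
#' @param object A `tugwar_run`.
#' @param ... Unused.
#' @return A ggplot: population-average fitness over time.
#' @method autoplot tugwar_run
#' @export
autoplot.tugwar_run <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$time, y = .data$mean_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "population-average fitness",
                  title = sprintf("Model %s, N = %d", object$params$model,
                                  object$params$N)) +
    ggplot2::theme_minimal()
}

#' Plot an observed site frequency spectrum
#'
#' @param object A `tugwar_sfs`.
#' @param ... Unused.
#' @return A ggplot of `S(k)` against `k / n`.
#' @method autoplot tugwar_sfs
#' @export
autoplot.tugwar_sfs <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat[dat$count > 0, ],
                  ggplot2::aes(x = .data$frequency, y = .data$count)) +
    ggplot2::geom_col(width = 0.8 / object$n) +
    ggplot2::labs(x = "mutation frequency k/n", y = "number of mutations S(k)") +
    ggplot2::theme_minimal()
}

#' Plot cumulative SFS tails in the field's comparison conventions
#'
#' Overlays one or more cumulative tails on semi-logarithmic (default) or
#' log-log axes; normalized tails are inscribed in the unit square.
#'
#' @param tails A `tugwar_tail` or named list of them.
#' @param scale `"semilog"` (log10 T vs x) or `"loglog"`.
#' @return A ggplot.
#' @export
plot_tails <- function(tails, scale = c("semilog", "loglog")) {
  scale <- match.arg(scale)
  if (inherits(tails, "tugwar_tail")) tails <- list(tail = tails)
  nms <- names(tails) %||% paste0("tail_", seq_along(tails))
  dat <- purrr::map2_dfr(tails, nms, function(tl, nm) {
    tibble(x = tl$x, T = tl$T, curve = nm)
  })
  dat <- dat[dat$T > 0, ]
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$T,
                                          colour = .data$curve)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency x", y = "cumulative tail T(x)") +
    ggplot2::theme_minimal()
  if (scale == "loglog") gg <- gg + ggplot2::scale_x_log10()
  gg
}

#' Muller-style clone succession plot
#'
#' Stacked cell fractions of driver-haplotype groups over the stored
#' snapshots (see [succession_by_driver()]), shaded by group mean fitness.
#'
#' @param run A `tugwar_run` with snapshots.
#' @return A ggplot.
#' @export
plot_succession <- function(run) {
  dat <- succession_by_driver(run)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$fraction,
                                    group = .data$driver_group,
                                    fill = .data$mean_fitness)) +
    ggplot2::geom_area(position = "stack", colour = "grey30",
                       linewidth = 0.1) +
    ggplot2::scale_fill_viridis_c(name = "mean fitness") +
    ggplot2::labs(x = "time", y = "cell fraction") +
    ggplot2::theme_minimal()
}
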