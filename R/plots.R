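#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a two-dimensional MFD histogram with FRET-lines
#'
#' Hexbin-style density of bursts in the (fluorescence-averaged donor
#' lifetime, FRET efficiency) plane, optionally overlaid with static and
#' dynamic FRET-lines.
#'
#' @param bursts tibble from [burst_indicators()].
#' @param lines optional list of `fret_line` objects to overlay.
#' @param tau_D0 donor-only lifetime, sets the x range.
#' @return a ggplot object.
#' @export
plot_mfd <- function(bursts, lines = NULL, tau_D0 = 4) {
  ok <- dplyr::filter(bursts, .data$valid, is.finite(.data$E),
                      is.finite(.data$tau_ns))
  p <- ggplot2::ggplot(ok, ggplot2::aes(x = .data$tau_ns, y = .data$E)) +
    ggplot2::geom_bin2d(bins = 61) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_cartesian(xlim = c(0, tau_D0 + 0.5), ylim = c(-0.1, 1.1)) +
    ggplot2::labs(x = "<tau_D(A)>_F (ns)", y = "FRET efficiency E")
  if (!is.null(lines)) {
    for (ln in lines) {
      p <- p + ggplot2::geom_line(
        data = as.data.frame(ln[, c("tau_F_ns", "E")]),
        ggplot2::aes(x = .data$tau_F_ns, y = .data$E),
        linewidth = 0.4, colour = if (attr(ln, "kind") == "static")
          "magenta" else "darkgreen")
    }
  }
  p
}

#' @export
autoplot.corr_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$lag_ms, y = .data$G,
                               colour = paste(.data$kind, .data$species_i,
                                              .data$species_j))) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$G - .data$sd,
                                        ymax = .data$G + .data$sd),
                           alpha = 0.4, width = 0) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag time (ms)", y = "G", colour = "curve")
}

#' @export
autoplot.support_plane <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(x = .data$value, y = .data$chi2r_global)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = attr(object, "parameter"), y = "global chi2_r")
}

#' @export
autoplot.decay_mcmc <- function(object, ...) {
  long <- tidyr::pivot_longer(object$samples, -dplyr::all_of("sample"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "samples")
}

#' Plot a fitted decay dataset
#'
#' Decay curves (data, model, IRF) on a log counts axis with weighted
#' residuals, in the style customary for TCSPC analysis.
#'
#' @param fit a `decay_fit`.
#' @param dataset dataset index.
#' @return a ggplot object.
#' @export
plot_decay_fit <- function(fit, dataset = 1L) {
  ds <- fit$datasets[[dataset]]
  up <- fit$unpacked
  dr <- dataset_residuals(ds, up$per[[dataset]], up$fracs, fit$R0,
                          fit$cfg$n_quad)
  d <- tibble::tibble(time_ns = ds$time_ns, data = ds$da,
                      model = dr$model_da, irf = ds$irf)
  long <- tidyr::pivot_longer(d, -dplyr::all_of("time_ns"),
                              names_to = "curve", values_to = "counts")
  ggplot2::ggplot(dplyr::filter(long, .data$counts > 0),
                  ggplot2::aes(x = .data$time_ns, y = .data$counts,
                               colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "counts")
}
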