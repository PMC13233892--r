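#' Plot a convergence report
#'
#' Log-log error-versus-mesh-size plot with one line per field/norm,
#' drawn with ggplot2.
#'
#' @param object A `convergence_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.convergence_report <- function(object, ...) {
  tab <- object$errors
  long <- do.call(rbind, lapply(setdiff(names(tab), "h_e"), function(cn)
    data.frame(h_e = tab$h_e, error = tab[[cn]], norm = cn)))
  ggplot2::ggplot(long, ggplot2::aes(x = h_e, y = error,
                                     colour = norm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mesh size h (m)", y = "relative error",
                  title = sprintf("Convergence, case %s", object$case))
}

#' Plot a porosity probe series
#'
#' @param run Result of [run_squeeze_benchmark()].
#' @return A ggplot object with the monitor-point porosity and the
#'   radial-line average against time.
#' @export
plot_porosity_probe <- function(run) {
  pr <- probe_porosity(run)
  long <- rbind(data.frame(t = pr$t, phi = pr$phi_point, series = "point"),
                data.frame(t = pr$t, phi = pr$phi_line_avg,
                           series = "radial-line average"))
  ggplot2::ggplot(long, ggplot2::aes(x = t, y = phi,
                                     colour = series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(phi[f]),
                  title = "Porosity at the squeezing-zone monitor")
}

#' Plot a parameter-sweep table
#'
#' @param tab Result of [run_parameter_sweep()].
#' @return A ggplot object of flow rate, peak pressure and gradient against
#'   the swept parameter, on log-log axes.
#' @export
plot_sweep <- function(tab) {
  xnm <- names(tab)[1]
  long <- rbind(
    data.frame(x = tab[[xnm]], y = tab$Q_um3_s, what = "Q (um^3/s)"),
    data.frame(x = tab[[xnm]], y = tab$peak_p_mmHg, what = "peak |p| (mmHg)"),
    data.frame(x = tab[[xnm]], y = tab$grad_mmHg_m, what = "avg dp/dz (mmHg/m)"))
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste(xnm), y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
utils::globalVariables(c("h_e", "error", "norm", "t", "phi", "series",
                         "x", "y", "what"))
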