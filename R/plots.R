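#' Plot a potential trace
#'
#' Potential versus time with the antioxidant addition time marked.
#'
#' @param object A `kp_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kp_trace
#' @export
autoplot.kp_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t,
                                            y = 1e3 * .data$e)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(x = "time (s)", y = "potential (mV)")
  t_add <- attr(object, "t_add")
  if (!is.null(t_add) && is.finite(t_add))
    p <- p + ggplot2::geom_vline(xintercept = t_add, linetype = "dashed",
                                 colour = "grey40")
  p
}

#' Plot a simulated trajectory
#'
#' Concentration time courses on a log axis: radicals, initiator-normalised
#' decay and each antioxidant.
#'
#' @param object A `kp_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kp_trajectory
#' @export
autoplot.kp_trajectory <- function(object, ...) {
  ao_names <- attr(object, "antioxidants")$name
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "t", "radical",
                  dplyr::all_of(ao_names)),
    -"t", names_to = "species", values_to = "conc")
  ggplot2::ggplot(dplyr::filter(long, .data$conc > 0),
                  ggplot2::aes(x = .data$t, y = .data$conc,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "concentration (M)")
}

#' Plot a rate-constant fit
#'
#' Raw initial slopes against starting concentration, with the
#' zero-concentration limit implied by the fitted rate constant.
#'
#' @param object A `kp_kinh_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kp_kinh_fit
#' @export
autoplot.kp_kinh_fit <- function(object, ...) {
  ggplot2::ggplot(object$slopes,
                  ggplot2::aes(x = 1e3 * .data$c0, y = .data$a)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$a0, linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::labs(x = "starting concentration (mM)",
                  y = "initial semilog slope a (1/s)",
                  subtitle = sprintf("kinh = %.3g 1/(M s); a0 = %.3g 1/s",
                                     object$kinh_hat, object$a0))
}
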