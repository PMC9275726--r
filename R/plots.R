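# ggplot2 displays for the main result types.

#' Plot a syllectogram trace
#'
#' Shows the recorded channels with the detected start (I_MIN) marked.
#'
#' @param object A [syl_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.syl_trace <- function(object, ...) {
  if (is.null(attr(object, "t0_index"))) object <- detect_start(object)
  t0 <- attr(object, "t0_index")
  long <- tidyr::pivot_longer(as_tibble(object), -"t_s",
                              names_to = "channel", values_to = "intensity")
  starts <- tibble(channel = names(t0), t_s = object$t_s[t0])
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = starts,
                        ggplot2::aes(xintercept = .data$t_s),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time since flow stop [s]",
                  y = "transmitted intensity [ADC]",
                  title = attr(object, "sample_id")) +
    ggplot2::theme_minimal()
}

#' Plot a modelled sedimentation curve
#'
#' Distance versus time with the lag/constant and packing phases
#' distinguished and the final settling distance marked when reached.
#'
#' @param object An `esr_curve` from [build_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.esr_curve <- function(object, ...) {
  p <- curve_params(object)
  g <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$t_min, .data$h_mm,
                                    colour = .data$phase)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "time [min]", y = "sedimentation distance [mm]",
                  subtitle = sprintf("Ht %.2f, Ve %.2f mm/min, alpha %.2f, lambda %.0f s",
                                     p$ht, p$ve_mm_min, p$alpha, p$lambda_s)) +
    ggplot2::theme_minimal()
  if (is.finite(p$h_inf_mm))
    g <- g + ggplot2::geom_hline(yintercept = p$h_inf_mm,
                                 linetype = "dotted", colour = "grey40")
  g
}

#' Plot a measured Westergren series
#'
#' @param object A [westergren_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.westergren_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$t_min, .data$h_mm)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time [min]", y = "sedimentation distance [mm]",
                  title = attr(object, "sample_id")) +
    ggplot2::theme_minimal()
}

#' Plot estimated 1-h ESR against a measured reference
#'
#' Scatter of estimates against measured values with the identity line.
#'
#' @param object An `esr_estimate` from [estimate_esr()].
#' @param measured Measured 1-h ESR values, mm (same length).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.esr_estimate <- function(object, measured = NULL, ...) {
  if (is.null(measured)) {
    return(ggplot2::ggplot(as_tibble(object),
                           ggplot2::aes(.data$hai5, .data$esr_1h_mm,
                                        colour = factor(.data$ht))) +
             ggplot2::geom_point() +
             ggplot2::labs(x = "HAI5", y = "estimated 1-h ESR [mm]",
                           colour = "Ht") +
             ggplot2::theme_minimal())
  }
  d <- mutate(as_tibble(object), measured = measured)
  r <- stats::cor(d$esr_1h_mm, d$measured)
  ggplot2::ggplot(d, ggplot2::aes(.data$measured, .data$esr_1h_mm)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$ht))) +
    ggplot2::labs(x = "measured 1-h ESR [mm]", y = "estimated 1-h ESR [mm]",
                  colour = "Ht", subtitle = sprintf("r = %.3f", r)) +
    ggplot2::theme_minimal()
}
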