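#' Plot a session's channels
#'
#' SC trace with injected artifact epochs shaded and, below, the
#' acceleration magnitude — the visual the gating rule is based on.
#'
#' @param session An `sc_session` from [generate_session()].
#' @return A ggplot object.
#' @export
plot_session <- function(session) {
  sc <- as_tibble(session$sc)
  epochs <- session$truth$artifact_epochs
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$time_s, y = .data$value))
  if (nrow(epochs)) {
    p <- p + ggplot2::geom_rect(
      data = epochs,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.3)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "skin conductance (μS)",
                  title = "Synthetic session: SC with artifact epochs")
}

#' @export
#' @method autoplot decomposed_sc
autoplot.decomposed_sc <- function(object, ...) {
  d <- tibble::tibble(
    time_s = (seq_along(object$sc) - 1) / object$fs,
    SC = object$sc, SCL = object$scl, SCR = object$scr
  ) |>
    tidyr::pivot_longer(-"time_s", names_to = "component",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "μS",
                  title = "Tonic/phasic decomposition")
}

#' @export
#' @method autoplot filter_comparison
autoplot.filter_comparison <- function(object, ...) {
  d <- object$samples |>
    tidyr::pivot_longer(c("dev_original", "dev_improved"),
                        names_to = "variant", values_to = "deviation") |>
    dplyr::mutate(variant = sub("dev_", "", .data$variant))
  ggplot2::ggplot(d, ggplot2::aes(.data$index, .data$deviation,
                                  colour = .data$variant)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$joints, linetype = "dotted",
                        alpha = 0.4) +
    ggplot2::labs(x = "sample", y = "|filtered - input| (μS)",
                  title = sprintf(
                    "Filter deviation from input (segment joints every %d samples)",
                    2^object$j))
}

#' @export
#' @method autoplot drowsiness_report
autoplot.drowsiness_report <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("true", "predicted", "count")
  ggplot2::ggplot(cm, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s, %d-fold CV: accuracy %.1f%%",
                      object$algorithm, object$k, object$accuracy),
      x = "predicted class", y = "true class")
}
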