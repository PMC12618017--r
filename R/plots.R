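#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: recording traces, training history and block-averaged
#' responses.
#'
#' @param object A `nirs_recording`.
#' @param channels Channel ids to show (default: first long channel and
#'   its paired short channel).
#' @param wavelength Wavelength to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nirs_recording <- function(object, channels = NULL,
                                    wavelength = NULL, ...) {
  if (is.null(wavelength)) wavelength <- object$montage$wavelengths[1]
  if (is.null(channels)) {
    l1 <- long_channels(object$montage)[1]
    channels <- c(l1, object$montage$pairing[[l1]])
  }
  cols <- paste0(channels, "@", wavelength)
  df <- tibble::tibble(
    time_s = rep((seq_len(nrow(object$data)) - 1) / object$fs_hz,
                 length(cols)),
    channel = rep(cols, each = nrow(object$data)),
    value = as.numeric(object$data[, cols])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = object$kind, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.nirs_recording
#' @export
autoplot.nirs_model <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "hybrid loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a block-averaged hemodynamic response
#'
#' @param ba Tibble from [block_average()] (optionally with `channel`
#'   and `subject` columns, as produced by [run_pipeline()]).
#' @param series Chromophores to show.
#' @return A ggplot object.
#' @export
plot_block_average <- function(ba, series = c("o2hb", "hhb")) {
  df <- ba[ba$series %in% series, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$mean,
                                        colour = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$series),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time from onset (s)", y = "concentration change (mM)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if ("channel" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~channel)
  }
  p
}
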