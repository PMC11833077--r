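#' Tidiers and plots for package result objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit tibble behind an
#' object, `glance()` a one-row summary, and `autoplot()` a ggplot.
#'
#' @param x A package object (`ecg_record`, `ecg_fit`, `agreement_report`).
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.ecg_fit <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(
      c("recon_loss", "label_loss", "domain_loss", "train_loss"),
      names_to = "loss", values_to = "value"
    ) |>
    dplyr::select(dplyr::all_of(c("phase", "epoch", "loss", "value")))
}

#' @rdname tidiers
#' @export
glance.ecg_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  tibble(
    n_epochs = nrow(h),
    final_train_loss = last$train_loss,
    label_accuracy = last$label_metric,
    dc_accuracy = last$dc_accuracy,
    decoder_loss = last$decoder_loss,
    checkpoints_saved = sum(h$checkpoint == "save", na.rm = TRUE)
  )
}

#' @rdname tidiers
#' @export
tidy.agreement_report <- function(x, ...) x$per_image

#' @rdname tidiers
#' @export
glance.agreement_report <- function(x, ...) {
  tidyr::pivot_wider(
    x$per_condition,
    names_from = "condition",
    values_from = c("mean_c", "sd_c", "n")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_df <- function(m) {
  tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @rdname tidiers
#' @param object Object to plot.
#' @export
autoplot.ecg_image <- function(object, ...) {
  px <- clamp(object$pixels, 0, 255) / 255
  df <- raster_df(px[, , 1])
  df$fill <- grDevices::rgb(as.vector(px[, , 1]), as.vector(px[, , 2]),
                            as.vector(px[, , 3]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @rdname tidiers
#' @export
autoplot.saliency_map <- function(object, ...) {
  m <- object$scaled %||% aggregate_and_scale(object)$scaled
  df <- raster_df(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "saliency", option = "magma") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(sprintf("%s (p = %.3f)", object$target,
                             object$label_prob))
}

#' @rdname tidiers
#' @export
autoplot.ecg_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
autoplot.ecg_record <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_s, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 3) +
    ggplot2::labs(x = "time (s)", y = "mV",
                  title = object$condition) +
    ggplot2::theme_minimal()
}
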