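#' @method autoplot smlm_image
#' @export
autoplot.smlm_image <- function(object, trans = "sqrt", ...) {
  p <- object$pixel_size
  df <- expand.grid(ix = seq_len(nrow(object$counts)),
                    iy = seq_len(ncol(object$counts)))
  df$x <- object$origin[1] + (df$ix - 0.5) * p
  df$y <- object$origin[2] + (df$iy - 0.5) * p
  df$count <- as.vector(object$counts)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "counts")
}

#' @method autoplot bivar_hist
#' @export
autoplot.bivar_hist <- function(object, ...) {
  cs <- (object$edges_s[-1] + object$edges_s[-length(object$edges_s)]) / 2
  cl <- (object$edges_l[-1] + object$edges_l[-length(object$edges_l)]) / 2
  df <- expand.grid(i_s = cs, i_l = cl)
  df$count <- as.vector(object$counts)
  lab <- if (object$scale == "log") c("log10 I_S", "log10 I_L") else
    c("I_S (photons)", "I_L (photons)")
  ggplot2::ggplot(df, ggplot2::aes(.data$i_s, .data$i_l, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::labs(x = lab[1], y = lab[2], fill = "pairs")
}

#' @method autoplot frc_result
#' @export
autoplot.frc_result <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$freq, .data$frc,
                               group = .data$repeat_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1 / 7, linetype = 2) +
    ggplot2::labs(x = "spatial frequency (1/nm)", y = "FRC",
                  title = sprintf("FRC(1/7) resolution %.1f +/- %.1f nm",
                                  object$mean, object$sd))
}

#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$r_mid, .data$density)) +
    ggplot2::geom_col(width = object$r_max[1] - object$r_min[1]) +
    ggplot2::labs(x = "radius (nm)", y = "density (1/nm^2)")
}

#' @method autoplot drift_track
#' @export
autoplot.drift_track <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("dx", "dy"),
                            names_to = "axis", values_to = "displacement")
  ggplot2::ggplot(df, ggplot2::aes(.data$frame_center, .data$displacement,
                                   color = .data$axis)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "frame", y = "drift (nm)")
}

#' @method autoplot sideview_fit
#' @export
autoplot.sideview_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(.data$position)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
    ggplot2::geom_vline(xintercept = object$center, linetype = 2) +
    ggplot2::labs(x = "axial position (nm)", y = "intensity")
}
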