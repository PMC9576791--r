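#' Fourier ring correlation of two half-images
#'
#' Ring-averaged normalized cross-correlation of the Fourier transforms of
#' two statistically independent reconstructions of the same structure.
#'
#' @param img1,img2 `smlm_image`s on the same grid (see
#'   [render_histogram()]).
#' @param n_steps Number of radial frequency bins up to the Nyquist
#'   frequency of the rendered image.
#' @return Tibble with `freq` (1/nm, bin centers) and `frc` (the curve); the
#'   DC point (frequency 0, correlation 1 for non-empty images) is included
#'   as the first row.
#' @export
frc_curve <- function(img1, img2, n_steps = 90) {
  A <- img1$counts; B <- img2$counts
  stopifnot(all(dim(A) == dim(B)), n_steps >= 2)
  p <- img1$pixel_size
  F1 <- fft(A); F2 <- fft(B)
  num <- Re(F1 * Conj(F2))
  d1 <- Mod(F1)^2; d2 <- Mod(F2)^2
  fftfreq <- function(n) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * p)
  }
  fx <- fftfreq(nrow(A)); fy <- fftfreq(ncol(A))
  q <- sqrt(outer(fx^2, fy^2, "+"))
  q_nyq <- 1 / (2 * p)
  edges <- seq(0, q_nyq, length.out = n_steps + 1)
  b <- findInterval(q, edges, rightmost.closed = TRUE)
  keep <- b >= 1 & b <= n_steps & q > 0
  bk <- b[keep]
  sum_by <- function(v) {
    out <- numeric(n_steps)
    agg <- rowsum(v[keep], bk)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  n_num <- sum_by(num); n_d1 <- sum_by(d1); n_d2 <- sum_by(d2)
  frc <- ifelse(n_d1 > 0 & n_d2 > 0, n_num / sqrt(n_d1 * n_d2), NA_real_)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  dc <- if (sum(A) > 0 && sum(B) > 0) 1 else NA_real_
  tibble(freq = c(0, centers), frc = c(dc, frc))
}

# light 3-point smoothing, ends kept
smooth3 <- function(v) {
  s <- as.numeric(stats::filter(v, rep(1 / 3, 3)))
  s[is.na(s)] <- v[is.na(s)]
  s
}

# first crossing of the curve below `thr`, linearly interpolated; NA if none
frc_crossing <- function(freq, frc, thr = 1 / 7) {
  ok <- is.finite(frc)
  freq <- freq[ok]; frc <- frc[ok]
  below <- which(frc < thr)
  below <- below[below > 1]
  if (!length(below)) return(NA_real_)
  k <- below[1]
  f0 <- freq[k - 1]; f1 <- freq[k]
  v0 <- frc[k - 1]; v1 <- frc[k]
  q <- f0 + (v0 - thr) / (v0 - v1) * (f1 - f0)
  1 / q
}

#' Image resolution by Fourier ring correlation (1/7 criterion)
#'
#' The localization set is split at random into two halves (Bernoulli 1/2
#' per localization, re-seeded per repeat), both halves are rendered as 2D
#' histograms, and the resolution is the inverse of the spatial frequency at
#' which the lightly smoothed FRC curve first drops below 1/7. The split is
#' stochastic, so the calculation is repeated (default 10 times) and
#' reported as mean ± sd.
#'
#' @param table Localization table (at least 100 localizations).
#' @param pixel_size Rendering pixel, nm (default 5).
#' @param n_steps Radial frequency bins (default 90).
#' @param n_repeats Number of random splits.
#' @param seed Optional seed for reproducible splits.
#' @return Object of class `frc_result`: `curves` (tibble: `repeat_id`,
#'   `freq`, `frc`), `resolutions` (nm per repeat; NA = threshold not
#'   reached), `mean`, `sd`, `n_not_reached`.
#' @export
frc_resolution <- function(table, pixel_size = 5, n_steps = 90,
                           n_repeats = 10, seed = NULL) {
  df <- as_tibble(table)
  if (nrow(df) < 100) abort_config("FRC needs at least 100 localizations")
  bounds <- c(min(df$x), max(df$x), min(df$y), max(df$y))
  run <- function() {
    curves <- vector("list", n_repeats)
    res <- numeric(n_repeats)
    for (k in seq_len(n_repeats)) {
      half <- rbinom(nrow(df), 1, 0.5) == 1
      i1 <- render_histogram(df[half, , drop = FALSE], pixel_size, bounds)
      i2 <- render_histogram(df[!half, , drop = FALSE], pixel_size, bounds)
      cv <- frc_curve(i1, i2, n_steps)
      cv$frc_smooth <- smooth3(cv$frc)
      res[k] <- frc_crossing(cv$freq, cv$frc_smooth)
      cv$repeat_id <- k
      curves[[k]] <- cv
    }
    list(curves = bind_rows(curves), res = res)
  }
  out <- with_opt_seed(seed, run)
  reached <- out$res[is.finite(out$res)]
  structure(list(curves = out$curves,
                 resolutions = out$res,
                 mean = if (length(reached)) mean(reached) else NA_real_,
                 sd = if (length(reached) > 1) sd(reached) else NA_real_,
                 n_not_reached = sum(!is.finite(out$res)),
                 pixel_size = pixel_size, n_steps = n_steps),
            class = "frc_result")
}

#' @export
print.frc_result <- function(x, ...) {
  cat("FRC(1/7) resolution: ", signif(x$mean, 4), " +/- ",
      signif(x$sd, 3), " nm (", length(x$resolutions), " repeats",
      if (x$n_not_reached) paste0(", ", x$n_not_reached, " not reached"),
      ")\n", sep = "")
  invisible(x)
}

#' @method tidy frc_result
#' @export
tidy.frc_result <- function(x, ...) {
  tibble(repeat_id = seq_along(x$resolutions), resolution = x$resolutions)
}

#' @method glance frc_result
#' @export
glance.frc_result <- function(x, ...) {
  tibble(resolution_mean = x$mean, resolution_sd = x$sd,
         n_repeats = length(x$resolutions), n_not_reached = x$n_not_reached,
         pixel_size = x$pixel_size)
}

#' Write FRC curves as CSV
#' @param frc An `frc_result`.
#' @param path Output CSV (`freq_per_nm`, `frc_mean`, `frc_sd`).
#' @export
write_frc_curves <- function(frc, path) {
  out <- frc$curves |>
    group_by(.data$freq) |>
    summarise(frc_mean = mean(.data$frc), frc_sd = sd(.data$frc),
              .groups = "drop")
  names(out)[1] <- "freq_per_nm"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
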