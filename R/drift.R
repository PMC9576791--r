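#' Estimate sample drift by time-binned image cross-correlation
#'
#' Because all demixed channels share the same physical drift, drift is best
#' estimated on the sum of localizations of all channels. Frames are
#' partitioned into equal time bins, each bin is rendered as a 2D histogram,
#' and the displacement of every bin relative to the first is the sub-pixel
#' cross-correlation peak of the two images. Per-frame drift is obtained by
#' linear interpolation between bin centers (constant beyond the ends).
#'
#' @param tables A localization table or a list of them (e.g. the demixed
#'   species tables); they are concatenated before binning.
#' @param n_bins Number of time bins (total frame span must be at least
#'   `2 * n_bins`).
#' @param render_pixel Histogram pixel for the correlation images, nm.
#' @param min_locs Bins with fewer localizations are skipped (warning) and
#'   interpolated over.
#' @return Object of class `drift_track`: tibble with `bin`, `frame_center`,
#'   `n`, `dx`, `dy` (nm, first bin fixed at 0); attribute `frame_range`.
#' @export
estimate_drift <- function(tables, n_bins = 10, render_pixel = 25,
                           min_locs = 10) {
  if (is.data.frame(tables)) tables <- list(tables)
  df <- bind_rows(lapply(tables, as_tibble))
  stopifnot(nrow(df) > 0, n_bins >= 2)
  frange <- range(df$frame)
  if (diff(frange) + 1 < 2 * n_bins) {
    abort_config("frame span too short for the requested number of time bins")
  }
  edges <- seq(frange[1], frange[2] + 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(df$frame, edges), n_bins)
  bounds <- c(min(df$x), max(df$x), min(df$y), max(df$y))
  imgs <- lapply(seq_len(n_bins), function(k) {
    render_histogram(df[bin == k, , drop = FALSE], render_pixel, bounds)$counts
  })
  n_k <- vapply(seq_len(n_bins), function(k) sum(bin == k), integer(1))
  dx <- rep(NA_real_, n_bins); dy <- rep(NA_real_, n_bins)
  dx[1] <- 0; dy[1] <- 0
  if (n_k[1] < min_locs) {
    warn("reference time bin has very few localizations; drift may be unreliable")
  }
  for (k in 2:n_bins) {
    if (n_k[k] < min_locs) {
      warn(paste0("time bin ", k, " has fewer than ", min_locs,
                  " localizations; interpolating over it"))
      next
    }
    sh <- tryCatch(xcorr_shift(imgs[[1]], imgs[[k]]) * render_pixel,
                   smlmdemix_alignment_error = function(e) c(NA_real_, NA_real_))
    dx[k] <- sh[1]; dy[k] <- sh[2]
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  fill <- function(v) {
    if (anyNA(v)) {
      ok <- !is.na(v)
      v <- approx(centers[ok], v[ok], xout = centers, rule = 2)$y
    }
    v
  }
  track <- tibble(bin = seq_len(n_bins), frame_center = centers,
                  n = n_k, dx = fill(dx), dy = fill(dy))
  structure(track, class = c("drift_track", class(track)),
            frame_range = frange)
}

#' Interpolate a drift track at arbitrary frames
#'
#' @param track A `drift_track`.
#' @param frames Frame indices.
#' @return Tibble with `dx`, `dy` (nm); constant extrapolation beyond the
#'   track's bin centers.
#' @export
drift_at <- function(track, frames) {
  tibble(dx = approx(track$frame_center, track$dx, xout = frames, rule = 2)$y,
         dy = approx(track$frame_center, track$dy, xout = frames, rule = 2)$y)
}

#' Subtract estimated drift from a localization table
#'
#' @param table Localization table.
#' @param track A `drift_track` from [estimate_drift()] (applied identically
#'   to every demixed channel).
#' @return The drift-corrected [loc_table()].
#' @export
apply_drift <- function(table, track) {
  frange <- attr(track, "frame_range")
  if (!is.null(frange) &&
      (min(table$frame) < frange[1] || max(table$frame) > frange[2])) {
    inform("frames outside the drift track range; using constant end values")
  }
  d <- drift_at(track, table$frame)
  out <- as_tibble(table)
  out$x <- out$x - d$dx
  out$y <- out$y - d$dy
  loc_table(out,
            source_channel = attr(table, "source_channel") %||% "none",
            pixel_size_camera = attr(table, "pixel_size_camera") %||% 100)
}

#' Write a drift track as CSV
#' @param track A `drift_track`.
#' @param path Output CSV (`bin`, `frame_center`, `n`, `dx_nm`, `dy_nm`).
#' @export
write_drift_track <- function(track, path) {
  out <- tibble(bin = track$bin, frame_center = track$frame_center,
                n = track$n, dx_nm = track$dx, dy_nm = track$dy)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
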