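#' Render a localization table as a 2D histogram image
#'
#' Each localization increments exactly one pixel (floor binning on
#' half-open pixels), so the image sum equals the number of rendered
#' localizations. The 5 nm default pixel is the standard rendering scale
#' for super-resolution reconstructions of nuclear-pore-scale structures.
#'
#' @param table Localization table (needs `x`, `y` in nm).
#' @param pixel_size Pixel edge in nm.
#' @param bounds Optional rectangle `c(xmin, xmax, ymin, ymax)`; localizations
#'   outside it are dropped. Defaults to the table's coordinate range.
#' @return An object of class `smlm_image`: list with `counts` (matrix, x
#'   along rows), `pixel_size` and `origin` (nm position of pixel (1,1)'s
#'   lower-left corner).
#' @export
render_histogram <- function(table, pixel_size = 5, bounds = NULL) {
  stopifnot(pixel_size > 0)
  x <- table$x
  y <- table$y
  if (is.null(bounds)) {
    bounds <- if (length(x)) c(min(x), max(x), min(y), max(y)) else c(0, 1, 0, 1)
  }
  nx <- max(1L, floor((bounds[2] - bounds[1]) / pixel_size) + 1L)
  ny <- max(1L, floor((bounds[4] - bounds[3]) / pixel_size) + 1L)
  ix <- floor((x - bounds[1]) / pixel_size) + 1L
  iy <- floor((y - bounds[3]) / pixel_size) + 1L
  keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  counts <- matrix(0L, nrow = nx, ncol = ny)
  if (any(keep)) {
    tab <- tabulate(ix[keep] + (iy[keep] - 1L) * nx, nbins = nx * ny)
    counts <- matrix(tab, nrow = nx, ncol = ny)
  }
  structure(list(counts = counts, pixel_size = pixel_size,
                 origin = c(bounds[1], bounds[3])),
            class = "smlm_image")
}

#' Write a rendered image as 16-bit grayscale TIFF
#'
#' @param image An `smlm_image` from [render_histogram()].
#' @param path Output path.
#' @param max_count Count mapped to white; defaults to the image maximum.
#' @export
write_image_tiff <- function(image, path, max_count = NULL) {
  m <- image$counts
  max_count <- max_count %||% max(1, max(m))
  # writeTIFF expects [0,1]; transpose so x runs along image columns
  tiff::writeTIFF(t(pmin(m / max_count, 1)), path, bits.per.sample = 16L)
  invisible(path)
}

# Sub-pixel displacement of image B relative to image A by FFT
# cross-correlation. Returns c(dx, dy) in pixels such that B is (approximately)
# A translated by +(dx, dy). Errors if the correlation peak is not
# distinguishable from the background of the correlation surface.
xcorr_shift <- function(A, B, subpixel = TRUE) {
  stopifnot(all(dim(A) == dim(B)))
  nr <- nrow(A); nc <- ncol(A)
  PA <- matrix(0, 2 * nr, 2 * nc); PA[1:nr, 1:nc] <- A
  PB <- matrix(0, 2 * nr, 2 * nc); PB[1:nr, 1:nc] <- B
  cc <- Re(fft(fft(PA) * Conj(fft(PB)), inverse = TRUE)) / length(PA)
  pk <- which.max(cc)
  if (max(cc) < mean(cc) + 5 * sd(cc)) {
    abort("cross-correlation peak indistinguishable from background; alignment failed",
          class = "smlmdemix_alignment_error")
  }
  pi0 <- (pk - 1) %% (2 * nr)       # zero-based row lag
  pj0 <- (pk - 1) %/% (2 * nr)      # zero-based col lag
  u <- c(pi0, pj0)
  if (subpixel) {
    # centroid of the 3x3 neighborhood (wrapped), background-subtracted
    ri <- ((pi0 + (-1:1)) %% (2 * nr)) + 1
    rj <- ((pj0 + (-1:1)) %% (2 * nc)) + 1
    w <- cc[ri, rj] - min(cc[ri, rj])
    if (sum(w) > 0) {
      u[1] <- u[1] + sum((-1:1) * rowSums(w)) / sum(w)
      u[2] <- u[2] + sum((-1:1) * colSums(w)) / sum(w)
    }
  }
  # wrap lags to (-n, n]
  if (u[1] > nr) u[1] <- u[1] - 2 * nr
  if (u[2] > nc) u[2] <- u[2] - 2 * nc
  # cc peaks at lag u = -s where B(x) = A(x - s); report s
  -u
}
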