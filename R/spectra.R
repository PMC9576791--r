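#' Read a two-column spectrum file
#'
#' Reads wavelength/value text (whitespace- or comma-delimited, optional
#' header) into a spectrum tibble. Wavelengths must be strictly increasing
#' and values non-negative.
#'
#' @param path File path.
#' @return Tibble with `wavelength` (nm) and `value`, class `spectrum`.
#' @export
read_spectrum <- function(path) {
  raw <- tryCatch(utils::read.table(path, header = FALSE, sep = "",
                                    comment.char = "#"),
                  error = function(e) NULL)
  if (is.null(raw) || ncol(raw) < 2 || !is.numeric(raw[[1]])) {
    raw <- tryCatch(utils::read.table(path, header = TRUE, sep = "",
                                      comment.char = "#"),
                    error = function(e) NULL)
  }
  if (is.null(raw) || ncol(raw) < 2) {
    raw <- tryCatch(utils::read.csv(path), error = function(e) NULL)
  }
  if (is.null(raw) || ncol(raw) < 2) {
    abort_format(paste0("cannot parse spectrum file: ", path))
  }
  spectrum(as.numeric(raw[[1]]), as.numeric(raw[[2]]))
}

#' @rdname read_spectrum
#' @param wavelength Wavelength samples, nm, strictly increasing.
#' @param value Intensity/transmission values, >= 0.
#' @export
spectrum <- function(wavelength, value) {
  if (any(diff(wavelength) <= 0)) {
    abort_format("spectrum wavelengths must be strictly increasing")
  }
  if (any(value < 0 | !is.finite(value))) {
    abort_format("spectrum values must be finite and non-negative")
  }
  structure(tibble(wavelength = wavelength, value = value),
            class = c("spectrum", class(tibble())))
}

#' Average wavelength of an emission spectrum through a filter chain
#'
#' The effective spectrum in a detection channel is the fluorophore emission
#' multiplied by the transmissions of the dichroics/filters in that channel
#' and the camera quantum efficiency. Its average (centroid) wavelength
#' \deqn{\lambda_0 = \int \lambda I(\lambda) d\lambda / \int I(\lambda) d\lambda}
#' over the detection range summarizes the channel's chromatic behavior; it
#' is invariant under rescaling any spectrum by a positive constant.
#'
#' @param emission Emission [spectrum()].
#' @param transmissions List of transmission spectra (multiplied in).
#' @param qe Optional camera quantum-efficiency spectrum.
#' @param range Integration range, nm (default 630-800).
#' @param grid_step Interpolation grid, nm.
#' @return The average wavelength \eqn{\lambda_0}, nm.
#' @export
average_wavelength <- function(emission, transmissions = list(), qe = NULL,
                               range = c(630, 800), grid_step = 0.5) {
  stopifnot(length(range) == 2, range[1] < range[2])
  grid <- seq(range[1], range[2], by = grid_step)
  interp <- function(s) {
    v <- approx(s$wavelength, s$value, xout = grid, rule = 1)$y
    v[is.na(v)] <- 0
    v
  }
  I <- interp(emission)
  for (tr in transmissions) I <- I * interp(tr)
  if (!is.null(qe)) I <- I * interp(qe)
  denom <- pracma::trapz(grid, I)
  if (denom <= 0) {
    abort("effective spectrum is zero over the integration range; average wavelength undefined",
          class = "smlmdemix_estimation_error")
  }
  pracma::trapz(grid, grid * I) / denom
}
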