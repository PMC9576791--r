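#' Split a whole-chip localization table into the two splitter channels
#'
#' The image splitter projects the short- (\eqn{\lambda_S}) and
#' long-wavelength (\eqn{\lambda_L}) channels side by side on one camera
#' chip; this selects the localizations belonging to each region of
#' interest. Localizations in neither ROI are dropped and counted.
#'
#' @param table Localization table covering the whole chip (nm).
#' @param roi_s,roi_l Rectangles `c(xmin, xmax, ymin, ymax)` in nm; must not
#'   overlap.
#' @return List with `s` and `l` localization tables (tagged `"S"`/`"L"`)
#'   and `n_dropped`.
#' @export
split_by_roi <- function(table, roi_s, roi_l) {
  overlap <- roi_s[1] < roi_l[2] && roi_l[1] < roi_s[2] &&
    roi_s[3] < roi_l[4] && roi_l[3] < roi_s[4]
  if (overlap) abort_config("channel ROIs overlap")
  s <- crop_region(table, roi_s)
  l <- crop_region(table, roi_l)
  attr(s, "source_channel") <- "S"
  attr(l, "source_channel") <- "L"
  n_dropped <- nrow(table) - nrow(s) - nrow(l)
  list(s = s, l = l, n_dropped = n_dropped)
}

#' Channel transform mapping the long-wavelength channel onto the short
#'
#' @param matrix 2x3 matrix applied to `(x, y, 1)` (nm).
#' @param kind `"translation"` or `"affine"`.
#' @param residual_rms RMS pairing residual after the transform, nm.
#' @return Object of class `channel_transform`.
#' @export
channel_transform <- function(matrix = cbind(diag(2), c(0, 0)),
                              kind = "translation", residual_rms = NA_real_) {
  matrix <- matrix(as.numeric(matrix), 2, 3)
  if (abs(det(matrix[, 1:2])) < 1e-12) {
    abort_config("channel transform linear part is singular")
  }
  structure(list(kind = kind, matrix = matrix, residual_rms = residual_rms),
            class = "channel_transform")
}

#' @rdname channel_transform
#' @param transform A `channel_transform`.
#' @param table Localization table whose coordinates are mapped.
#' @export
apply_transform <- function(table, transform) {
  m <- transform$matrix
  x <- m[1, 1] * table$x + m[1, 2] * table$y + m[1, 3]
  y <- m[2, 1] * table$x + m[2, 2] * table$y + m[2, 3]
  out <- as_tibble(table)
  out$x <- x
  out$y <- y
  out
}

#' Save or load a channel transform as YAML
#' @param path YAML path.
#' @inheritParams apply_transform
#' @export
write_transform <- function(transform, path) {
  yaml::write_yaml(list(kind = transform$kind,
                        matrix = as.numeric(transform$matrix),
                        residual_rms = transform$residual_rms), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  d <- yaml::read_yaml(path)
  channel_transform(matrix(as.numeric(d$matrix), 2, 3), kind = d$kind,
                    residual_rms = d$residual_rms %||% NA_real_)
}

#' Estimate the registration of the long channel onto the short channel
#'
#' The splitter geometry is static, so one transform is estimated per
#' dataset. The translation is the sub-pixel peak of the cross-correlation
#' of the two rendered 2D histograms; the affine model refines it by least
#' squares on provisional per-frame pairs, absorbing unequal channel
#' magnification.
#'
#' @param table_s,table_l Localization tables of the two channels, already
#'   in a common coordinate origin (e.g. both cropped from the chip).
#' @param model `"translation"` or `"affine"`.
#' @param render_pixel Histogram pixel for the correlation step, nm.
#' @param pair_tolerance Pairing tolerance for the affine refinement, nm.
#' @return A [channel_transform()] mapping `table_l` coordinates into the
#'   `table_s` frame of reference, with `residual_rms` in nm.
#' @export
estimate_alignment <- function(table_s, table_l,
                               model = c("translation", "affine"),
                               render_pixel = 50,
                               pair_tolerance = 2 * render_pixel) {
  model <- arg_match(model)
  if (!nrow(table_s) || !nrow(table_l)) {
    abort_config("both channel tables must be non-empty for alignment")
  }
  bounds <- c(min(table_s$x, table_l$x), max(table_s$x, table_l$x),
              min(table_s$y, table_l$y), max(table_s$y, table_l$y))
  A <- render_histogram(table_s, render_pixel, bounds)$counts
  B <- render_histogram(table_l, render_pixel, bounds)$counts
  # displacement of L relative to S; mapping L -> S subtracts it
  d <- xcorr_shift(A, B) * render_pixel
  tr <- channel_transform(cbind(diag(2), -d), kind = "translation")
  pr <- pair_localizations(table_s, table_l, transform = tr,
                           tolerance = pair_tolerance)
  if (model == "affine") {
    if (nrow(pr$pairs) < 4) {
      abort("not enough provisional pairs for affine refinement",
            class = "smlmdemix_alignment_error")
    }
    # regress reference (S) coordinates on the *original* L coordinates
    orig <- as_tibble(table_l)[pr$pairs$id_l, c("x", "y")]
    X <- cbind(orig$x, orig$y, 1)
    cx <- lm.fit(X, pr$pairs$x_s)$coefficients
    cy <- lm.fit(X, pr$pairs$y_s)$coefficients
    tr <- channel_transform(rbind(cx, cy), kind = "affine")
    pr <- pair_localizations(table_s, table_l, transform = tr,
                             tolerance = pair_tolerance)
  }
  res <- sqrt(mean((pr$pairs$x_s - pr$pairs$x_l)^2 +
                     (pr$pairs$y_s - pr$pairs$y_l)^2))
  tr$residual_rms <- res
  tr
}

#' Pair localizations of the same molecule across the two channels
#'
#' A molecule must be detected in both channels in the same frame to be
#' considered reliable; pairing is per-frame mutual nearest neighbor within
#' a distance tolerance (default 100 nm, accounting for chromatic offsets
#' and localization imprecision). Ambiguous matches (a localization with two
#' in-tolerance partners at equal distance, or non-reciprocated nearest
#' neighbors) are left unpaired; unpaired localizations form the
#' "unreliable" set rejected from reconstruction.
#'
#' @param table_s,table_l Localization tables of the two channels.
#' @param transform Optional [channel_transform()] applied to `table_l`
#'   before pairing (\eqn{\lambda_S} is the reference frame).
#' @param tolerance Pairing distance tolerance, nm.
#' @return List with `pairs` (tibble: `frame`, `x_s`, `y_s`, `x_l`, `y_l`,
#'   `photons_s`, `photons_l`, `ratio`, plus row indices `id_s`, `id_l`
#'   into the input tables), and the `unpaired_s` / `unpaired_l` subsets of
#'   the inputs.
#' @export
pair_localizations <- function(table_s, table_l, transform = NULL,
                               tolerance = 100) {
  stopifnot(tolerance > 0)
  s <- as_tibble(table_s)
  l <- if (is.null(transform)) as_tibble(table_l) else
    apply_transform(table_l, transform)
  ns <- nrow(s); nl <- nrow(l)
  empty_pairs <- tibble(frame = numeric(), x_s = numeric(), y_s = numeric(),
                        x_l = numeric(), y_l = numeric(),
                        photons_s = numeric(), photons_l = numeric(),
                        ratio = numeric(), id_s = integer(), id_l = integer())
  if (!ns || !nl) {
    return(list(pairs = empty_pairs, unpaired_s = s, unpaired_l = l))
  }
  tol2 <- tolerance^2
  # match frame groups of the two tables
  fs <- s$frame; fl <- l$frame
  frames <- intersect(unique(fs), unique(fl))
  idx_s_by_f <- split(seq_len(ns), fs)
  idx_l_by_f <- split(seq_len(nl), fl)
  key <- as.character(frames)
  cnt_s <- lengths(idx_s_by_f)[key]
  cnt_l <- lengths(idx_l_by_f)[key]

  sel_s <- integer(0); sel_l <- integer(0)

  # fast path: frames with exactly one localization in each channel
  simple <- which(cnt_s == 1L & cnt_l == 1L)
  if (length(simple)) {
    i <- unlist(idx_s_by_f[key[simple]], use.names = FALSE)
    j <- unlist(idx_l_by_f[key[simple]], use.names = FALSE)
    ok <- (s$x[i] - l$x[j])^2 + (s$y[i] - l$y[j])^2 <= tol2
    sel_s <- i[ok]; sel_l <- j[ok]
  }

  # general per-frame mutual nearest neighbor with tie rejection
  hard <- which(!(cnt_s == 1L & cnt_l == 1L))
  for (k in hard) {
    i <- idx_s_by_f[[key[k]]]
    j <- idx_l_by_f[[key[k]]]
    d2 <- outer(s$x[i], l$x[j], "-")^2 + outer(s$y[i], l$y[j], "-")^2
    nn_s <- max.col(-d2, ties.method = "first")
    nn_l <- max.col(-t(d2), ties.method = "first")
    min_s <- d2[cbind(seq_along(i), nn_s)]
    min_l <- d2[cbind(nn_l, seq_along(j))]
    # ambiguity: a second partner at (numerically) the same distance
    amb_s <- vapply(seq_along(i), function(a)
      sum(sqrt(d2[a, ]) - sqrt(min_s[a]) < 1e-9) > 1L, logical(1))
    amb_l <- vapply(seq_along(j), function(b)
      sum(sqrt(d2[, b]) - sqrt(min_l[b]) < 1e-9) > 1L, logical(1))
    ok <- which(nn_l[nn_s] == seq_along(i) &
                  min_s <= tol2 & !amb_s & !amb_l[nn_s])
    sel_s <- c(sel_s, i[ok]); sel_l <- c(sel_l, j[nn_s[ok]])
  }

  ord <- order(s$frame[sel_s])
  sel_s <- sel_s[ord]; sel_l <- sel_l[ord]
  pairs <- tibble(
    frame = s$frame[sel_s],
    x_s = s$x[sel_s], y_s = s$y[sel_s],
    x_l = l$x[sel_l], y_l = l$y[sel_l],
    photons_s = s$photons[sel_s], photons_l = l$photons[sel_l],
    ratio = l$photons[sel_l] / s$photons[sel_s],
    id_s = as.integer(sel_s), id_l = as.integer(sel_l)
  )
  list(pairs = pairs,
       unpaired_s = s[setdiff(seq_len(ns), sel_s), , drop = FALSE],
       unpaired_l = l[setdiff(seq_len(nl), sel_l), , drop = FALSE])
}
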