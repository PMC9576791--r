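#' Annulus-normalized radial distribution of particle localizations
#'
#' Pools the distances of localizations to their particle centers into a
#' radius histogram and divides each bin by the area of the corresponding
#' concentric annulus, yielding a density (per nm^2) proportional to the
#' image profile. Used on aligned particle ensembles such as nuclear pore
#' complexes (localizations kept within ~130 nm of each picked center).
#'
#' @param locs Tibble with `x`, `y` (nm) and a `particle` id column; if
#'   `centers` is `NULL`, `x`/`y` are taken as already centered on the
#'   particle.
#' @param centers Optional tibble `particle`, `x`, `y` of per-particle
#'   centers.
#' @param bin_width Radius bin width, nm.
#' @param r_max Maximum radius, nm.
#' @return Object of class `radial_profile`: tibble `r_min`, `r_max`,
#'   `r_mid`, `count`, `density` (counts per nm^2).
#' @export
radial_distribution <- function(locs, centers = NULL, bin_width = 5,
                                r_max = 130) {
  stopifnot(bin_width > 0, r_max > 0)
  df <- as_tibble(locs)
  if (!is.null(centers)) {
    centers <- as_tibble(centers)
    names(centers)[match(c("x", "y"), names(centers))] <- c("cx", "cy")
    df <- left_join(df, centers, by = "particle")
    if (anyNA(df$cx)) abort_config("some particles have no center")
    r <- sqrt((df$x - df$cx)^2 + (df$y - df$cy)^2)
  } else {
    r <- sqrt(df$x^2 + df$y^2)
  }
  edges <- seq(0, r_max, by = bin_width)
  if (tail(edges, 1) < r_max) edges <- c(edges, tail(edges, 1) + bin_width)
  nb <- length(edges) - 1
  b <- findInterval(r, edges, rightmost.closed = FALSE)
  counts <- tabulate(b[b >= 1 & b <= nb], nbins = nb)
  area <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  out <- tibble(r_min = edges[-length(edges)], r_max = edges[-1],
                r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                count = as.integer(counts), density = counts / area)
  structure(out, class = c("radial_profile", class(out)))
}

#' Fit a double-Gaussian axial profile and find its center
#'
#' Side-view intensity profiles of ring-like particles (e.g. the two Nup96
#' rings of the nuclear pore complex) show two peaks; the profile is fitted
#' with a sum of two Gaussians and the midpoint between the two means
#' becomes the new origin, so particles can be summed after alignment.
#'
#' @param profile Tibble with `position` (nm) and `intensity` (>= 8
#'   samples).
#' @return Object of class `sideview_fit`: parameter tibble (`a1`, `mu1`,
#'   `s1`, `a2`, `mu2`, `s2`), `center` = (mu1+mu2)/2, `shift` = -center,
#'   `separation`, `degenerate` flag (the two Gaussians collapse onto one),
#'   `rss` and the fitted values.
#' @export
fit_sideview_profile <- function(profile) {
  df <- as_tibble(profile)
  if (!all(c("position", "intensity") %in% names(df))) {
    names(df)[1:2] <- c("position", "intensity")
  }
  if (nrow(df) < 8) abort_config("profile needs at least 8 samples")
  x <- df$position; yv <- df$intensity
  # initial guesses: two highest well-separated samples
  o <- order(yv, decreasing = TRUE)
  span <- diff(range(x))
  mu1_0 <- x[o[1]]
  cand <- o[abs(x[o] - mu1_0) > span / 8]
  mu2_0 <- if (length(cand)) x[cand[1]] else mu1_0 + span / 4
  s0 <- span / 8
  a0 <- max(yv)
  # zero-residual (noise-free) profiles make the nls model construction fail
  # at the perfect fit; retry once with a negligible deterministic dither
  try_fit <- function(data) {
    fits <- list(
      two = tryCatch(
        minpack.lm::nlsLM(
          intensity ~ a1 * exp(-(position - mu1)^2 / (2 * s1^2)) +
            a2 * exp(-(position - mu2)^2 / (2 * s2^2)),
          data = data,
          start = list(a1 = a0, mu1 = mu1_0, s1 = s0, a2 = a0 * 0.8,
                       mu2 = mu2_0, s2 = s0),
          lower = c(0, min(x), span / 1e4, 0, min(x), span / 1e4),
          upper = c(Inf, max(x), span, Inf, max(x), span),
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL),
      one = tryCatch(
        minpack.lm::nlsLM(intensity ~ a * exp(-(position - mu)^2 / (2 * s^2)),
                          data = data,
                          start = list(a = a0, mu = mu1_0, s = s0),
                          lower = c(0, min(x), span / 1e4),
                          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL))
    fits
  }
  fits <- try_fit(df)
  if (is.null(fits$two) || is.null(fits$one)) {
    dithered <- df
    eps <- 1e-6 * a0
    dithered$intensity <- dithered$intensity +
      eps * rep_len(c(1, -1), nrow(df))
    retry <- try_fit(dithered)
    if (is.null(fits$two)) fits$two <- retry$two
    if (is.null(fits$one)) fits$one <- retry$one
  }
  fit2 <- fits$two
  fit1 <- fits$one
  if (is.null(fit2) && is.null(fit1)) {
    abort(paste0("profile fit failed to converge (n = ", nrow(df),
                 ", peak guesses at ", signif(mu1_0, 4), " and ",
                 signif(mu2_0, 4), " nm)"),
          class = "smlmdemix_fit_error")
  }
  rss1 <- if (is.null(fit1)) Inf else sum(resid(fit1)^2)
  if (is.null(fit2)) {
    # two-peak model unfittable (e.g. a genuinely single-peaked profile):
    # degenerate result from the single Gaussian
    c1 <- as.list(coef(fit1))
    cf <- list(a1 = c1$a, mu1 = c1$mu, s1 = c1$s,
               a2 = 0, mu2 = c1$mu, s2 = c1$s)
    rss2 <- rss1
    fitted_v <- predict(fit1)
  } else {
    cf <- as.list(coef(fit2))
    if (cf$mu2 < cf$mu1) {
      cf <- cf[c("a2", "mu2", "s2", "a1", "mu1", "s1")]
      names(cf) <- c("a1", "mu1", "s1", "a2", "mu2", "s2")
    }
    rss2 <- sum(resid(fit2)^2)
    fitted_v <- predict(fit2)
  }
  sep <- abs(cf$mu2 - cf$mu1)
  # degenerate when the two means collapse within the fitted widths or a
  # single Gaussian explains the data essentially as well
  degenerate <- sep < (cf$s1 + cf$s2) / 4 ||
    (is.finite(rss1) && rss1 <= rss2 * 1.01)
  structure(list(
    parameters = as_tibble(cf),
    center = (cf$mu1 + cf$mu2) / 2,
    shift = -(cf$mu1 + cf$mu2) / 2,
    separation = sep,
    degenerate = degenerate,
    rss = rss2,
    fitted = tibble(position = x, intensity = yv,
                    fitted = fitted_v)),
    class = "sideview_fit")
}

#' @export
print.sideview_fit <- function(x, ...) {
  cat("Double-Gaussian profile fit: mu = (",
      signif(x$parameters$mu1, 4), ", ", signif(x$parameters$mu2, 4),
      ") nm, center = ", signif(x$center, 4), " nm",
      if (x$degenerate) " [degenerate: single peak]", "\n", sep = "")
  invisible(x)
}

#' @method tidy sideview_fit
#' @export
tidy.sideview_fit <- function(x, ...) {
  tidyr::pivot_longer(x$parameters, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @method glance sideview_fit
#' @export
glance.sideview_fit <- function(x, ...) {
  tibble(center = x$center, separation = x$separation,
         degenerate = x$degenerate, rss = x$rss,
         n = nrow(x$fitted))
}
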