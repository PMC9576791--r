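#' Fit the residual chromatic field of weighted-mean coordinates
#'
#' The weighted-mean fusion of the two channels leaves a residual chromatic
#' shift: the difference between a molecule's weighted-mean and simple-mean
#' positions, \eqn{\Delta x = x_{wm} - x_m}, contains a random part (photon
#' shot noise) and a systematic part \eqn{\Delta x_{chro}} that varies
#' smoothly with position (lateral chromatic aberration plus unequal channel
#' magnification). The simple mean is chromatic-free, so \eqn{\Delta x_{chro}}
#' can be registered from the data alone: it is fitted here as a 2D
#' polynomial of position, separately for the x and y offsets, and
#' subtracted from the weighted-mean coordinates by
#' [demix_coordinates()] with `method = "wmean_chroma"`.
#'
#' @param wmean,mean Data frames (or 2-column matrices) of weighted-mean and
#'   simple-mean positions, same ordering, columns `x`, `y` (nm).
#' @param degree Polynomial degree per axis (default 1: captures lateral
#'   chromatic aberration and unequal magnification).
#' @return Object of class `chromatic_model`: coefficients per axis,
#'   `fit_residual_rms` (nm) and fit size.
#' @export
fit_chromatic_model <- function(wmean, mean, degree = 1) {
  wm <- as.data.frame(wmean); m <- as.data.frame(mean)
  if (is.null(names(wm)) || !all(c("x", "y") %in% names(wm))) {
    names(wm)[1:2] <- c("x", "y")
  }
  if (!all(c("x", "y") %in% names(m))) names(m)[1:2] <- c("x", "y")
  stopifnot(nrow(wm) == nrow(m))
  n_min <- 10 * (degree + 1)^2
  if (nrow(wm) < max(n_min, (degree + 1) * (degree + 2) / 2)) {
    warn(paste0("chromatic fit with fewer than ", n_min, " pairs"))
  }
  X <- poly_design(m$x, m$y, degree)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort(paste0("rank-deficient chromatic design (points collinear?); ",
                 "try a lower degree"),
          class = "smlmdemix_fit_error")
  }
  dx <- wm$x - m$x
  dy <- wm$y - m$y
  fx <- lm.fit(X, dx)
  fy <- lm.fit(X, dy)
  rms <- sqrt(mean(fx$residuals^2 + fy$residuals^2))
  structure(list(degree = degree,
                 coef_x = setNames(fx$coefficients, colnames(X)),
                 coef_y = setNames(fy$coefficients, colnames(X)),
                 fit_residual_rms = rms, n = nrow(wm)),
            class = "chromatic_model")
}

#' Fit chromatic models from assigned pairs
#'
#' Convenience wrapper computing the weighted-mean and simple-mean positions
#' of each pair and fitting [fit_chromatic_model()] per species (the
#' residual shift scales with \eqn{w_L - 1/2} and hence with the species
#' ratio) or pooled over all assigned pairs.
#'
#' @param pairs Pair tibble with a `species` column.
#' @inheritParams fit_chromatic_model
#' @param by_species Fit one model per species (default) or pooled.
#' @return A `chromatic_model`, or a named list of them (class
#'   `chromatic_model_set`) when `by_species = TRUE`.
#' @export
chromatic_from_pairs <- function(pairs, degree = 1, by_species = TRUE) {
  p <- if ("species" %in% names(pairs)) {
    pairs[!is.na(pairs$species), , drop = FALSE]
  } else {
    pairs
  }
  w_l <- p$photons_l / (p$photons_s + p$photons_l)
  wm <- tibble(x = (1 - w_l) * p$x_s + w_l * p$x_l,
               y = (1 - w_l) * p$y_s + w_l * p$y_l)
  m <- tibble(x = (p$x_s + p$x_l) / 2, y = (p$y_s + p$y_l) / 2)
  if (!by_species || !"species" %in% names(p)) {
    return(fit_chromatic_model(wm, m, degree))
  }
  sp <- unique(p$species)
  models <- setNames(lapply(sp, function(s) {
    i <- p$species == s
    fit_chromatic_model(wm[i, ], m[i, ], degree)
  }), sp)
  structure(models, class = "chromatic_model_set")
}

#' Evaluate a chromatic model at positions
#'
#' @param model `chromatic_model` or `chromatic_model_set`.
#' @param x,y Positions (nm).
#' @param species Species labels (required for a model set).
#' @return Tibble with `dx`, `dy` offsets (nm).
#' @export
predict_chromatic <- function(model, x, y, species = NULL) {
  if (inherits(model, "chromatic_model_set")) {
    if (is.null(species)) {
      abort_config("species labels required to evaluate a per-species chromatic model")
    }
    dx <- numeric(length(x)); dy <- numeric(length(x))
    for (s in unique(species)) {
      i <- species == s
      if (!s %in% names(model)) {
        abort_config(paste0("no chromatic model for species '", s, "'"))
      }
      pr <- predict_chromatic(model[[s]], x[i], y[i])
      dx[i] <- pr$dx; dy[i] <- pr$dy
    }
    return(tibble(dx = dx, dy = dy))
  }
  X <- poly_design(x, y, model$degree)
  out <- tibble(dx = as.numeric(X %*% model$coef_x),
                dy = as.numeric(X %*% model$coef_y))
  if (any(!is.finite(out$dx)) || any(!is.finite(out$dy))) {
    abort("chromatic model evaluated to non-finite offsets",
          class = "smlmdemix_fit_error")
  }
  out
}

#' @method tidy chromatic_model
#' @export
tidy.chromatic_model <- function(x, ...) {
  tibble(axis = rep(c("x", "y"), each = length(x$coef_x)),
         term = rep(names(x$coef_x), 2),
         estimate = c(unname(x$coef_x), unname(x$coef_y)))
}

#' @method glance chromatic_model
#' @export
glance.chromatic_model <- function(x, ...) {
  tibble(degree = x$degree, fit_residual_rms = x$fit_residual_rms, n = x$n)
}

#' @method tidy chromatic_model_set
#' @export
tidy.chromatic_model_set <- function(x, ...) {
  bind_rows(lapply(names(x), function(s) {
    out <- tidy.chromatic_model(x[[s]])
    out$species <- s
    out
  }))
}

#' @method glance chromatic_model_set
#' @export
glance.chromatic_model_set <- function(x, ...) {
  bind_rows(lapply(names(x), function(s) {
    out <- glance.chromatic_model(x[[s]])
    out$species <- s
    out
  }))
}

#' @export
print.chromatic_model <- function(x, ...) {
  cat("Chromatic field model (degree ", x$degree, ", n = ", x$n,
      ", residual rms = ", signif(x$fit_residual_rms, 4), " nm)\n", sep = "")
  invisible(x)
}
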