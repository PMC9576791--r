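#' Photon-count ratio of paired localizations
#'
#' The demixing observable: the ratio \eqn{r = I_L / I_S} of a molecule's
#' photon counts in the long- and short-wavelength channels, set by its
#' emission spectrum and the dichroic splitting point.
#'
#' @param pairs Pair tibble from [pair_localizations()] (columns
#'   `photons_s`, `photons_l`).
#' @return Numeric vector of ratios.
#' @export
photon_ratio <- function(pairs) {
  stopifnot(all(pairs$photons_s > 0))
  pairs$photons_l / pairs$photons_s
}

#' Sector regions on the bivariate photon-count histogram
#'
#' A sector assigns paired localizations to a fluorophore species: it is the
#' wedge \eqn{r_{min} \le I_L/I_S < r_{max}} intersected with a total-intensity
#' band \eqn{I_{min} \le I_S + I_L < I_{max}}. The intensity floor removes
#' low-photon localizations that cannot be demixed reliably. Ratio intervals
#' are half-open so that adjacent sectors partition ratio space.
#'
#' @param species Species label.
#' @param r_min,r_max Ratio bounds, `0 <= r_min < r_max` (may be `Inf`).
#' @param i_total_min,i_total_max Total-photon bounds.
#' @return One-row tibble; bind rows to build a sector set.
#' @export
sector_region <- function(species, r_min, r_max, i_total_min = 0,
                          i_total_max = Inf) {
  stopifnot(r_min >= 0, r_min < r_max, i_total_min >= 0,
            i_total_min < i_total_max)
  tibble(species = as.character(species), r_min = r_min, r_max = r_max,
         i_total_min = i_total_min, i_total_max = i_total_max)
}

#' @rdname sector_region
#' @param sectors Tibble of sectors.
#' @export
validate_sectors <- function(sectors) {
  need <- c("species", "r_min", "r_max", "i_total_min")
  if (!all(need %in% names(sectors))) {
    abort_config("sector table must have columns species, r_min, r_max, i_total_min")
  }
  if (!"i_total_max" %in% names(sectors)) sectors$i_total_max <- Inf
  if (anyDuplicated(sectors$species)) abort_config("duplicate sector species")
  n <- nrow(sectors)
  if (n >= 2) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      r_ov <- sectors$r_min[a] < sectors$r_max[b] &&
        sectors$r_min[b] < sectors$r_max[a]
      i_ov <- sectors$i_total_min[a] < sectors$i_total_max[b] &&
        sectors$i_total_min[b] < sectors$i_total_max[a]
      if (r_ov && i_ov) {
        abort_config(paste0("sectors '", sectors$species[a], "' and '",
                            sectors$species[b], "' overlap"))
      }
    }
  }
  sectors
}

#' Read or write sector regions as YAML
#' @param path YAML file: a list of `{species, r_min, r_max, i_total_min[, i_total_max]}`.
#' @export
read_sectors <- function(path) {
  d <- yaml::read_yaml(path)
  validate_sectors(bind_rows(lapply(d, function(s) {
    sector_region(s$species, s$r_min, s$r_max,
                  s$i_total_min %||% 0, s$i_total_max %||% Inf)
  })))
}

#' @rdname read_sectors
#' @param sectors Sector tibble.
#' @export
write_sectors <- function(sectors, path) {
  sectors <- validate_sectors(sectors)
  yaml::write_yaml(lapply(seq_len(nrow(sectors)), function(i) {
    s <- as.list(sectors[i, ])
    if (!is.finite(s$i_total_max)) s$i_total_max <- NULL
    s
  }), path, precision = 15)
  invisible(path)
}

#' Bivariate histogram of per-channel photon counts
#'
#' On this histogram a fixed-ratio species populates a wedge along the line
#' \eqn{I_L = r I_S}; on log-log axes, a band of slope 1 and intercept
#' \eqn{\log r}.
#'
#' @param pairs Pair tibble.
#' @param bins Bins per axis.
#' @param scale `"linear"` or `"log"` (base-10; requires positive counts).
#' @return Object of class `bivar_hist`: `counts` matrix (\eqn{I_S} along
#'   rows), bin `edges_s`, `edges_l`, and the `scale`.
#' @export
bivariate_histogram <- function(pairs, bins = 64, scale = c("linear", "log")) {
  scale <- arg_match(scale)
  stopifnot(bins >= 2)
  is_ <- pairs$photons_s
  il <- pairs$photons_l
  if (scale == "log") {
    stopifnot(all(is_ > 0), all(il > 0))
    is_ <- log10(is_); il <- log10(il)
  }
  if (!length(is_)) {
    edges <- seq(0, 1, length.out = bins + 1)
    return(structure(list(counts = matrix(0L, bins, bins), edges_s = edges,
                          edges_l = edges, scale = scale),
                     class = "bivar_hist"))
  }
  pad <- function(rng) if (diff(rng) == 0) rng + c(-0.5, 0.5) else rng
  rs <- pad(range(is_)); rl <- pad(range(il))
  edges_s <- seq(rs[1], rs[2], length.out = bins + 1)
  edges_l <- seq(rl[1], rl[2], length.out = bins + 1)
  bi <- pmin(pmax(findInterval(is_, edges_s, rightmost.closed = TRUE), 1L), bins)
  bj <- pmin(pmax(findInterval(il, edges_l, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(tabulate(bi + (bj - 1L) * bins, nbins = bins * bins),
                   bins, bins)
  structure(list(counts = counts, edges_s = edges_s, edges_l = edges_l,
                 scale = scale),
            class = "bivar_hist")
}

#' Assign paired localizations to fluorophore species
#'
#' A pair belongs to species `s` iff `r_min(s) <= ratio < r_max(s)` and its
#' total photon count lies in the sector's intensity band; pairs outside all
#' sectors are rejected (`species` is `NA`). The rejected fraction is
#' attached as an attribute.
#'
#' @param pairs Pair tibble.
#' @param sectors Sector tibble (see [sector_region()]); validated for
#'   overlap before any assignment.
#' @return `pairs` with a `species` column; attribute `rejected_fraction`.
#' @export
assign_species <- function(pairs, sectors) {
  sectors <- validate_sectors(sectors)
  r <- pairs$photons_l / pairs$photons_s
  itot <- pairs$photons_s + pairs$photons_l
  species <- rep(NA_character_, nrow(pairs))
  for (k in seq_len(nrow(sectors))) {
    hit <- is.na(species) &
      r >= sectors$r_min[k] & r < sectors$r_max[k] &
      itot >= sectors$i_total_min[k] & itot < sectors$i_total_max[k]
    species[hit] <- sectors$species[k]
  }
  out <- pairs
  out$species <- species
  attr(out, "rejected_fraction") <-
    if (nrow(pairs)) mean(is.na(species)) else 0
  out
}

#' Compute demixed output coordinates
#'
#' Implements the output-coordinate methods for demixed localizations:
#' \describe{
#'   \item{`lambdaS`, `lambdaL`}{coordinates of one input channel only; no
#'     chromatic mixing but the other channel's photons are wasted, so
#'     precision drops to \eqn{\sigma_0/\sqrt{I_c}}.}
#'   \item{`brightest`}{the channel with the larger photon count (ties go to
#'     \eqn{\lambda_S}); different species come from different channels, so
#'     the full inter-channel chromatic offset appears between species.}
#'   \item{`mean`}{simple mean \eqn{(X_S + X_L)/2}; chromatic offsets cancel
#'     identically but precision is sub-optimal unless \eqn{I_S = I_L}.}
#'   \item{`wmean`}{photon-weighted mean \eqn{w_S X_S + w_L X_L} with
#'     \eqn{w_c = I_c/(I_S + I_L)}; the precision of the full photon budget,
#'     \eqn{\sigma_0/\sqrt{I_S + I_L}}, with a small ratio-dependent residual
#'     chromatic shift.}
#'   \item{`wmean_chroma`}{weighted mean minus a fitted polynomial chromatic
#'     field (see [fit_chromatic_model()]): full precision and nanometer-scale
#'     chromatic correction.}
#' }
#' Output photon counts are always \eqn{I_S + I_L}.
#'
#' @param pairs Pair tibble with a `species` column (see [assign_species()]);
#'   rejected pairs (`NA` species) are dropped and counted.
#' @param method One of `"brightest"`, `"lambdaS"`, `"lambdaL"`, `"mean"`,
#'   `"wmean"`, `"wmean_chroma"`.
#' @param chromatic For `wmean_chroma`: a [fit_chromatic_model()] result, a
#'   named list of them (one per species), or `NULL` to fit from `pairs`.
#' @param chroma_degree Polynomial degree when fitting internally.
#' @param by_species Fit the chromatic field separately per species
#'   (default); the residual shift \eqn{(w_L - 1/2)\Delta} depends on the
#'   species ratio, so the pooled alternative cannot separate species with
#'   different ratios.
#' @return Tibble with `species`, `frame`, `x`, `y`, `photons`; attributes
#'   `method`, `n_rejected` and (if fitted) `chromatic_model`.
#' @export
demix_coordinates <- function(pairs,
                              method = c("wmean", "wmean_chroma", "brightest",
                                         "lambdaS", "lambdaL", "mean"),
                              chromatic = NULL, chroma_degree = 1,
                              by_species = TRUE) {
  method <- arg_match(method)
  if (!"species" %in% names(pairs)) {
    abort_config("pairs must carry a species column; run assign_species() first")
  }
  n_rejected <- sum(is.na(pairs$species))
  p <- pairs[!is.na(pairs$species), , drop = FALSE]
  w_l <- p$photons_l / (p$photons_s + p$photons_l)
  xy <- switch(
    method,
    lambdaS = cbind(p$x_s, p$y_s),
    lambdaL = cbind(p$x_l, p$y_l),
    brightest = {
      use_l <- p$photons_l > p$photons_s   # tie -> lambda_S
      cbind(ifelse(use_l, p$x_l, p$x_s), ifelse(use_l, p$y_l, p$y_s))
    },
    mean = cbind((p$x_s + p$x_l) / 2, (p$y_s + p$y_l) / 2),
    wmean = ,
    wmean_chroma = cbind((1 - w_l) * p$x_s + w_l * p$x_l,
                         (1 - w_l) * p$y_s + w_l * p$y_l)
  )
  model <- NULL
  if (method == "wmean_chroma") {
    xm <- (p$x_s + p$x_l) / 2
    ym <- (p$y_s + p$y_l) / 2
    if (is.null(chromatic)) {
      model <- chromatic_from_pairs(p, degree = chroma_degree,
                                    by_species = by_species)
    } else {
      model <- chromatic
    }
    corr <- predict_chromatic(model, x = xm, y = ym, species = p$species)
    xy[, 1] <- xy[, 1] - corr$dx
    xy[, 2] <- xy[, 2] - corr$dy
  }
  out <- tibble(species = p$species, frame = p$frame,
                x = xy[, 1], y = xy[, 2],
                photons = p$photons_s + p$photons_l)
  attr(out, "method") <- method
  attr(out, "n_rejected") <- n_rejected
  if (!is.null(model)) attr(out, "chromatic_model") <- model
  out
}

#' Split a demixed table into per-species localization tables
#'
#' @param demixed Result of [demix_coordinates()].
#' @return Named list of [loc_table()]s, one per species, tagged
#'   `"demixed:<species>"`.
#' @export
demixed_tables <- function(demixed) {
  sp <- unique(demixed$species)
  setNames(lapply(sp, function(s) {
    loc_table(demixed[demixed$species == s,
                      c("frame", "x", "y", "photons"), drop = FALSE],
              source_channel = paste0("demixed:", s))
  }), sp)
}

#' Estimate cross-talk between demixed channels from a single-label sample
#'
#' With a sample labeled by one declared fluorophore, the fraction of its
#' assigned localizations that fall in each sector estimates the cross-talk
#' into the other output channels. Rejected pairs are excluded from the
#' denominator (spurious dim localizations would otherwise inflate the
#' estimate); the rejection fraction is reported alongside.
#'
#' @param pairs Pair tibble from a single-labeled acquisition.
#' @param sectors Sector tibble (at least 2 sectors).
#' @param declared The species actually present, if known; stored on the
#'   result.
#' @return Tibble `species`, `n`, `fraction` (fractions sum to 1 over the
#'   sectors); attributes `declared`, `rejected_fraction`, `n_assigned`.
#' @export
estimate_crosstalk <- function(pairs, sectors, declared = NULL) {
  sectors <- validate_sectors(sectors)
  if (nrow(sectors) < 2) abort_config("cross-talk needs at least 2 sectors")
  lab <- assign_species(pairs, sectors)
  assigned <- lab$species[!is.na(lab$species)]
  if (!length(assigned)) {
    abort("no pairs were assigned to any sector; cross-talk undefined",
          class = "smlmdemix_estimation_error")
  }
  counts <- vapply(sectors$species, function(s) sum(assigned == s), integer(1),
                   USE.NAMES = FALSE)
  out <- tibble(species = sectors$species, n = as.integer(counts),
                fraction = counts / length(assigned))
  attr(out, "declared") <- declared
  attr(out, "rejected_fraction") <- attr(lab, "rejected_fraction")
  attr(out, "n_assigned") <- length(assigned)
  out
}
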