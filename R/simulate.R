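#' Fluorophore species specification for the simulator
#'
#' @param name Species label.
#' @param ratio Channel photon ratio \eqn{r = E[I_L]/E[I_S] > 0}.
#' @param photons Mean total photons per blink event.
#' @param n_emitters Number of emitters of this species.
#' @return One-row tibble; bind rows for several species.
#' @export
species_spec <- function(name, ratio, photons, n_emitters = 1) {
  stopifnot(ratio > 0, photons > 0, n_emitters >= 1)
  tibble(name = as.character(name), ratio = ratio, photons = photons,
         n_emitters = as.integer(n_emitters))
}

#' Simulation configuration for two-channel SMLM acquisitions
#'
#' Describes a synthetic acquisition with the statistical structure the
#' demixing method assumes: every blink event's photon total is split
#' binomially between the channels at the species ratio (so
#' \eqn{I_S + I_L = I} exactly per event and \eqn{E[I_L]/E[I_S] = r}); each
#' channel localization carries shot-noise-limited error
#' \eqn{\sigma_0/\sqrt{I_c}} per axis; the long channel is displaced by a
#' chromatic offset field; emitters blink in geometric-length runs of
#' consecutive frames; and each channel receives independent uniform
#' background localizations.
#'
#' @param species Tibble from [species_spec()] rows.
#' @param fov Field of view `c(xmin, xmax, ymin, ymax)`, nm.
#' @param psf_fwhm PSF full width at half maximum, nm (default 300);
#'   \eqn{\sigma_0 = FWHM / (2\sqrt{2\ln 2})}.
#' @param psf_sigma PSF standard deviation, nm; overrides `psf_fwhm`.
#' @param chromatic Chromatic offset applied to long-channel positions:
#'   constant `c(dx, dy)` nm or a `function(x, y)` returning a 2-column
#'   matrix of offsets.
#' @param n_frames Number of acquisition frames (blinking mode).
#' @param p_on Per-frame per-emitter probability of starting a blink run.
#' @param mean_run Mean run length in frames (geometric).
#' @param detections_per_emitter If set, blinking is replaced by exactly
#'   this many detections per emitter, one event per frame (events of
#'   different emitters interleaved across frames).
#' @param photon_model `"fixed"`, `"poisson"` or `"lognormal"` for the total
#'   photons per event.
#' @param photon_sdlog Lognormal sd (log scale) when
#'   `photon_model = "lognormal"`.
#' @param background_rate Expected spurious localizations per frame, per
#'   channel: `c(s, l)`.
#' @param background_photons Meanlog/sdlog of lognormal background photon
#'   counts.
#' @param threshold Per-channel detection threshold `c(s, l)` in photons;
#'   events below it are omitted from that channel's table (under-detection
#'   creates realistic unpaired localizations).
#' @param positions Optional tibble `species`, `x`, `y` of emitter positions
#'   (default: uniform in the field of view).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(species,
                       fov = c(0, 20000, 0, 20000),
                       psf_fwhm = 300, psf_sigma = NULL,
                       chromatic = c(0, 0),
                       n_frames = 1000, p_on = 1e-4, mean_run = 2,
                       detections_per_emitter = NULL,
                       photon_model = c("lognormal", "fixed", "poisson"),
                       photon_sdlog = 0.5,
                       background_rate = c(0, 0),
                       background_photons = c(meanlog = log(500), sdlog = 0.5),
                       threshold = c(0, 0),
                       positions = NULL) {
  photon_model <- arg_match(photon_model)
  stopifnot(is.data.frame(species), nrow(species) >= 1,
            all(species$ratio > 0), all(species$photons > 0),
            length(fov) == 4, fov[1] < fov[2], fov[3] < fov[4],
            p_on >= 0, p_on <= 1, mean_run >= 1,
            all(background_rate >= 0), all(threshold >= 0))
  sigma0 <- psf_sigma %||% (psf_fwhm / (2 * sqrt(2 * log(2))))
  stopifnot(sigma0 > 0)
  structure(list(species = as_tibble(species), fov = fov, sigma0 = sigma0,
                 chromatic = chromatic, n_frames = n_frames, p_on = p_on,
                 mean_run = mean_run,
                 detections_per_emitter = detections_per_emitter,
                 photon_model = photon_model, photon_sdlog = photon_sdlog,
                 background_rate = background_rate,
                 background_photons = background_photons,
                 threshold = threshold, positions = positions),
            class = "sim_config")
}

# evaluate the chromatic field at positions -> 2-col matrix (dx, dy) nm
chromatic_offset <- function(chromatic, x, y) {
  if (is.function(chromatic)) {
    m <- chromatic(x, y)
    matrix(as.numeric(m), ncol = 2)
  } else {
    cbind(rep(chromatic[1], length(x)), rep(chromatic[2], length(x)))
  }
}

#' Simulate a two-channel SMLM acquisition with ground truth
#'
#' @param config A [sim_config()].
#' @param seed Optional integer; the same seed reproduces the tables
#'   byte-for-byte.
#' @param drift Linear drift `c(dx, dy)` in nm per frame added to true
#'   positions (both channels; see [simulate_drifted_series()]).
#' @return List with `table_s`, `table_l` ([loc_table()]s carrying an extra
#'   `event` id column; background rows have `event = NA`), `truth` (one row
#'   per blink event: `event`, `emitter`, `species`, `frame`, `mu_x`,
#'   `mu_y`, `i_s`, `i_l`, `det_s`, `det_l`) and the `config`.
#' @export
simulate_acquisition <- function(config, seed = NULL, drift = c(0, 0)) {
  stopifnot(inherits(config, "sim_config"), length(drift) == 2,
            all(is.finite(drift)))
  with_opt_seed(seed, function() simulate_impl(config, drift))
}

simulate_impl <- function(config, drift) {
  sp <- config$species
  fov <- config$fov
  # emitter positions
  if (is.null(config$positions)) {
    em <- bind_rows(lapply(seq_len(nrow(sp)), function(k) {
      tibble(species = sp$name[k],
             x = runif(sp$n_emitters[k], fov[1], fov[2]),
             y = runif(sp$n_emitters[k], fov[3], fov[4]))
    }))
  } else {
    em <- as_tibble(config$positions)
  }
  em$emitter <- seq_len(nrow(em))
  em <- left_join(em, sp[, c("name", "ratio", "photons")],
                  by = c(species = "name"))

  # blink events: (emitter, frame)
  if (!is.null(config$detections_per_emitter)) {
    k <- config$detections_per_emitter
    ne <- nrow(em)
    ev <- tibble(emitter = rep(em$emitter, times = k),
                 det = rep(seq_len(k), each = ne))
    # one event per frame, emitters interleaved
    ev$frame <- (ev$det - 1) * ne + ev$emitter
    n_frames <- ne * k
  } else {
    n_frames <- config$n_frames
    ev <- bind_rows(lapply(em$emitter, function(e) {
      n_runs <- rbinom(1, n_frames, config$p_on)
      if (!n_runs) return(NULL)
      starts <- sample.int(n_frames, n_runs)
      lens <- 1 + rgeom(n_runs, prob = 1 / config$mean_run)
      frames <- unlist(lapply(seq_len(n_runs), function(j) {
        seq(starts[j], min(starts[j] + lens[j] - 1, n_frames))
      }))
      tibble(emitter = e, frame = sort(unique(frames)))
    }))
    if (is.null(ev) || !nrow(ev)) {
      ev <- tibble(emitter = integer(), frame = integer())
    }
  }

  n_ev <- nrow(ev)
  idx <- match(ev$emitter, em$emitter)
  mu_x <- em$x[idx] + drift[1] * ev$frame
  mu_y <- em$y[idx] + drift[2] * ev$frame
  ratio <- em$ratio[idx]
  mean_ph <- em$photons[idx]

  i_tot <- switch(config$photon_model,
                  fixed = round(mean_ph),
                  poisson = rpois(n_ev, mean_ph),
                  lognormal = round(rlnorm(
                    n_ev,
                    meanlog = log(mean_ph) - config$photon_sdlog^2 / 2,
                    sdlog = config$photon_sdlog)))
  i_tot <- pmax(i_tot, 0)
  i_l <- rbinom(n_ev, i_tot, ratio / (1 + ratio))
  i_s <- i_tot - i_l

  off <- chromatic_offset(config$chromatic, mu_x, mu_y)
  sigma0 <- config$sigma0
  det_s <- i_s > 0 & i_s >= config$threshold[1]
  det_l <- i_l > 0 & i_l >= config$threshold[2]
  x_s <- mu_x + rnorm(n_ev) * sigma0 / sqrt(pmax(i_s, 1))
  y_s <- mu_y + rnorm(n_ev) * sigma0 / sqrt(pmax(i_s, 1))
  x_l <- mu_x + off[, 1] + rnorm(n_ev) * sigma0 / sqrt(pmax(i_l, 1))
  y_l <- mu_y + off[, 2] + rnorm(n_ev) * sigma0 / sqrt(pmax(i_l, 1))

  truth <- tibble(event = seq_len(n_ev), emitter = ev$emitter,
                  species = em$species[idx], frame = ev$frame,
                  mu_x = mu_x, mu_y = mu_y,
                  i_s = as.numeric(i_s), i_l = as.numeric(i_l),
                  det_s = det_s, det_l = det_l)

  bg <- function(rate) {
    n_bg <- rpois(1, rate * n_frames)
    tibble(frame = sample.int(max(n_frames, 1), n_bg, replace = TRUE),
           x = runif(n_bg, fov[1], fov[2]),
           y = runif(n_bg, fov[3], fov[4]),
           photons = pmax(round(rlnorm(n_bg,
                                       config$background_photons[["meanlog"]],
                                       config$background_photons[["sdlog"]])),
                          1),
           event = NA_integer_)
  }
  tab_s <- bind_rows(
    tibble(frame = ev$frame[det_s], x = x_s[det_s], y = y_s[det_s],
           photons = as.numeric(i_s[det_s]), event = truth$event[det_s]),
    bg(config$background_rate[1]))
  tab_l <- bind_rows(
    tibble(frame = ev$frame[det_l], x = x_l[det_l], y = y_l[det_l],
           photons = as.numeric(i_l[det_l]), event = truth$event[det_l]),
    bg(config$background_rate[2]))

  list(table_s = loc_table(tab_s, source_channel = "S"),
       table_l = loc_table(tab_l, source_channel = "L"),
       truth = truth, config = config)
}

#' Preset: two co-located species imaged through the splitter
#'
#' The canonical demixing stress test: two fluorophore species with channel
#' ratios 0.6 and 3.5 at the same true position, a fixed total of 2000
#' photons per event, a 300 nm FWHM PSF, and a constant chromatic offset of
#' (24, 8) nm applied to the long channel. Each species is detected
#' `n_detections` times (in both channels; no background, no threshold).
#' With this preset the output methods separate cleanly: `mean` cancels the
#' chromatic offset between the species, `brightest` shows the full
#' (24, 8) nm inter-species shift, and `wmean` keeps the full-photon-budget
#' precision with a reduced, correctable shift.
#'
#' @param n_detections Detections per species.
#' @param position True emitter position `c(x, y)`, nm.
#' @return A [sim_config()].
#' @export
two_species_scenario <- function(n_detections = 50, position = c(0, 0)) {
  sp <- bind_rows(species_spec("red", 0.6, 2000),
                  species_spec("blue", 3.5, 2000))
  sim_config(
    species = sp,
    fov = c(position[1] - 1000, position[1] + 1000,
            position[2] - 1000, position[2] + 1000),
    psf_fwhm = 300,
    chromatic = c(24, 8),
    detections_per_emitter = n_detections,
    photon_model = "fixed",
    background_rate = c(0, 0),
    threshold = c(0, 0),
    positions = tibble(species = c("red", "blue"),
                       x = position[1], y = position[2])
  )
}

#' @rdname two_species_scenario
#' @param boundary Sector boundary ratio; defaults to the geometric mean of
#'   the two species ratios, sqrt(0.6 * 3.5).
#' @param i_total_min Intensity floor of both sectors.
#' @export
two_species_sectors <- function(boundary = sqrt(0.6 * 3.5), i_total_min = 0) {
  bind_rows(sector_region("red", 0, boundary, i_total_min),
            sector_region("blue", boundary, Inf, i_total_min))
}

#' Simulate an acquisition with linear stage drift
#'
#' Adds `frame * drift_nm_per_frame` to every true position before the
#' localization noise is drawn; fixture for [estimate_drift()].
#'
#' @inheritParams simulate_acquisition
#' @param drift_nm_per_frame `c(dx, dy)` in nm per frame.
#' @export
simulate_drifted_series <- function(config, drift_nm_per_frame, seed = NULL) {
  simulate_acquisition(config, seed = seed, drift = drift_nm_per_frame)
}
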