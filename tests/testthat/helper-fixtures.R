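# Shared fixture builders (all data generated in code).

tiny_table <- function(frame, x, y, photons = 1000, ...) {
  loc_table(tibble::tibble(frame = frame, x = x, y = y, photons = photons, ...))
}

random_table <- function(n, fov = c(0, 10000, 0, 10000), frames = n,
                         photons_range = c(500, 3000)) {
  tiny_table(frame = sample.int(frames, n, replace = TRUE),
             x = runif(n, fov[1], fov[2]),
             y = runif(n, fov[3], fov[4]),
             photons = round(runif(n, photons_range[1], photons_range[2])))
}

# Grid of well-separated emitters blinking in runs of `run_len` consecutive
# frames, runs separated by a one-frame gap; localization noise sd follows
# the photon budget. Returns a loc_table with an `emitter` column.
grid_blink_table <- function(n_side = 10, spacing = 500, n_runs = 5,
                             run_len = 2, photons = 1000, sigma_psf = 140) {
  em <- expand.grid(ex = seq_len(n_side), ey = seq_len(n_side))
  em$x <- em$ex * spacing
  em$y <- em$ey * spacing
  ne <- nrow(em)
  sd0 <- sigma_psf / sqrt(photons)
  rows <- lapply(seq_len(n_runs), function(j) {
    f0 <- (run_len + 1) * (j - 1) + 1
    tibble::tibble(
      frame = rep(f0:(f0 + run_len - 1), each = ne),
      x = rep(em$x, run_len) + stats::rnorm(run_len * ne, 0, sd0),
      y = rep(em$y, run_len) + stats::rnorm(run_len * ne, 0, sd0),
      photons = photons,
      emitter = rep(seq_len(ne), run_len))
  })
  loc_table(dplyr::bind_rows(rows))
}

# ground-truth species of each pair, via the simulator's event ids
pair_truth_species <- function(sim, pairs) {
  ev <- sim$table_s$event[pairs$id_s]
  sim$truth$species[match(ev, sim$truth$event)]
}

expect_within <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", object, tol, expected))
}
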