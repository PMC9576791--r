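test_that("histogram rendering bins with floor on half-open pixels", {
  tab <- tiny_table(1, 12.4, 3.0)
  img <- render_histogram(tab, pixel_size = 5, bounds = c(0, 20, 0, 20))
  expect_equal(img$counts[3, 1], 1L)    # zero-based pixel (2, 0)
  expect_equal(sum(img$counts), 1)

  # a localization exactly on a pixel boundary goes to the upper pixel
  edge <- render_histogram(tiny_table(1, 5, 0), 5, bounds = c(0, 20, 0, 20))
  expect_equal(edge$counts[2, 1], 1L)

  withr::local_seed(71)
  many <- random_table(5000, fov = c(0, 1000, 0, 1000))
  expect_equal(sum(render_histogram(many, 5)$counts), 5000)

  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(render_histogram(many, 20), path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("FRC is 1 for identical halves and ~0 for independent noise", {
  withr::local_seed(72)
  tab <- random_table(4000, fov = c(0, 2000, 0, 2000))
  img <- render_histogram(tab, 5)
  cv <- frc_curve(img, img, n_steps = 40)
  expect_true(all(abs(cv$frc[is.finite(cv$frc)] - 1) < 1e-9))

  a <- render_histogram(random_table(4000, fov = c(0, 2000, 0, 2000)), 5,
                        bounds = c(0, 2000, 0, 2000))
  b <- render_histogram(random_table(4000, fov = c(0, 2000, 0, 2000)), 5,
                        bounds = c(0, 2000, 0, 2000))
  cv2 <- frc_curve(a, b, n_steps = 40)
  high <- cv2$frc[cv2$freq > 0.02 & is.finite(cv2$frc)]
  expect_lt(max(abs(high)), 0.2)
})

test_that("FRC resolution is translation invariant and degrades with blur", {
  make_grid <- function(sdv, shift = 0) {
    em <- expand.grid(x = seq(100, 3000, by = 150),
                      y = seq(100, 3000, by = 150))
    n <- nrow(em) * 30
    tiny_table(frame = rep(1:30, each = nrow(em)),
               x = rep(em$x, 30) + rnorm(n, 0, sdv) + shift,
               y = rep(em$y, 30) + rnorm(n, 0, sdv) + shift)
  }
  withr::local_seed(73)
  sharp <- make_grid(5)
  blurred <- make_grid(20)
  f_sharp <- frc_resolution(sharp, n_repeats = 5, seed = 7)
  f_blur <- frc_resolution(blurred, n_repeats = 5, seed = 7)
  expect_lt(f_sharp$mean, f_blur$mean)

  # common translation of the data leaves the resolution unchanged
  moved <- sharp
  moved$x <- moved$x + 12345
  moved$y <- moved$y - 321
  f_moved <- frc_resolution(moved, n_repeats = 5, seed = 7)
  expect_equal(f_moved$mean, f_sharp$mean, tolerance = 1e-9)

  gl <- glance(f_sharp)
  expect_equal(gl$n_repeats, 5)
  expect_equal(nrow(tidy(f_sharp)), 5)
  expect_error(frc_resolution(tiny_table(1, 0, 0)),
               class = "smlmdemix_config_error")

  path <- withr::local_tempfile(fileext = ".csv")
  write_frc_curves(f_sharp, path)
  expect_true(all(c("freq_per_nm", "frc_mean", "frc_sd") %in%
                    names(readr::read_csv(path, show_col_types = FALSE))))
})

test_that("radial profiles are annulus-normalized densities", {
  withr::local_seed(74)
  # uniform disc -> flat density profile
  n <- 2e5
  r <- 100 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  prof <- radial_distribution(tibble::tibble(x = r * cos(th), y = r * sin(th)),
                              bin_width = 10, r_max = 100)
  expect_lt(sd(prof$density) / mean(prof$density), 0.05)
  # densities integrate back to the point count
  expect_equal(sum(prof$density * pi * (prof$r_max^2 - prof$r_min^2)), n)

  # all mass at radius 75 lands in the bin containing 75
  ring <- radial_distribution(tibble::tibble(x = 75 * cos(th[1:100]),
                                             y = 75 * sin(th[1:100])),
                              bin_width = 10, r_max = 130)
  expect_equal(sum(ring$count > 0), 1)
  expect_equal(ring$count[ring$r_min <= 75 & ring$r_max > 75], 100)

  empty <- radial_distribution(tibble::tibble(x = numeric(), y = numeric()))
  expect_true(all(empty$density == 0))

  # per-particle centers
  locs <- tibble::tibble(particle = c(1, 1, 2), x = c(10, 20, 110),
                         y = c(0, 0, 0))
  centers <- tibble::tibble(particle = c(1, 2), x = c(0, 100), y = c(0, 0))
  prof2 <- radial_distribution(locs, centers, bin_width = 5, r_max = 50)
  expect_equal(sum(prof2$count), 3)
})

test_that("double-Gaussian side-view profiles are fitted and centered", {
  xp <- seq(-100, 100, by = 2.5)
  withr::local_seed(75)
  yp <- 1000 * exp(-(xp + 25)^2 / 200) + 900 * exp(-(xp - 25)^2 / 200) +
    rnorm(length(xp), 0, 10)
  fit <- fit_sideview_profile(tibble::tibble(position = xp, intensity = yp))
  expect_within(fit$separation, 50, 2.5)
  expect_false(fit$degenerate)
  expect_equal(fit$shift, -fit$center)

  # symmetric profile -> center at the axis midpoint
  ys <- 1000 * exp(-(xp + 30)^2 / 450) + 1000 * exp(-(xp - 30)^2 / 450)
  fit_sym <- fit_sideview_profile(tibble::tibble(position = xp, intensity = ys))
  expect_within(fit_sym$center, 0, 0.5)

  # single-Gaussian input flagged degenerate
  y1 <- 800 * exp(-xp^2 / 500)
  fit1 <- fit_sideview_profile(tibble::tibble(position = xp, intensity = y1))
  expect_true(fit1$degenerate)

  expect_equal(nrow(tidy(fit)), 6)
  expect_true(is.numeric(glance(fit)$center))
  expect_error(fit_sideview_profile(tibble::tibble(position = 1:4,
                                                   intensity = 1:4)),
               class = "smlmdemix_config_error")
})

test_that("average wavelength is the centroid of the effective spectrum", {
  # flat emission on [700, 720] with unit transmission: centroid 710
  box <- spectrum(seq(700, 720, by = 1), rep(1, 21))
  expect_within(average_wavelength(box), 710, 1e-6)

  # narrow peak converges on its location
  for (w in c(5, 1, 0.5)) {
    pk <- spectrum(c(680 - w, 680, 680 + w), c(0, 1, 0))
    expect_within(average_wavelength(pk), 680, 0.5)
  }

  # flat emission through a step filter passing [630, 690]: centroid 660
  flat <- spectrum(seq(630, 800, by = 1), rep(1, 171))
  step <- spectrum(c(630, 689.99, 690.01, 800), c(1, 1, 0, 0))
  expect_within(average_wavelength(flat, list(step)), 660, 0.1)

  # scale invariance in every factor
  l0 <- average_wavelength(flat, list(step))
  flat10 <- spectrum(flat$wavelength, flat$value * 10)
  step03 <- spectrum(step$wavelength, step$value * 0.3)
  expect_equal(average_wavelength(flat10, list(step03)), l0,
               tolerance = 1e-12)

  # zero overlap -> undefined
  blue <- spectrum(seq(400, 500, by = 1), rep(1, 101))
  expect_error(average_wavelength(blue),
               class = "smlmdemix_estimation_error")

  # spectrum files parse from two-column text
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("650 0.1", "660 0.9", "670 0.4"), path)
  sp <- read_spectrum(path)
  expect_equal(sp$wavelength, c(650, 660, 670))
  expect_error(spectrum(c(650, 650), c(1, 1)),
               class = "smlmdemix_format_error")
})
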