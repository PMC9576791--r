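make_pairs <- function(frame = 1, x_s = 0, y_s = 0, x_l = 0, y_l = 0,
                       photons_s = 1000, photons_l = 1000, species = NULL) {
  out <- tibble::tibble(frame = frame, x_s = x_s, y_s = y_s, x_l = x_l,
                        y_l = y_l, photons_s = photons_s,
                        photons_l = photons_l,
                        ratio = photons_l / photons_s)
  if (!is.null(species)) out$species <- species
  out
}

test_that("photon ratio is the exact per-pair channel quotient", {
  p <- make_pairs(photons_s = c(1000, 1000, 1000),
                  photons_l = c(600, 1000, 3500))
  expect_equal(photon_ratio(p), c(0.6, 1, 3.5))
})

test_that("bivariate histogram conserves counts and resolves ratio ridges", {
  p <- make_pairs(frame = 1:100, photons_s = 1000, photons_l = 1000)
  h <- bivariate_histogram(p, bins = 16)
  expect_equal(sum(h$counts), 100)
  expect_equal(max(h$counts), 100)   # all pairs in one bin

  h0 <- bivariate_histogram(make_pairs()[0, ], bins = 8)
  expect_equal(sum(h0$counts), 0)

  # two binomially split species populate ridges along I_L = r * I_S
  withr::local_seed(9)
  n <- 2000
  itot <- round(stats::rlnorm(2 * n, log(2000), 0.3))
  r_true <- rep(c(0.6, 3.5), each = n)
  il <- stats::rbinom(2 * n, itot, r_true / (1 + r_true))
  p2 <- make_pairs(frame = seq_len(2 * n), photons_s = itot - il,
                   photons_l = pmax(il, 1))
  h2 <- bivariate_histogram(p2, bins = 48)
  cs <- (h2$edges_s[-1] + h2$edges_s[-49]) / 2
  cl <- (h2$edges_l[-1] + h2$edges_l[-49]) / 2
  grid <- expand.grid(i_s = cs, i_l = cl)
  grid$n <- as.vector(h2$counts)
  grid$r <- grid$i_l / grid$i_s
  b <- sqrt(0.6 * 3.5)
  slope <- function(g) sum(g$n * g$i_s * g$i_l) / sum(g$n * g$i_s^2)
  expect_within(slope(grid[grid$r < b & grid$n > 0, ]), 0.6, 0.6 * 0.05)
  expect_within(slope(grid[grid$r >= b & grid$n > 0, ]), 3.5, 3.5 * 0.05)
})

test_that("sector assignment follows ratio and intensity bounds", {
  sectors <- dplyr::bind_rows(
    sector_region("A", 0.3, 1.0, i_total_min = 500),
    sector_region("B", 1.0, 4.0, i_total_min = 500))
  p <- make_pairs(frame = 1:3,
                  photons_s = c(1250, 188, 400),
                  photons_l = c(750, 112, 1400))
  lab <- assign_species(p, sectors)
  expect_equal(lab$species, c("A", NA, "B"))     # row 2: I_total 300 < 500
  expect_equal(attr(lab, "rejected_fraction"), 1 / 3)

  # ratio exactly at r_max falls outside the sector (half-open)
  p_edge <- make_pairs(photons_s = 1000, photons_l = 1000)
  expect_equal(assign_species(p_edge, sectors)$species, "B")

  overlapping <- dplyr::bind_rows(
    sector_region("A", 0.3, 1.5), sector_region("B", 1.0, 4.0))
  expect_error(assign_species(p, overlapping),
               class = "smlmdemix_config_error")
  # non-overlap can also come from disjoint intensity bands
  banded <- dplyr::bind_rows(
    sector_region("A", 0.3, 1.5, 0, 1000), sector_region("B", 1.0, 4.0, 1000))
  expect_silent(validate_sectors(banded))
})

test_that("sector sets round trip through YAML", {
  sectors <- two_species_sectors(i_total_min = 500)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sectors(sectors, path)
  back <- read_sectors(path)
  expect_equal(back$species, sectors$species)
  expect_equal(back$r_min, sectors$r_min)
  expect_equal(back$i_total_max, c(Inf, Inf))
})

test_that("output coordinate methods implement the documented arithmetic", {
  p <- make_pairs(x_s = 0, y_s = 0, x_l = 24, y_l = 8,
                  photons_s = 1000, photons_l = 1000, species = "a")
  expect_equal(unlist(demix_coordinates(p, "wmean")[, c("x", "y")]),
               c(x = 12, y = 4))          # equal weights = simple mean
  expect_equal(unlist(demix_coordinates(p, "mean")[, c("x", "y")]),
               c(x = 12, y = 4))
  expect_equal(unlist(demix_coordinates(p, "brightest")[, c("x", "y")]),
               c(x = 0, y = 0))           # tie resolves to lambda_S

  p2 <- make_pairs(x_s = 0, y_s = 0, x_l = 24, y_l = 8,
                   photons_s = 500, photons_l = 1500, species = "a")
  expect_equal(unlist(demix_coordinates(p2, "wmean")[, c("x", "y")]),
               c(x = 18, y = 6))          # w_L = 0.75
  expect_equal(unlist(demix_coordinates(p2, "brightest")[, c("x", "y")]),
               c(x = 24, y = 8))
  expect_equal(unlist(demix_coordinates(p2, "lambdaS")[, c("x", "y")]),
               c(x = 0, y = 0))
  expect_equal(unlist(demix_coordinates(p2, "lambdaL")[, c("x", "y")]),
               c(x = 24, y = 8))

  expect_error(demix_coordinates(p2, "median"))
  expect_error(demix_coordinates(make_pairs(), "wmean"),
               class = "smlmdemix_config_error")  # no species column
})

test_that("every method conserves the summed photon count per pair", {
  withr::local_seed(15)
  n <- 500
  p <- make_pairs(frame = 1:n,
                  x_s = runif(n, 0, 1000), y_s = runif(n, 0, 1000),
                  x_l = runif(n, 0, 1000), y_l = runif(n, 0, 1000),
                  photons_s = round(runif(n, 100, 3000)),
                  photons_l = round(runif(n, 100, 3000)),
                  species = sample(c("a", "b"), n, replace = TRUE))
  for (m in c("brightest", "lambdaS", "lambdaL", "mean", "wmean")) {
    dm <- demix_coordinates(p, m)
    expect_equal(dm$photons, p$photons_s + p$photons_l)
    expect_equal(nrow(dm), n)
  }
  # species splitting conserves counts
  tabs <- demixed_tables(demix_coordinates(p, "wmean"))
  expect_equal(sum(vapply(tabs, nrow, 1L)), n)
  expect_equal(attr(tabs[["a"]], "source_channel"), "demixed:a")
})

test_that("cross-talk estimation counts sector assignments correctly", {
  sectors <- two_species_sectors()
  # all pairs inside their own sector
  p <- make_pairs(frame = 1:50, photons_s = 1250, photons_l = 750)
  ct <- estimate_crosstalk(p, sectors, declared = "red")
  expect_equal(ct$fraction[ct$species == "red"], 1)
  expect_equal(ct$fraction[ct$species == "blue"], 0)

  # pairs spanning both sectors: fractions are a proper distribution
  p2 <- make_pairs(frame = 1:100, photons_s = 1000,
                   photons_l = round(seq(200, 3800, length.out = 100)))
  ct2 <- estimate_crosstalk(p2, sectors)
  expect_equal(sum(ct2$fraction), 1)
  expect_equal(sum(ct2$n), attr(ct2, "n_assigned"))

  # nothing assigned -> undefined
  low <- dplyr::bind_rows(sector_region("red", 0, 1, 1e6),
                          sector_region("blue", 1, Inf, 1e6))
  expect_error(estimate_crosstalk(p, low),
               class = "smlmdemix_estimation_error")
  expect_error(estimate_crosstalk(p, sectors[1, ]),
               class = "smlmdemix_config_error")
})
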