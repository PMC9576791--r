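test_that("photon totals split exactly between the channels", {
  cfg <- sim_config(species = species_spec("a", 1, 2000, 5),
                    fov = c(0, 1000, 0, 1000),
                    detections_per_emitter = 200, photon_model = "fixed")
  sim <- simulate_acquisition(cfg, seed = 81)
  expect_true(all(sim$truth$i_s + sim$truth$i_l == 2000))
  expect_within(mean(sim$truth$i_l), 1000, 15)
  expect_within(mean(sim$truth$i_s), 1000, 15)

  # lognormal totals still split exactly per event
  cfg2 <- sim_config(species = species_spec("a", 0.6, 2000, 5),
                     fov = c(0, 1000, 0, 1000),
                     detections_per_emitter = 200,
                     photon_model = "lognormal", photon_sdlog = 0.4)
  sim2 <- simulate_acquisition(cfg2, seed = 82)
  tot <- sim2$truth$i_s + sim2$truth$i_l
  expect_true(all(sim2$table_s$photons ==
                    sim2$truth$i_s[match(sim2$table_s$event, sim2$truth$event)]))
  expect_gt(sd(tot), 0)
})

test_that("the empirical channel ratio matches the species ratio", {
  cfg <- sim_config(species = species_spec("b", 3.5, 2000, 100),
                    fov = c(0, 20000, 0, 20000),
                    detections_per_emitter = 100, photon_model = "fixed")
  sim <- simulate_acquisition(cfg, seed = 83)
  expect_within(median(sim$truth$i_l / sim$truth$i_s), 3.5, 0.02 * 3.5)
})

test_that("per-channel localization errors follow sigma0/sqrt(I_c)", {
  cfg <- sim_config(species = species_spec("a", 0.6, 2000, 1),
                    fov = c(-100, 100, -100, 100),
                    detections_per_emitter = 1e5, photon_model = "fixed",
                    positions = tibble::tibble(species = "a", x = 0, y = 0))
  sim <- simulate_acquisition(cfg, seed = 84)
  sigma0 <- cfg$sigma0
  expect_within(sd(sim$table_s$x), sigma0 / sqrt(2000 / 1.6),
                0.03 * sigma0 / sqrt(2000 / 1.6))
  expect_within(sd(sim$table_l$y), sigma0 / sqrt(2000 * 0.6 / 1.6),
                0.03 * sigma0 / sqrt(2000 * 0.6 / 1.6))
})

test_that("simulations are reproducible from the seed", {
  cfg <- sim_config(species = species_spec("a", 1, 1500, 20),
                    n_frames = 300, p_on = 2e-3,
                    background_rate = c(0.5, 0.5))
  s1 <- simulate_acquisition(cfg, seed = 85)
  s2 <- simulate_acquisition(cfg, seed = 85)
  expect_identical(as.data.frame(s1$table_s), as.data.frame(s2$table_s))
  expect_identical(as.data.frame(s1$table_l), as.data.frame(s2$table_l))
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  s3 <- simulate_acquisition(cfg, seed = 86)
  expect_false(identical(as.data.frame(s1$table_s), as.data.frame(s3$table_s)))
})

test_that("a closed system pairs completely", {
  cfg <- sim_config(species = species_spec("a", 1, 2000, 1),
                    fov = c(0, 100, 0, 100),
                    detections_per_emitter = 100, photon_model = "fixed",
                    positions = tibble::tibble(species = "a", x = 50, y = 50))
  sim <- simulate_acquisition(cfg, seed = 87)
  expect_equal(nrow(sim$table_s), 100)
  expect_equal(nrow(sim$table_l), 100)
  pr <- pair_localizations(sim$table_s, sim$table_l, tolerance = 100)
  expect_equal(nrow(pr$pairs), 100)
})

test_that("detection thresholds create unpaired localizations", {
  cfg <- sim_config(species = species_spec("dim", 0.25, 600, 50),
                    fov = c(0, 20000, 0, 20000),
                    detections_per_emitter = 50, photon_model = "fixed",
                    threshold = c(0, 150))
  sim <- simulate_acquisition(cfg, seed = 88)
  # r = 0.25 -> E[I_L] = 120 < threshold 150: many events missing from L
  expect_lt(nrow(sim$table_l), nrow(sim$table_s))
  expect_true(all(sim$table_l$photons >= 150))
})

test_that("the two-species preset encodes the stated conditions", {
  cfg <- two_species_scenario(50)
  expect_within(cfg$sigma0, 300 / 2.3548, 0.01)
  expect_equal(sort(cfg$species$ratio), c(0.6, 3.5))
  expect_equal(cfg$species$photons, c(2000, 2000))
  expect_equal(cfg$chromatic, c(24, 8))
  sim <- simulate_acquisition(cfg, seed = 89)
  expect_equal(nrow(sim$truth), 100)
  # with the simple mean the inter-species centroid offset vanishes
  pr <- pair_localizations(sim$table_s, sim$table_l, tolerance = 100)
  lab <- assign_species(pr$pairs, two_species_sectors())
  dm <- demix_coordinates(lab, "mean")
  cen <- tapply(dm$x, dm$species, mean)
  # Monte-Carlo error at 50 detections/species: se ~ sqrt(2) * sigma/sqrt(50)
  expect_lt(abs(cen[["blue"]] - cen[["red"]]), 4 * sqrt(2) * 3 / sqrt(50) + 1)
})

test_that("linear drift enters the ground truth and the tables", {
  cfg <- sim_config(species = species_spec("a", 1, 2000, 10),
                    fov = c(0, 2000, 0, 2000), n_frames = 1000, p_on = 5e-3,
                    photon_model = "fixed")
  s0 <- simulate_drifted_series(cfg, c(0, 0), seed = 90)
  s1 <- simulate_acquisition(cfg, seed = 90)
  expect_identical(as.data.frame(s0$table_s), as.data.frame(s1$table_s))

  sd_ <- simulate_drifted_series(cfg, c(0.01, 0), seed = 90)
  shift <- sd_$truth$mu_x - s1$truth$mu_x
  expect_equal(shift, 0.01 * sd_$truth$frame)
})

test_that("end-to-end species recovery error matches the cross-talk estimate", {
  cfg <- sim_config(
    species = dplyr::bind_rows(species_spec("red", 0.6, 2000, 50),
                               species_spec("blue", 3.5, 2000, 50)),
    fov = c(0, 20000, 0, 20000), detections_per_emitter = 40,
    photon_model = "fixed")
  sim <- simulate_acquisition(cfg, seed = 91)
  pr <- pair_localizations(sim$table_s, sim$table_l, tolerance = 100)
  lab <- assign_species(pr$pairs, two_species_sectors())
  truth_sp <- pair_truth_species(sim, pr$pairs)
  ok <- !is.na(lab$species)
  mis <- mean(lab$species[ok] != truth_sp[ok])
  expect_lt(mis, 0.02)
  # against the cross-talk estimator run on each single-species subset
  for (sp in c("red", "blue")) {
    ct <- estimate_crosstalk(pr$pairs[truth_sp == sp, ], two_species_sectors(),
                             declared = sp)
    other <- setdiff(c("red", "blue"), sp)
    mis_sp <- mean(lab$species[ok & truth_sp == sp] == other)
    expect_within(ct$fraction[ct$species == other], mis_sp, 0.005)
  }
})
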