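test_that("conduit population matches requested moments and stays separated", {
  pop <- sample_conduit_population(500, 96, 66, field_um = 900, seed = 101)
  expect_equal(nrow(pop), 500)
  expect_gt(mean(pop$area_um2), 90)
  expect_lt(mean(pop$area_um2), 102)
  expect_gt(sd(pop$area_um2), 56)
  expect_lt(sd(pop$area_um2), 76)
  expect_true(all(pop$area_um2 > 0))
  # pairwise non-overlap of lumen disks
  r <- sqrt(pop$area_um2 / pi)
  d2 <- as.matrix(dist(cbind(pop$center_x_um, pop$center_y_um)))
  rr <- outer(r, r, `+`)
  diag(d2) <- Inf
  expect_true(all(d2 > rr - 1e-9))
})

test_that("population generator handles the empty case and is deterministic", {
  expect_equal(nrow(sample_conduit_population(0)), 0)
  a <- sample_conduit_population(40, 96, 66, field_um = 200, seed = 7)
  b <- sample_conduit_population(40, 96, 66, field_um = 200, seed = 7)
  expect_identical(a, b)
  expect_error(sample_conduit_population(500, 96, 66, field_um = 100, seed = 1),
               "dense|fit")
})

test_that("embolism thresholds realise the logistic law", {
  pop <- sample_conduit_population(10000, 96, 66, field_um = 4000, seed = 3)
  b <- -2.5; S <- 50
  pop <- assign_embolism_thresholds(pop, b, S, seed = 4)
  expect_true(all(is.finite(pop$embolism_threshold_MPa)))
  # at psi = b half the conduits are embolized (median of the logistic)
  expect_equal(mean(is_embolized(pop, b)), 0.5, tolerance = 0.04)
  # at psi = b - 25*ln(3)/S the expected fraction is 0.75 (logistic survival)
  psi75 <- b - 25 * log(3) / S
  expect_equal(mean(is_embolized(pop, psi75)), 0.75, tolerance = 0.04)
  # thresholds independent of conduit area
  expect_lt(abs(cor(pop$area_um2, pop$embolism_threshold_MPa)), 0.03)
  expect_error(assign_embolism_thresholds(pop, -2, S = -5), "positive")
  expect_error(assign_embolism_thresholds(pop, 1, S = 50), "negative")
})

test_that("mean embolized fraction is non-increasing in psi", {
  pop <- sample_conduit_population(3000, 96, 66, field_um = 2200, seed = 8)
  pop <- assign_embolism_thresholds(pop, -3, 30, seed = 9)
  fracs <- vapply(seq(-0.5, -8, by = -1.5),
                  function(p) mean(is_embolized(pop, p)), numeric(1))
  expect_true(all(diff(fracs) >= 0))  # psi grid is decreasing
})

test_that("scan pair renders embolism state and is deterministic", {
  pair <- make_test_pair(n = 15, psi = -3, seed = 21)
  expect_s3_class(pair$truth, "tbl_df")
  expect_true(all(pair$truth$embolized[is_embolized(pair$truth, -3)]))
  pair2 <- make_test_pair(n = 15, psi = -3, seed = 21)
  expect_identical(pair$image_pre, pair2$image_pre)
  expect_identical(pair$image_post, pair2$image_post)
  expect_true(is.integer(pair$image_pre))
  expect_true(all(pair$image_pre >= 0 & pair$image_pre <= 255))
})

test_that("far above P50 the pre-cut image is clean and post-cut fully dark", {
  pop <- sample_conduit_population(10, 96, 40, field_um = 110, seed = 31)
  pop <- assign_embolism_thresholds(pop, -6, 50, seed = 32)
  pair <- render_scan_pair(pop, -0.1, test_render_params(110, noise_sd = 0),
                           seed = 33)
  expect_equal(sum(pair$truth$embolized), 0)
  pre <- segment_dark_lumina(pair$image_pre, 0.65, threshold = 80)
  post <- segment_dark_lumina(pair$image_post, 0.65, threshold = 80)
  expect_equal(nrow(pre), 0)
  expect_equal(nrow(post), 10)
})

test_that("conduits outside the frame are rejected", {
  pop <- sample_conduit_population(5, 96, 40, field_um = 200, seed = 41)
  pop <- assign_embolism_thresholds(pop, -2, 40, seed = 42)
  small <- test_render_params(40)
  expect_error(render_scan_pair(pop, -1, small), "frame")
})

test_that("centrifuge runs start at -0.58 MPa and stop once PLC reaches 90", {
  run <- generate_centrifuge_run(b_MPa = -2, S = 50, start_MPa = -0.58,
                                 step_MPa = -0.5, noise_sd = 0, seed = 1)
  expect_equal(run$pressure_MPa[1], -0.58)
  expect_true(all(diff(run$pressure_MPa) < 0))
  # noiseless PLC at psi = b is exactly 50 (grid passing through b)
  run_b <- generate_centrifuge_run(b_MPa = -2, S = 50, start_MPa = -0.5,
                                   step_MPa = -0.5, noise_sd = 0)
  expect_equal(run_b$plc_percent[run_b$pressure_MPa == -2], 50)
  # first grid point with noiseless sigmoid >= 90 is -3.58 (at -3.08 it is 89.66)
  expect_equal(min(run$pressure_MPa), -3.58)
  expect_gte(run$plc_percent[which.min(run$pressure_MPa)], 90)
  expect_lt(plc_sigmoid(-3.08, -2, 50), 90)
})

test_that("noisy centrifuge PLC stays clamped to [0, 100]", {
  run <- generate_centrifuge_run(-2, 50, noise_sd = 25, seed = 5)
  expect_true(all(run$plc_percent >= 0 & run$plc_percent <= 100))
  r1 <- generate_centrifuge_run(-2, 50, noise_sd = 5, seed = 9)
  r2 <- generate_centrifuge_run(-2, 50, noise_sd = 5, seed = 9)
  expect_identical(r1, r2)
})

test_that("anatomy table generator reproduces cell moments and truncation", {
  spec0 <- tibble::tibble(species = "betula", organ = "leaf_midrib",
                          trait = "T_PM", mean = 240, sd = 60, n = 10000)
  tab <- generate_anatomy_table(spec0, seed = 11)
  expect_equal(mean(tab$value), 240, tolerance = 0.02 * 240)
  expect_equal(sd(tab$value), 60, tolerance = 0.02 * 60)
  expect_equal(unique(tab$unit), "nm")

  # sd = 0 gives constant replicates
  spec1 <- tibble::tibble(species = "x", organ = "branch", trait = "A_C",
                          mean = 100, sd = 0, n = 5)
  expect_true(all(generate_anatomy_table(spec1, seed = 1)$value == 100))

  # heavy-left cells stay non-negative (truncated redraw)
  spec2 <- tibble::tibble(species = "x", organ = "branch", trait = "A_Pit_Ap",
                          mean = 0.6, sd = 1.5, n = 500)
  expect_gte(min(generate_anatomy_table(spec2, seed = 2)$value), 0)

  expect_error(generate_anatomy_table(dplyr::mutate(spec1, n = 1)), "n >= 2")
})

test_that("presets carry the full three-species design", {
  ps <- species_presets()
  expect_equal(nrow(ps), 9)
  expect_setequal(unique(ps$organ), c("leaf_midrib", "order23", "branch"))
  leaf_n <- ps$n_samples[ps$organ == "leaf_midrib"]
  expect_setequal(leaf_n, c(16L, 26L, 24L))
  ap <- anatomy_presets()
  expect_equal(nrow(ap), 3 * 2 * 7)
  expect_true(all(ap$sd >= 0) && all(ap$n >= 2))
})
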