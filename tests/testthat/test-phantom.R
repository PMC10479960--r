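test_that("label volume matches exhaustive ellipsoid membership", {
  spec <- phantom_spec(
    grid_dims = c(16, 16, 9), voxel_size = c(0.25, 0.25, 1),
    regions = list(roi_geometry(3L, "wulst", "left", 5L,
                                center = c(8, 8, 5), radii = c(2, 2, 1))),
    background_r1 = 0.7)
  vol <- build_label_volume(spec)
  # independent brute-force membership test over every voxel
  expected <- 0L
  for (x in 1:16) for (y in 1:16) for (z in 1:9) {
    inside <- ((x - 8) / 2)^2 + ((y - 8) / 2)^2 + ((z - 5) / 1)^2 <= 1
    expect_identical(vol[x, y, z] == 3L, inside)
    expected <- expected + inside
  }
  expect_identical(sum(vol == 3L), as.integer(expected))
  expect_true(expected > 0)
})

test_that("empty region list yields an all-zero volume", {
  spec <- phantom_spec(c(8, 8, 8), c(1, 1, 1), list(), background_r1 = 0.7)
  expect_true(all(build_label_volume(spec) == 0L))
})

test_that("overlapping ellipsoids raise a geometry error naming the labels", {
  spec <- phantom_spec(
    c(16, 16, 9), c(1, 1, 1),
    list(roi_geometry(1L, "wulst", "left", 5L, c(7, 8, 5), c(2, 2, 0.6)),
         roi_geometry(2L, "wulst", "right", 5L, c(9, 8, 5), c(2, 2, 0.6))),
    background_r1 = 0.7)
  expect_error(build_label_volume(spec), "overlap.*1.*2")
})

test_that("phantom spec rejects out-of-grid and duplicate geometry", {
  expect_error(phantom_spec(
    c(16, 16, 9), c(1, 1, 1),
    list(roi_geometry(1L, "wulst", "left", 9L, c(8, 8, 9), c(2, 2, 1.5))),
    background_r1 = 0.7), "grid bounds")
  expect_error(phantom_spec(
    c(16, 16, 9), c(1, 1, 1),
    list(roi_geometry(1L, "wulst", "left", 5L, c(5, 8, 5), c(1, 1, 0.4)),
         roi_geometry(1L, "wulst", "right", 5L, c(11, 8, 5), c(1, 1, 0.4))),
    background_r1 = 0.7), "unique")
})

test_that("Mn concentration maps linearly onto relaxation rate", {
  m <- tissue_contrast_model(relaxivity_r1 = 6.0, baseline_r1 = 0.5)
  expect_equal(concentration_to_r1(0, m), 0.5)
  expect_equal(concentration_to_r1(0.1, m), 1.1)
  # doubling concentration doubles the increment above baseline
  inc1 <- concentration_to_r1(0.2, m) - 0.5
  inc2 <- concentration_to_r1(0.4, m) - 0.5
  expect_equal(inc2, 2 * inc1)
  expect_error(concentration_to_r1(-0.1, m), "non-negative")
  conc <- seq(0, 1, by = 0.1)
  expect_true(all(diff(concentration_to_r1(conc, m)) > 0))
})

test_that("index-to-rates inversion is exact and round-trips", {
  expect_equal(li_to_hemispheric_rates(0, 2.0),
               c(left = 2.0, right = 2.0))
  r <- li_to_hemispheric_rates(-0.038, 2.0)
  expect_equal(unname(r), c(1.924, 2.076))
  expect_equal(lateralization_index(r[["left"]], r[["right"]]), -0.038)
  expect_error(li_to_hemispheric_rates(1, 2.0), "< 1")
  set.seed(404)
  for (x in runif(100, -0.999, 0.999)) {
    rr <- li_to_hemispheric_rates(x, 1.7)
    expect_equal(lateralization_index(rr[["left"]], rr[["right"]]), x,
                 tolerance = 1e-12)
  }
})

test_that("noiseless simulation follows the closed-form recovery curve", {
  r1 <- array(2.0, dim = c(4, 4, 2))   # T1 = 500 ms
  acq <- acquisition_spec(noise_sigma = 0)
  s <- simulate_vtr(r1, acq, seed = 1)
  expect_equal(dim(s$intensities), c(4, 4, 2, 13))
  # closed form at the longest TR
  expect_equal(s$intensities[1, 1, 1, 13], 100 * (1 - exp(-4990.6 / 500)),
               tolerance = 1e-12)
  expect_equal(s$intensities[1, 1, 1, 13], 99.9953, tolerance = 1e-4)
  # TR -> 0 limit: signal -> 0 (shortest TR is already small)
  tiny <- acquisition_spec(tr_list_ms = c(0.001, 10, 100), noise_sigma = 0)
  st <- simulate_vtr(r1, tiny, seed = 1)
  # S(TR) ~ s0 * TR * R1 / 1000 -> 2e-4 at TR = 1 us, R1 = 2/s
  expect_lt(st$intensities[1, 1, 1, 1], 1e-3)
  expect_error(simulate_vtr(array(0, c(2, 2, 2)), acq, 1), "positive")
})

test_that("simulation is seed-reproducible and seed-sensitive", {
  r1 <- array(1.5, dim = c(4, 4, 2))
  acq <- acquisition_spec(noise_sigma = 3)
  a <- simulate_vtr(r1, acq, seed = 1)
  b <- simulate_vtr(r1, acq, seed = 1)
  c <- simulate_vtr(r1, acq, seed = 2)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
  # rician magnitudes are non-negative
  ric <- simulate_vtr(r1, acquisition_spec(noise_sigma = 30,
                                           noise_model = "rician"), 3)
  expect_true(all(ric$intensities >= 0))
})

test_that("cohort defaults reproduce the 8 dark / 10 light design", {
  coh <- sample_cohort(cohort_spec(phantom = small_phantom(),
                                   master_seed = 5L), render = FALSE)
  conds <- vapply(coh$subjects, `[[`, character(1), "condition")
  expect_length(conds, 18)
  expect_equal(sum(conds == "dark"), 8)
  expect_equal(sum(conds == "light"), 10)
  expect_equal(nrow(coh$truth), 18 * 3)
})

test_that("zero index SD makes every draw equal the configured mean", {
  sds <- default_li_sds() * 0
  coh <- sample_cohort(cohort_spec(li_sd_by_region_condition = sds,
                                   phantom = small_phantom(),
                                   master_seed = 3L), render = FALSE)
  means <- default_li_means()
  key <- paste(coh$truth$region, coh$truth$condition, sep = "/")
  expect_equal(coh$truth$li_true, unname(means[key]))
})

test_that("drawn dark-thalamus indices are calibrated to the target mean", {
  vals <- unlist(lapply(1:60, function(r) {
    coh <- sample_cohort(cohort_spec(phantom = small_phantom(),
                                     master_seed = 100L + r),
                         render = FALSE)
    with(coh$truth, li_true[region == "thalamus_gld" & condition == "dark"])
  }))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - (-0.038)), 3 * se)
})

test_that("per-subject seeds are deterministic and distinct", {
  expect_identical(subject_seed(1L, 3L), subject_seed(1L, 3L))
  s <- vapply(1:18, function(i) subject_seed(7L, i), integer(1))
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 0 & s < 2^31 - 1))
})
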