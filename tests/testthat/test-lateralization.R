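# builds a t1_map-like object directly so ROI pooling is tested in isolation
fake_map <- function(t1, converged = NULL) {
  if (is.null(converged)) converged <- array(TRUE, dim = dim(t1))
  structure(list(t1_ms = t1, s0 = t1 * 0 + 100, rmse = t1 * 0,
                 converged = converged, model = "sr2",
                 voxel_size = c(1, 1, 1)), class = "t1_map")
}

two_section_fixture <- function() {
  dims <- c(10, 10, 2)
  labels <- array(0L, dim = dims)
  labels[1:10, 1, 1] <- 1L            # section 1, 10 voxels
  labels[1:10, 2:3, 2] <- 2L          # section 2, 20 voxels
  t1 <- array(500, dim = dims)
  t1[labels == 1L] <- 400
  t1[labels == 2L] <- 700
  legend <- data.frame(label_id = 1:2, region = "wulst",
                       hemisphere = "left", section = 1:2)
  list(map = fake_map(t1), labels = labels, legend = legend)
}

test_that("ROI mean pools voxels across sections, unweighted", {
  fx <- two_section_fixture()
  m <- roi_mean_t1(fx$map, fx$labels, fx$legend, "wulst", "left")
  expect_equal(m$mean_t1_ms, (10 * 400 + 20 * 700) / 30)
  expect_equal(m$n_voxels, 30)
})

test_that("uniform T1 field gives the constant regardless of ROI shape", {
  fx <- two_section_fixture()
  fx$map$t1_ms[] <- 500
  m <- roi_mean_t1(fx$map, fx$labels, fx$legend, "wulst", "left")
  expect_equal(m$mean_t1_ms, 500)
})

test_that("non-converged voxels are excluded; empty ROI is an error", {
  fx <- two_section_fixture()
  conv <- fx$map$converged
  conv[fx$labels == 2L] <- FALSE
  fx$map$converged <- conv
  m <- roi_mean_t1(fx$map, fx$labels, fx$legend, "wulst", "left")
  expect_equal(m$mean_t1_ms, 400)
  expect_equal(m$n_voxels, 10)
  conv[] <- FALSE
  fx$map$converged <- conv
  expect_error(roi_mean_t1(fx$map, fx$labels, fx$legend, "wulst", "left"),
               "empty ROI.*wulst.*left")
  expect_error(roi_mean_t1(fx$map, fx$labels, fx$legend, "wulst", "right"),
               "no entries")
})

test_that("rate transform is 1000/T1 and strictly decreasing", {
  expect_equal(rate_transform(500), 2.0)
  expect_equal(rate_transform(1000), 1.0)
  # involution up to units: 1000 / (1000 / x) = x
  expect_equal(rate_transform(rate_transform(730)), 730)
  expect_error(rate_transform(0), "positive")
  expect_true(all(diff(rate_transform(seq(100, 5000, 100))) < 0))
})

test_that("lateralization index formula, range and antisymmetry", {
  expect_equal(lateralization_index(2, 2), 0)
  expect_equal(lateralization_index(3, 1), 0.5)
  expect_error(lateralization_index(0, 1), "positive")
  set.seed(12)
  a <- runif(50, 0.1, 5)
  b <- runif(50, 0.1, 5)
  expect_equal(lateralization_index(a, b), -lateralization_index(b, a))
  expect_true(all(abs(lateralization_index(a, b)) < 1))
})

test_that("subject record reproduces a configured index through the chain", {
  sds <- default_li_sds() * 0
  coh <- sample_cohort(cohort_spec(
    li_sd_by_region_condition = sds,
    acquisition = acquisition_spec(noise_sigma = 0),
    phantom = small_phantom(), master_seed = 2L))
  s <- coh$subjects[[1]]                      # a dark subject
  map <- fit_t1_volume(s$series, mask = coh$label_volume > 0)
  rec <- build_subject_record(map, coh$label_volume, coh$legend,
                              s$subject_id, s$condition)
  thal <- rec[rec$region == "thalamus_gld", ]
  expect_equal(thal$lateralization_index, -0.038, tolerance = 1e-6)
  # voxel-count bookkeeping matches the label volume
  legend <- coh$legend
  ids_l <- legend$label_id[legend$region == "thalamus_gld" &
                             legend$hemisphere == "left"]
  expect_equal(thal$n_left, sum(coh$label_volume %in% ids_l))
})

test_that("a symmetric phantom yields zero indices in all regions", {
  means <- default_li_means() * 0
  sds <- default_li_sds() * 0
  coh <- sample_cohort(cohort_spec(
    li_mean_by_region_condition = means, li_sd_by_region_condition = sds,
    acquisition = acquisition_spec(noise_sigma = 0),
    phantom = small_phantom(), master_seed = 2L))
  s <- coh$subjects[[1]]
  map <- fit_t1_volume(s$series, mask = coh$label_volume > 0)
  rec <- build_subject_record(map, coh$label_volume, coh$legend,
                              s$subject_id, s$condition)
  expect_equal(rec$lateralization_index, rep(0, 3), tolerance = 1e-9)
})

test_that("swapping hemisphere labels in the legend negates every index", {
  coh <- sample_cohort(small_cohort_spec(master_seed = 21L))
  s <- coh$subjects[[1]]
  map <- fit_t1_volume(s$series, mask = coh$label_volume > 0)
  rec <- build_subject_record(map, coh$label_volume, coh$legend,
                              s$subject_id, s$condition)
  flipped <- coh$legend
  flipped$hemisphere <- ifelse(flipped$hemisphere == "left",
                               "right", "left")
  rec2 <- build_subject_record(map, coh$label_volume, flipped,
                               s$subject_id, s$condition)
  expect_equal(rec2$lateralization_index, -rec$lateralization_index,
               tolerance = 1e-12)
})

test_that("index is invariant to global intensity scaling of the series", {
  coh <- sample_cohort(small_cohort_spec(master_seed = 8L))
  s <- coh$subjects[[1]]
  scaled <- vtr_series(s$series$intensities * 3.7, s$series$tr_list_ms)
  m1 <- fit_t1_volume(s$series, mask = coh$label_volume > 0)
  m2 <- fit_t1_volume(scaled, mask = coh$label_volume > 0)
  r1 <- build_subject_record(m1, coh$label_volume, coh$legend, "a", "dark")
  r2 <- build_subject_record(m2, coh$label_volume, coh$legend, "a", "dark")
  expect_equal(r2$lateralization_index, r1$lateralization_index,
               tolerance = 1e-9)
})

test_that("mean-then-transform differs from transform-then-mean", {
  fx <- two_section_fixture()
  m <- roi_mean_t1(fx$map, fx$labels, fx$legend, "wulst", "left")
  implemented <- rate_transform(m$mean_t1_ms)
  voxelwise <- mean(rate_transform(fx$map$t1_ms[fx$labels > 0]))
  expect_false(isTRUE(all.equal(implemented, voxelwise)))
  # Jensen: mean of 1/T1 exceeds 1/mean(T1) for heterogeneous T1
  expect_gt(voxelwise, implemented)
})

test_that("cohort table validation enforces the complete design", {
  tab <- toy_table(2, 2, function(reg, cond) 0.01)
  expect_s3_class(cohort_table(tab), "cohort_table")
  expect_error(cohort_table(tab[-1, ]), "exactly one row per region")
  bad <- tab; bad$condition[1] <- "dim"
  expect_error(cohort_table(bad), "light")
})
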