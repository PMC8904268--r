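test_that("negative-control calibration matches empirical quantiles", {
  # constant-zero control: threshold excludes the control itself
  flat <- image_channel_set(nuclei = matrix(1, 120, 120),
                            marker = matrix(0, 120, 120))
  expect_warning(cal0 <- calibrate_marker_threshold(flat), "constant")
  expect_false(any(flat$marker > cal0$marker_threshold))

  # Gaussian background mean 100 sd 10: 0.999 quantile ~ 130.9
  set.seed(12)
  bg <- matrix(pmax(rnorm(512 * 512, 100, 10), 0), 512, 512)
  nc <- image_channel_set(nuclei = matrix(1, 512, 512), marker = bg)
  cal <- calibrate_marker_threshold(nc, quantile = 0.999)
  expect_lt(abs(cal$marker_threshold - quantile(bg, 0.999)), 1e-9)
  expect_lt(abs(cal$marker_threshold - 130.9), 1.0)

  # median threshold on uniform noise leaves ~half the pixels above
  set.seed(13)
  u <- matrix(runif(200 * 200), 200, 200)
  ncu <- image_channel_set(nuclei = matrix(1, 200, 200), marker = u)
  cal5 <- calibrate_marker_threshold(ncu, quantile = 0.5)
  expect_lt(abs(mean(u > cal5$marker_threshold) - 0.5), 0.02)

  tiny <- image_channel_set(nuclei = matrix(1, 5, 5),
                            marker = matrix(0, 5, 5))
  expect_error(calibrate_marker_threshold(tiny), "1e4")
})

test_that("nucleus segmentation finds synthetic disks exactly", {
  blank <- image_channel_set(nuclei = matrix(0, 64, 64),
                             marker = matrix(0, 64, 64))
  nuc0 <- segment_nuclei(blank)
  expect_true(nuc0$empty_field)
  expect_length(nuc0$ids, 0)

  sim <- simulate_image(image_sim_params(seed = 21))  # default 50 nuclei
  nuc <- segment_nuclei(sim$image)
  expect_length(nuc$ids, 50)
  expect_true(all(nuc$areas >= 30 & nuc$areas <= 500))
  # centroids land on the true centers (within a pixel)
  d <- vapply(seq_len(50), function(i) {
    min(sqrt((sim$truth$centers[, 1] - nuc$centroids[i, 1])^2 +
               (sim$truth$centers[, 2] - nuc$centroids[i, 2])^2))
  }, numeric(1))
  expect_lt(max(d), 1)

  # exclusion mask removing 10 whole nuclei removes exactly 10 components
  mask <- matrix(FALSE, 512, 512)
  for (i in 1:10) {
    cr <- sim$truth$centers[i, 1]; cc <- sim$truth$centers[i, 2]
    r <- ceiling(sim$truth$radii[i]) + 2
    mask[max(1, round(cr - r)):round(cr + r),
         max(1, round(cc - r)):round(cc + r)] <- TRUE
  }
  img_m <- image_channel_set(sim$image$nuclei, sim$image$marker,
                             exclusion_mask = mask)
  expect_length(segment_nuclei(img_m)$ids, 40)

  all_excluded <- image_channel_set(sim$image$nuclei, sim$image$marker,
                                    exclusion_mask = matrix(TRUE, 512, 512))
  expect_error(segment_nuclei(all_excluded), "excluded")
})

test_that("marker objects obey the threshold and size gates", {
  cal <- structure(list(marker_threshold = 50, size_min = 20,
                        size_max = 500, localization = "nuclear",
                        quantile = 0.999),
                   class = "threshold_calibration")
  img0 <- image_channel_set(nuclei = matrix(1, 40, 40),
                            marker = matrix(10, 40, 40))
  expect_length(marker_objects(img0, cal)$ids, 0)  # threshold above max

  mk <- matrix(0, 40, 40)
  mk <- paint_disk(mk, 20, 20, 6, 100)          # ~113 px blob
  mk <- paint_disk(mk, 8, 8, 1.6, 100)          # ~9 px blob, under size_min
  img <- image_channel_set(nuclei = matrix(1, 40, 40), marker = mk)
  obj <- marker_objects(img, cal)
  expect_length(obj$ids, 1)
  expect_gt(obj$areas[1], 100)
})

test_that("localization rules associate marker signal correctly", {
  for (loc in c("nuclear", "cytoplasmic", "apical")) {
    sim <- simulate_image(image_sim_params(
      field = c(320, 320), n_nuclei = 25, positive_fraction = 0.4,
      localization = loc, seed = 31))
    cal <- calibrate_marker_threshold(sim$negative_control,
                                      localization = loc)
    nuc <- segment_nuclei(sim$image)
    expect_length(nuc$ids, 25)
    mk <- marker_objects(sim$image, cal)
    flags <- associate_nuclei(nuc, mk$labels > 0, cal)
    expect_equal(sum(flags), sim$truth$n_positive)
  }

  # empty marker mask: everything negative
  sim <- simulate_image(image_sim_params(field = c(256, 256), n_nuclei = 15,
                                         positive_fraction = 0, seed = 32))
  cal <- calibrate_marker_threshold(sim$negative_control)
  nuc <- segment_nuclei(sim$image)
  flags <- associate_nuclei(nuc, matrix(FALSE, 256, 256), cal)
  expect_false(any(flags))
  expect_equal(percent_positive(flags)$fraction, 0)
})

test_that("positivity is monotone in threshold and coverage fraction", {
  sim <- simulate_image(image_sim_params(field = c(320, 320), n_nuclei = 25,
                                         positive_fraction = 0.5, seed = 41))
  nuc <- segment_nuclei(sim$image)
  base <- calibrate_marker_threshold(sim$negative_control)
  counts_thr <- vapply(c(base$marker_threshold, 500, 900, 1200), function(t) {
    cal <- base; cal$marker_threshold <- t
    sum(associate_nuclei(nuc, marker_objects(sim$image, cal)$labels > 0, cal))
  }, numeric(1))
  expect_true(all(diff(counts_thr) <= 0))

  mk <- marker_objects(sim$image, base)$labels > 0
  counts_f <- vapply(c(0.1, 0.3, 0.6, 0.95, 1.01), function(f) {
    sum(associate_nuclei(nuc, mk, base, f_nuc = f))
  }, numeric(1))
  expect_true(all(diff(counts_f) <= 0))
  expect_equal(counts_f[5], 0)  # coverage cannot exceed 1
})

test_that("percent_positive conventions and group comparison", {
  q0 <- percent_positive(logical(0))
  expect_equal(q0$fraction, 0)
  expect_true(q0$flagged_empty)
  expect_equal(percent_positive(rep(FALSE, 200))$fraction, 0)

  expect_warning(res <- compare_image_groups(list(a = c(.1, .2)), "a"),
                 "single group")
  expect_null(res)

  same <- list(ctrl = c(.1, .15, .12, .13), TO = c(.1, .15, .12, .13))
  cmp <- compare_image_groups(same, "ctrl")
  expect_gt(cmp$omnibus$p_value, 0.5)

  three <- list(ctrl = c(.1, .12, .11, .13), TO = c(.3, .32, .31, .29),
                CDH = c(.1, .11, .13, .12))
  cmp3 <- compare_image_groups(three, "ctrl")
  expect_s3_class(cmp3$omnibus, "occ_test_result")
  expect_length(cmp3$pairwise, 2)
})

test_that("quantification is deterministic for identical inputs", {
  sim <- simulate_image(image_sim_params(field = c(256, 256), n_nuclei = 20,
                                         positive_fraction = 0.3, seed = 51))
  cal <- calibrate_marker_threshold(sim$negative_control)
  q1 <- quantify_image(sim$image, cal)
  q2 <- quantify_image(sim$image, cal)
  expect_identical(q1[c("n_nuclei", "n_positive", "fraction")],
                   q2[c("n_nuclei", "n_positive", "fraction")])
})
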