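test_that("object counting measures hand-countable fixtures", {
  arr <- array(0, c(9, 9, 9))
  arr[4:6, 4:6, 4:6] <- 1000
  det <- count_objects_3d(arr, 500, min_size = 5)
  expect_equal(nrow(det), 1)
  expect_equal(det$voxel_count, 27)
  expect_equal(c(det$x, det$y, det$z), c(5, 5, 5))
  expect_equal(det$mean_intensity, 1000)
  expect_equal(det$integrated_intensity, 27000)
  expect_equal(det$max_intensity, 1000)
  # empty result allowed
  expect_equal(nrow(count_objects_3d(array(0, c(5, 5, 5)), 10)), 0)
  # single bright voxels: merged at Chebyshev distance 1, split at 2
  a <- array(0, c(7, 7, 7)); a[2, 2, 2] <- 9; a[3, 3, 3] <- 9
  expect_equal(nrow(count_objects_3d(a, 5, min_size = 1)), 1)
  b <- array(0, c(7, 7, 7)); b[2, 2, 2] <- 9; b[4, 4, 4] <- 9
  expect_equal(nrow(count_objects_3d(b, 5, min_size = 1)), 2)
})

test_that("counting agrees with the flood-fill oracle on random volumes", {
  for (seed in 1:20) {
    arr <- withr::with_seed(seed,
      array(stats::runif(10^3), c(10, 10, 10)))
    thr <- 0.6
    det <- count_objects_3d(arr, thr, min_size = 1)
    oracle <- flood_fill_components(arr > thr)
    expect_equal(nrow(det), max(oracle), info = paste("seed", seed))
    mine <- label_components(arr > thr)
    expect_identical(component_voxel_sets(mine),
                     component_voxel_sets(oracle),
                     info = paste("seed", seed))
  }
})

test_that("greedy matching is one-to-one and classifies detections correctly", {
  truth <- data.frame(id = 1:3, x = c(10, 30, 50), y = c(10, 10, 10),
                      z = c(5, 5, 5))
  det_exact <- data.frame(id = 1:3, x = truth$x, y = truth$y, z = truth$z)
  cmp <- match_to_truth(det_exact, truth, max_dist = 4)
  expect_equal(c(cmp$tp, cmp$fp, cmp$fn), c(3, 0, 0))
  expect_equal(cmp$tpr, 1)
  # a single detection equidistant from two truths matches exactly one
  truth2 <- data.frame(id = 1:2, x = c(10, 14), y = c(0, 0), z = c(0, 0))
  det1 <- data.frame(id = 1, x = 12, y = 0, z = 0)
  cmp2 <- match_to_truth(det1, truth2, max_dist = 4)
  expect_equal(cmp2$tp, 1)
  expect_equal(cmp2$fn, 1)
  expect_equal(nrow(cmp2$matches), 1)
  # empty detections
  cmp3 <- match_to_truth(det1[0, ], truth, max_dist = 4)
  expect_equal(cmp3$tpr, 0)
  expect_equal(cmp3$fn, 3)
  # never double-assigns
  det_two <- data.frame(id = 1:2, x = c(9.5, 10.5), y = c(10, 10),
                        z = c(5, 5))
  cmp4 <- match_to_truth(det_two, truth, max_dist = 4)
  expect_equal(cmp4$tp, 1)
  expect_equal(anyDuplicated(cmp4$matches$truth_id), 0)
})

test_that("relative MAE compares common true positives against the reference", {
  truth <- data.frame(id = 1:2, x = c(10, 30), y = c(10, 10), z = c(5, 5))
  ref_det <- data.frame(id = 1:2, x = c(10, 30), y = c(10, 10), z = c(5, 5),
                        voxel_count = c(100, 200),
                        mean_intensity = c(50, 70),
                        integrated_intensity = c(5000, 14000))
  ref_cmp <- match_to_truth(ref_det, truth, 4)
  # self-comparison: all errors zero
  mae0 <- mae_vs_reference(ref_cmp, ref_cmp, ref_det, ref_det)
  expect_equal(unname(mae0[1:3]), c(0, 0, 0))
  # voxel counts uniformly 10% low
  test_det <- ref_det
  test_det$voxel_count <- ref_det$voxel_count * 0.9
  test_cmp <- match_to_truth(test_det, truth, 4)
  mae <- mae_vs_reference(test_cmp, ref_cmp, test_det, ref_det)
  expect_equal(unname(mae["voxel_count"]), 0.10)
  # a constant intensity offset leaves the voxel-count error unchanged
  test_det2 <- test_det
  test_det2$mean_intensity <- test_det$mean_intensity + 25
  mae2 <- mae_vs_reference(match_to_truth(test_det2, truth, 4), ref_cmp,
                           test_det2, ref_det)
  expect_equal(unname(mae2["voxel_count"]), 0.10)
  expect_gt(unname(mae2["mean_intensity"]), 0)
})

test_that("histogram distance is scale-free and matches hand transport costs", {
  arr <- withr::with_seed(5, array(stats::runif(4096, 100, 900), c(16, 16, 16)))
  expect_equal(histogram_distance(arr, arr), 0)
  expect_equal(histogram_distance(arr, arr * 2), 0)  # min-max matched
  # two-spike histograms: all mass moves from bin of 0 to bin of x
  a <- array(c(0, 1), c(2, 1, 1))
  b <- array(c(0, 1, 1, 1), c(4, 1, 1))
  # a: mass .5 at 0, .5 at 1; b: mass .25 at 0, .75 at 1; with 2 bins the
  # centers sit 0.5 apart, so the cost is 0.25 mass x 0.5 distance
  expect_equal(histogram_distance(a, b, bins = 2), 0.125, tolerance = 1e-12)
})

test_that("the Otsu threshold splits a well-separated bimodal volume", {
  arr <- withr::with_seed(6, {
    v <- c(stats::rnorm(9000, 200, 20), stats::rnorm(1000, 900, 40))
    array(pmax(v, 0), c(10, 10, 100))
  })
  thr <- otsu_threshold(arr)
  # the threshold must fall in the gap between the two modes
  expect_gt(thr, 200 + 4 * 20)
  expect_lt(thr, 900 - 3 * 40)
  # frozen reference from an independent between-class-variance maximizer
  # (scikit-image threshold_otsu on the identical sample gives 288.07);
  # agreement expected within one 256-bin width (~3.6 ADU)
  expect_lt(abs(thr - 288.07), 4)
  # constant volume degenerates to its own value
  expect_equal(otsu_threshold(array(7, c(3, 3, 3))), 7)
})
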