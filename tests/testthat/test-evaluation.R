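test_that("pixel classification rate ignores background agreement", {
  truth <- array(0L, c(2, 5, 5)); pred <- truth
  truth[1, 1:2, 1:5] <- 9L
  pred[1, 1:2, 1:5] <- 9L
  pred[1, 1, 1:3] <- 10L            # 3 of 10 spine pixels wrong
  pred[2, 5, 5] <- 26L              # background error: ignored
  expect_equal(pixel_classification_rate(pred, truth), 0.7)
  expect_equal(pixel_classification_rate(truth, truth), 1.0)
  expect_equal(pixel_classification_rate(array(0L, dim(truth)), truth), 0)
  expect_error(pixel_classification_rate(pred, array(0L, dim(truth))), "no spine")
})

test_that("the 20 mm identification rule flips exactly at the threshold", {
  truth <- centroid_set(8L, matrix(c(0, 0, 0), 1))
  near <- centroid_set(8L, matrix(c(0, 0, 19.9), 1))
  far <- centroid_set(8L, matrix(c(0, 0, 20.1), 1))
  at <- centroid_set(8L, matrix(c(0, 0, 20), 1))
  expect_equal(id_rate(near, truth)$rate, 1)
  expect_equal(id_rate(far, truth)$rate, 0)
  expect_equal(id_rate(at, truth)$rate, 1)     # inclusive: "no more than"
})

test_that("identification rate counts misses and id-mismatches as errors", {
  truth <- centroid_set(8:11, cbind(0, 0, c(0, 21, 42, 64)))
  pred <- centroid_set(8:10, cbind(0, 0, c(1, 22, 300)))  # 11 missing, 10 far
  r <- id_rate(pred, truth)
  expect_equal(r$rate, 0.5)
  expect_equal(unname(r$correct), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(id_rate(centroid_set(), truth)$rate, 0)
  expect_error(id_rate(pred, centroid_set()), "empty")
  # label swap: same positions, swapped ids -> both wrong
  swapped <- centroid_set(8:9, cbind(0, 0, c(21, 0)))
  expect_equal(id_rate(swapped, truth)$rate, 0)
})

test_that("identification rate is monotone in the threshold", {
  set.seed(23)
  truth <- centroid_set(8:13, cbind(0, 0, seq(0, 125, length.out = 6)))
  pred <- centroid_set(8:13, cbind(rnorm(6, 0, 8), rnorm(6, 0, 8),
                                   seq(0, 125, length.out = 6) + rnorm(6, 0, 8)))
  rates <- vapply(c(5, 10, 20, 40), function(th) id_rate(pred, truth, th)$rate,
                  numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("distance statistics use matched ids and population sd", {
  truth <- centroid_set(8:9, cbind(0, 0, c(0, 21)))
  pred <- centroid_set(8:9, cbind(c(3, 0), 0, c(0, 26)))   # distances 3, 5
  ds <- distance_stats(pred, truth)
  expect_equal(ds$mean_mm, 4)
  expect_equal(ds$std_mm, 1)
  single <- distance_stats(centroid_set(8L, matrix(c(8.1, 0, 0), 1)),
                           centroid_set(8L, matrix(0, 1, 3)))
  expect_equal(single$mean_mm, 8.1)
  expect_equal(single$std_mm, 0)
  expect_equal(distance_stats(truth, truth)$mean_mm, 0)
  expect_error(distance_stats(centroid_set(20L, matrix(0, 1, 3)), truth),
               "no vertebra id")
})

test_that("segmentation metrics reproduce set arithmetic", {
  truth <- array(0L, c(10, 10, 10)); truth[1:4, 1:5, 1:5] <- 1L   # 100 voxels
  pred <- array(0L, c(10, 10, 10)); pred[1:2, 1:5, 1:5] <- 1L     # 50, all inside
  m <- segmentation_metrics(pred, truth)
  expect_equal(m$vertebrae$iou, 0.5)
  expect_equal(m$vertebrae$dice, 2 / 3)
  expect_equal(m$vertebrae$recall, 0.5)
  perfect <- segmentation_metrics(truth, truth)
  expect_equal(unlist(perfect), rep(1, 7), ignore_attr = TRUE)
  expect_equal(segmentation_metrics(array(0L, dim(truth)), truth)$vertebrae$recall, 0)
  expect_error(segmentation_metrics(pred, array(0L, dim(truth))), "empty")
})

test_that("dice and IoU satisfy dice = 2*IoU/(1+IoU) on random masks", {
  set.seed(31)
  for (rep in 1:20) {
    truth <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
    pred <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
    if (!any(truth == 1)) next
    m <- segmentation_metrics(pred, truth)
    expect_equal(m$vertebrae$dice, 2 * m$vertebrae$iou / (1 + m$vertebrae$iou))
    expect_equal(m$overall$dice, 2 * m$overall$iou / (1 + m$overall$iou))
  }
})

test_that("vertebra ids map to the standard spine regions", {
  expect_equal(region_of(c(7, 8)), c("cervical", "thoracic"))
  expect_equal(region_of(c(19, 20)), c("thoracic", "lumbar"))
  expect_equal(region_of(c(24, 25, 26)), c("lumbar", "sacral", "sacral"))
  expect_error(region_of(27), "1..26")
  expect_error(region_of(0), "1..26")
})

test_that("eval_report aggregates the per-scan metrics", {
  ph <- generate_phantom(tiny_phantom_config(seed = 19))
  rep1 <- eval_report(ph$dense, ph$dense, ph$centroids, ph$centroids)
  expect_equal(rep1$pixel_rate, 1)
  expect_equal(rep1$id_rate, 1)
  expect_equal(rep1$mean_dist_mm, 0)
  expect_equal(rep1$region_breakdown$thoracic, 1)
})
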