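test_that("histogram statistics follow the population-moment conventions", {
  s <- histogram_stats(c(1, 1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  expect_true(is.na(s$skewness) && is.na(s$kurtosis))

  # hand computation: m2 = 0.25, m3 = 0, m4 = 0.0625
  s2 <- histogram_stats(c(0, 0, 1, 1))
  expect_equal(s2$skewness, 0)
  expect_equal(s2$kurtosis, 1)
  expect_equal(s2$sd, 0.5)

  set.seed(1)
  x <- rnorm(1e6)
  s3 <- histogram_stats(x)
  expect_lt(abs(s3$kurtosis - 3), 0.02)
  expect_equal(histogram_stats(x, excess_kurtosis = TRUE)$kurtosis,
               s3$kurtosis - 3)
  expect_error(histogram_stats(numeric(0)), "empty")
})

test_that("histogram statistics agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(4)
  x <- rgamma(500, shape = 2)
  s <- histogram_stats(x)
  expect_equal(s$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(s$kurtosis, e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
})

test_that("per-slice averaging reduces correctly and falls back when sparse", {
  set.seed(7)
  map <- array(rnorm(6 * 6 * 4, mean = 10), c(6, 6, 4))
  mask <- array(FALSE, c(6, 6, 4))
  mask[2:5, 2:5, 2] <- TRUE # single slice
  a <- lesion_features(map, mask, mode = "per_slice_mean")
  b <- lesion_features(map, mask, mode = "whole_voi")
  for (k in c("mean", "sd", "skewness", "kurtosis"))
    expect_equal(a[[k]], b[[k]])

  # two equal-count slices with means 1 and 3 -> slice-average mean 2
  map2 <- array(0, c(4, 4, 2))
  map2[, , 1] <- 1; map2[, , 2] <- 3
  mask2 <- array(TRUE, c(4, 4, 2))
  f2 <- lesion_features(map2, mask2, mode = "per_slice_mean",
                        min_slice_voxels = 8)
  expect_equal(f2$mean, 2)

  # no slice reaches the minimum -> whole-VOI fallback with a warning
  mask3 <- array(FALSE, c(6, 6, 4)); mask3[1:2, 1, 1] <- TRUE
  expect_warning(f3 <- lesion_features(map, mask3, min_slice_voxels = 8),
                 "whole_voi")
  expect_equal(f3$mode, "whole_voi")
})

test_that("per-slice statistics match direct per-slice computation", {
  set.seed(9)
  map <- array(rexp(8 * 8 * 5), c(8, 8, 5))
  mask <- array(runif(8 * 8 * 5) < 0.6, c(8, 8, 5))
  f <- lesion_features(map, mask, mode = "per_slice_mean",
                       min_slice_voxels = 5)
  direct <- sapply(1:5, function(s) {
    v <- map[, , s][mask[, , s]]
    if (length(v) < 5) return(c(NA, NA, NA, NA))
    m <- mean(v); d <- v - m; m2 <- mean(d^2)
    c(m, sqrt(m2), mean(d^3) / m2^1.5, mean(d^4) / m2^2)
  })
  keep <- !is.na(direct[1, ])
  expect_equal(f$mean, mean(direct[1, keep]), tolerance = 1e-12)
  expect_equal(f$sd, mean(direct[2, keep]), tolerance = 1e-12)
  expect_equal(f$skewness, mean(direct[3, keep]), tolerance = 1e-12)
  expect_equal(f$kurtosis, mean(direct[4, keep]), tolerance = 1e-12)
})

test_that("scale and shift equivariance of the feature set", {
  set.seed(11)
  map <- array(rnorm(5^3, 4, 2), c(5, 5, 5))
  mask <- array(TRUE, c(5, 5, 5))
  f <- lesion_features(map, mask)
  fs <- lesion_features(3 * map, mask)
  expect_equal(fs$mean, 3 * f$mean)
  expect_equal(fs$sd, 3 * f$sd)
  expect_equal(fs$skewness, f$skewness)
  expect_equal(fs$kurtosis, f$kurtosis)
  fsh <- lesion_features(map + 7, mask)
  expect_equal(fsh$mean, f$mean + 7)
  expect_equal(fsh$sd, f$sd)
})

test_that("delta features are post minus pre with missing propagation", {
  pre <- list(mean = 1.44, sd = 0.2, skewness = -0.3, kurtosis = 4.93)
  post <- list(mean = 1.42, sd = 0.25, skewness = -0.4, kurtosis = 2.88)
  d <- delta_features(pre, post)
  expect_equal(d$mean, -0.02)
  expect_equal(d$kurtosis, -2.05) # responder-like kurtosis decline
  expect_lt(d$kurtosis, 0)
  post$kurtosis <- NA_real_
  expect_true(is.na(delta_features(pre, post)$kurtosis))
  same <- delta_features(pre, pre)
  expect_true(all(unlist(same) == 0))
})
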