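test_that("top-k averaging reproduces hand-built columns", {
  ## k equal maxima at z in {5..9} -> a = 7
  pl <- matrix(0, 20, 2)
  pl[6:10, 1] <- 1                      # z = 5..9 (0-based)
  ## five brightest at z = {4,5,6,7,8} -> mean 6
  pl[5:9, 2] <- c(0.9, 1.0, 0.8, 0.95, 0.85)
  prof <- extract_apical_profile(pl, k = 5)
  expect_equal(prof$a, c(7, 6))
})

test_that("ties among brightest pixels break toward lower z", {
  pl <- matrix(1, 30, 3)               # all-equal plane
  prof <- extract_apical_profile(pl, k = 5)
  expect_equal(prof$a, rep(mean(0:4), 3))
})

test_that("extraction matches an exhaustive sort-by-intensity oracle", {
  set.seed(42)
  for (rep in 1:20) {
    pl <- matrix(runif(20 * 30), 20, 30)
    prof <- extract_apical_profile(pl, k = 5)
    oracle <- vapply(seq_len(30), function(x) {
      df <- data.frame(z = 0:19, i = pl[, x])
      df <- df[order(-df$i, df$z), ]
      mean(df$z[1:5])
    }, 0)
    expect_identical(prof$a, oracle)
  }
})

test_that("extraction is invariant to affine intensity rescaling", {
  set.seed(1)
  pl <- matrix(runif(40 * 25), 40, 25)
  base <- extract_apical_profile(pl, k = 5)$a
  expect_identical(extract_apical_profile(pl + 3.7, k = 5)$a, base)
  expect_identical(extract_apical_profile(pl * 12.5, k = 5)$a, base)
})

test_that("z-extent smaller than k is a parameter error", {
  expect_error(extract_apical_profile(matrix(1, 4, 10), k = 5), "k = 5")
})

test_that("noiseless generator surfaces are recovered within 1 px", {
  for (depth in c(0, 10)) {
    g <- generate_stack(small_tissue(fold_depth_px = depth),
                        small_signal(noise_sigma = 0))
    prof <- extract_apical_profile(xz_plane(g$stack, 0, "junctional"))
    expect_lte(max(abs(prof$a - g$truth$a)), 1)
  }
})

test_that("invalid columns are flagged and interpolated", {
  pl <- matrix(0.01, 30, 5)
  for (x in c(1, 2, 4, 5)) pl[10 + x, x] <- 1   # column 3 has no tissue
  prof <- extract_apical_profile(pl, k = 1, intensity_floor = 0.5)
  expect_identical(prof$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  filled <- fill_invalid_profile(prof)
  expect_equal(filled$a[3], mean(c(filled$a[2], filled$a[4])))
})

test_that("flat profiles yield no fold", {
  prof <- structure(list(a = rep(10, 100), valid = rep(TRUE, 100),
                         plane_index = 0L, nz = 48L),
                    class = "ApicalProfile")
  expect_null(detect_fold(prof))
})

test_that("Gaussian peak descriptors match the analytic half-height", {
  x <- 0:199
  a <- 5 + gaussian_bump(x, 100, 10, 15)
  prof <- structure(list(a = a, valid = rep(TRUE, 200), plane_index = 0L,
                         nz = 48L), class = "ApicalProfile")
  fd <- detect_fold(prof)
  expect_equal(fd$x_F, 100)
  half <- 15 * sqrt(2 * log(2))        # 17.66 px
  ## direct-scan oracle: nearest columns at or below half prominence
  h <- max(a) - fd$depth / 2
  xs_oracle <- max(x[x < 100 & a <= h])
  xe_oracle <- min(x[x > 100 & a <= h])
  expect_equal(fd$x_S, xs_oracle)
  expect_equal(fd$x_E, xe_oracle)
  expect_lt(abs(fd$x_S - (100 - half)), 1.5)
  expect_lt(abs(fd$x_E - (100 + half)), 1.5)
  expect_true(fd$x_S < fd$x_F && fd$x_F < fd$x_E)
})

test_that("the widest peak within the search window wins", {
  x <- 0:299
  wide <- gaussian_bump(x, 90, 6, 18)
  narrow <- gaussian_bump(x, 130, 9, 4)
  far <- gaussian_bump(x, 250, 12, 10)
  prof <- structure(list(a = 5 + wide + narrow + far,
                         valid = rep(TRUE, 300), plane_index = 0L, nz = 60L),
                    class = "ApicalProfile")
  ## without a previous center the widest overall peak (x = 90) wins
  expect_equal(detect_fold(prof)$x_F, 90)
  ## the +-50 px vicinity rule excludes the far peak even though it is
  ## taller and wider than the narrow one
  fd <- detect_fold(prof, prev_center = 100, window = 50)
  expect_equal(fd$x_F, 90)
  ## a window around the far peak selects it
  expect_equal(detect_fold(prof, prev_center = 240, window = 50)$x_F, 250)
})

test_that("fold descriptors are ordered for random parameterizations", {
  set.seed(5)
  for (rep in 1:25) {
    ctr <- runif(1, 60, 140); dep <- runif(1, 3, 12); sig <- runif(1, 5, 20)
    a <- 8 + gaussian_bump(0:199, ctr, dep, sig)
    prof <- structure(list(a = a, valid = rep(TRUE, 200), plane_index = 0L,
                           nz = 48L), class = "ApicalProfile")
    fd <- detect_fold(prof)
    expect_false(is.null(fd))
    expect_true(fd$x_S < fd$x_F && fd$x_F < fd$x_E)
  }
})

test_that("a straight fold is tracked across planes", {
  surf <- function(y) 10 + gaussian_bump(0:199, 120, 8, 8)
  ## noiseless: apex exact to the 1-px quantization plateau middle
  folds0 <- track_fold(junctional_stack(surf), seed_center = 120)
  expect_true(all(abs(vapply(folds0, `[[`, 0, "x_F") - 120) <= 2))
  ## 5% noise: noise dithers the quantized apex plateau by ~1 px more
  folds <- track_fold(junctional_stack(surf, noise_sigma = 0.05),
                      seed_center = 120)
  expect_true(all(abs(vapply(folds, `[[`, 0, "x_F") - 120) <= 3))
})

test_that("a drifting fold stays within the tracking window", {
  st <- junctional_stack(function(y)
    10 + gaussian_bump(0:199, 60 + 30 * y, 8, 8), ny = 4L)
  folds <- track_fold(st, seed_center = 60)
  centers <- vapply(folds, function(f) f$x_F, 0)
  expect_equal(centers, 60 + 30 * (0:3), tolerance = 1e-8)
})

test_that("flat tissue produces a tracking failure", {
  st <- junctional_stack(function(y) rep(10, 200))
  expect_error(track_fold(st, seed_center = 100), "tracking failure")
})
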