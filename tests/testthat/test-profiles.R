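raw_profile <- function(l, p, idx = 0L) {
  structure(list(p = p, l = l, plane_index = idx, channel = "x"),
            class = "RawProfile")
}

test_that("reference sigmoid recovery: exact model, step limit, noisy mean", {
  l <- seq(0, 60, by = 0.21)
  y <- 0.8 / (1 + exp(0.5 * (l - 30)))
  f <- fit_reference_sigmoid(raw_profile(l, y))
  expect_true(f$converged)
  expect_lt(abs(f$params[["l0"]] - 30), 0.1)
  expect_lt(abs(f$params[["A"]] - 0.8), 0.01)
  ## step function = infinite-steepness limit
  fs <- fit_reference_sigmoid(raw_profile(l, ifelse(l < 22, 1, 0)))
  expect_lt(abs(fs$params[["l0"]] - 22), 0.21)
  ## 5% noise, 50 replicates: mean recovered l0 within 1 um of truth
  set.seed(21)
  l0s <- replicate(50, {
    yn <- y + rnorm(length(l), 0, 0.05)
    fit_reference_sigmoid(raw_profile(l, yn))$params[["l0"]]
  })
  expect_lt(abs(mean(l0s) - 30), 1)
  ## flat profile: no plateaus to fit
  expect_error(fit_reference_sigmoid(raw_profile(l, rep(1, length(l)))),
               "dynamic range")
})

test_that("alignment recovers constructed per-plane shifts", {
  f <- function(l) 1 / (1 + exp(0.3 * l))   # smooth: interp-friendly
  l <- seq(0, 50, by = 0.21)
  shifts <- c(0, 3.5, -2.1, 1.2)
  profs <- lapply(shifts, function(s) raw_profile(l, f(l - 20 - s)))
  refs <- 20 + shifts
  set <- align_profiles(profs, refs)
  expect_equal(set$dropped, 0L)
  spread <- apply(set$mat, 2, function(v) diff(range(v)))
  expect_lt(max(spread), 0.01)         # linear-interp error only
  ## identical profiles and refs: the average is any single profile
  set2 <- align_profiles(profs[c(1, 1, 1)], rep(20, 3))
  avg <- average_profiles(set2)
  ## linear interpolation of the logistic at 0.21 um spacing is accurate
  ## to ~ f'' h^2 / 8 ~ 5e-5
  expect_lt(max(abs(avg$P - f(avg$l))), 1e-4)
  expect_true(all(avg$sem == 0))
  ## planes without a reference are dropped and counted
  set3 <- align_profiles(profs, c(20, NA, 21.2, NA))
  expect_equal(nrow(set3$mat), 2L)
  expect_equal(set3$dropped, 2L)
  expect_error(align_profiles(profs, rep(NA_real_, 4)), "all planes")
})

test_that("alignment is invariant to a common coordinate shift", {
  f <- function(l) 1 / (1 + exp(0.4 * (l - 10)))
  l <- seq(0, 40, by = 0.21)
  profs <- lapply(c(0, 1.7), function(s) raw_profile(l, f(l - s)))
  refs <- c(10, 11.7)
  a <- average_profiles(align_profiles(profs, refs))
  profs2 <- lapply(profs, function(p) { p$l <- p$l + 5; p })
  b <- average_profiles(align_profiles(profs2, refs + 5))
  expect_equal(a$P, b$P, tolerance = 1e-10)
  expect_equal(a$l, b$l, tolerance = 1e-10)
})

test_that("averaging constants and repeats behaves arithmetically", {
  l <- seq(0, 10, by = 0.5)
  set <- align_profiles(list(raw_profile(l, rep(2, length(l))),
                             raw_profile(l, rep(5, length(l)))),
                        c(0, 0))
  avg <- average_profiles(set)
  expect_true(all(avg$P == 3.5))
  expect_true(all(avg$n == 2))
})

test_that("control subtraction: identity, annihilation, linearity", {
  l <- seq(-10, 10, by = 0.5)
  P <- morphoflat:::mean_profile(l, exp(-0.1 * pmax(l, 0)))
  zero <- morphoflat:::mean_profile(l, rep(0, length(l)))
  expect_equal(subtract_control(P, zero)$P, P$P)
  expect_true(all(abs(subtract_control(P, P)$P) < 1e-12))
  C1 <- morphoflat:::mean_profile(l, sin(l / 3) + 2)
  lincomb <- function(a, b, X, Y)
    morphoflat:::mean_profile(l, a * X$P + b * Y$P)
  lhs <- subtract_control(lincomb(2, 3, P, C1), lincomb(2, 3, zero, C1))
  expect_equal(lhs$P, 2 * P$P, tolerance = 1e-12)
  ## a constructed fold bump shared by data and control cancels
  bump <- gaussian_bump(l, 0, 0.4, 2)
  data <- morphoflat:::mean_profile(l, exp(-0.1 * pmax(l, 0)) + bump)
  ctrl <- morphoflat:::mean_profile(l, bump)
  expect_equal(subtract_control(data, ctrl)$P, exp(-0.1 * pmax(l, 0)),
               tolerance = 1e-12)
  ## disjoint grids error
  far <- morphoflat:::mean_profile(l + 100, rep(1, length(l)))
  expect_error(subtract_control(P, far), "disjoint")
})

test_that("depth correction recovers the attenuation slope and flattens", {
  l <- seq(0, 80, by = 0.21)
  s_true <- -0.02
  depth <- 8 + 0.15 * l                # apical depth varies along l'
  P <- morphoflat:::mean_profile(l, 0.5 * (1 + s_true * depth))
  dc <- depth_correction(P, depth)
  expect_lt(abs(dc$slope - s_true) / abs(s_true), 0.1)
  expect_lt(diff(range(dc$profile$P)), 1e-6)
  ## constant depth: identity with a warning
  expect_warning(
    dc0 <- depth_correction(P, rep(10, length(l))), "skipped")
  expect_identical(dc0$profile$P, P$P)
  expect_identical(dc0$slope, 0)
})

test_that("depth correction reduces decay-rate variability on attenuated
           stacks of varying fold depth", {
  ## replicates differ in fold depth (and hence in how much signal the
  ## attenuation removes around the fold); the tissue is slightly tilted
  ## so the far-anterior window spans a depth range to fit against
  ## the fitting window (l' > 30 um, ~4.5 decay lengths in) must be far
  ## enough anterior that the true gradient is dead, otherwise the linear
  ## fit attributes gradient decay to depth
  mus <- function(correct) {
    vapply(1:5, function(i) {
      tis <- tissue_spec(nx = 320L, ny = 3L, nz = 56L, surface_base_z = 8,
                         fold_center_x = 80, fold_depth_px = 4 + 2 * i,
                         fold_sigma_px = 8, tilt_px = 18,
                         roi_height_um = 6, seed = i)
      sig <- small_signal(noise_sigma = 0.02,
                          depth_attenuation_slope = -0.04)
      g <- generate_stack(tis, sig)
      cfg <- run_config("wildtype_gradient", roi_height_um = 6,
                        anterior_threshold_um = 30,
                        depth_correct = correct)
      run_pipeline(g$stack, cfg)$decay_rate
    }, 0)
  }
  expect_lt(sd(mus(TRUE)), sd(mus(FALSE)))
})

test_that("normalization matches direct substitution and records windows", {
  l <- seq(-20, 60, by = 0.5)
  P <- morphoflat:::mean_profile(l, ifelse(l < 0, 2, 0.5))
  nz <- normalize_profile(P, anterior_threshold_um = 40, source_window = 0)
  expect_equal(nz$P, (P$P - 0.5) / 1.5, tolerance = 1e-12)
  expect_equal(mean(nz$P[l < 0]), 1, tolerance = 1e-12)
  expect_equal(mean(nz$P[l > 40]), 0, tolerance = 1e-12)
  expect_identical(nz$anterior_threshold_um, 40)
  expect_identical(nz$source_threshold_um, 0)
  ## degenerate profile
  expect_error(normalize_profile(
    morphoflat:::mean_profile(l, rep(1, length(l)))), "degenerate")
  ## predicate windows
  nz2 <- normalize_profile(P, 40, source_window = function(l) l < -5)
  expect_equal(nz2$P, nz$P, tolerance = 1e-12)
})

test_that("normalization is idempotent", {
  l <- seq(-20, 60, by = 0.5)
  P <- morphoflat:::mean_profile(l, 0.3 + 1.7 * exp(-0.1 * pmax(l, 0)))
  n1 <- normalize_profile(P)
  n2 <- normalize_profile(n1)
  expect_equal(n1$P, n2$P, tolerance = 1e-9)
})
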