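#' Align per-plane profiles to their reference locations
#'
#' Shifts every profile's contour coordinate by its own reference
#' (`l' = l - l_ref`), then resamples all profiles onto a common regular
#' grid by linear interpolation. Planes whose reference is missing
#' (`NA`/`NULL`) are dropped and counted. The common grid spans the
#' intersection of the shifted coordinate ranges at `grid_spacing`.
#'
#' @param profiles list of `RawProfile`s.
#' @param refs numeric vector of per-plane reference positions `l_ref` in
#'   um (`NA` drops the plane).
#' @param grid_spacing common-grid spacing in um; defaults to the median
#'   native spacing of the first retained profile (nominally `dx`).
#' @param reference_kind label recorded for provenance, one of
#'   `"reporter-sigmoid"`, `"fold-center"`, `"morphogen-sigmoid"`,
#'   `"manual"`.
#' @return an `AlignedProfileSet`: list with `grid` (l' in um), `mat`
#'   (plane x grid intensity matrix, `NA` outside a plane's range), `refs`,
#'   `dropped` (count), `reference_kind`.
#' @export
align_profiles <- function(profiles, refs, grid_spacing = NULL,
                           reference_kind = c("reporter-sigmoid",
                                              "fold-center",
                                              "morphogen-sigmoid",
                                              "manual")) {
  reference_kind <- match.arg(reference_kind)
  stopifnot(length(profiles) == length(refs))
  n_in <- length(refs)
  keep <- which(is.finite(refs))
  if (!length(keep)) stop("all planes dropped: no finite references")
  profiles <- profiles[keep]; refs <- refs[keep]
  if (is.null(grid_spacing))
    grid_spacing <- stats::median(diff(profiles[[1]]$l))
  stopifnot(grid_spacing > 0)
  lo <- max(vapply(seq_along(profiles),
                   function(i) min(profiles[[i]]$l) - refs[i], 0))
  hi <- min(vapply(seq_along(profiles),
                   function(i) max(profiles[[i]]$l) - refs[i], 0))
  if (hi <= lo) stop("aligned profiles have no common coordinate range")
  grid <- seq(ceiling(lo / grid_spacing) * grid_spacing, hi,
              by = grid_spacing)
  mat <- t(vapply(seq_along(profiles), function(i) {
    stats::approx(profiles[[i]]$l - refs[i], profiles[[i]]$p,
                  xout = grid, rule = 1)$y
  }, numeric(length(grid))))
  structure(list(grid = grid, mat = mat, refs = refs,
                 dropped = n_in - length(keep),
                 reference_kind = reference_kind),
            class = "AlignedProfileSet")
}

#' Average an aligned profile set over planes
#'
#' Arithmetic mean and standard error per grid position over the planes
#' contributing at that position.
#'
#' @param set an `AlignedProfileSet`.
#' @return a `MeanProfile`: list with `l` (the l' grid), `P`, `sem`, `n`.
#' @export
average_profiles <- function(set) {
  stopifnot(inherits(set, "AlignedProfileSet"), nrow(set$mat) >= 1)
  n <- colSums(!is.na(set$mat))
  P <- colMeans(set$mat, na.rm = TRUE)
  sdev <- apply(set$mat, 2L, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 1, sdev / sqrt(n), 0)
  keep <- n >= 1
  structure(list(l = set$grid[keep], P = P[keep], sem = sem[keep],
                 n = n[keep]),
            class = "MeanProfile")
}

mean_profile <- function(l, P, sem = rep(0, length(P)),
                         n = rep(1L, length(P))) {
  structure(list(l = l, P = P, sem = sem, n = n), class = "MeanProfile")
}

#' Subtract a control (autofluorescence) profile
#'
#' Pointwise subtraction of a control mean profile from a data mean
#' profile, both aligned to the same reference (for folded tissue, the
#' average fold location, `l* = l - l_F`). The control is interpolated
#' onto the data grid; positions covered by only one profile are dropped.
#'
#' @param P,control `MeanProfile`s on a common coordinate frame.
#' @return a `MeanProfile` of the difference, with pooled standard errors.
#' @export
subtract_control <- function(P, control) {
  stopifnot(inherits(P, "MeanProfile"), inherits(control, "MeanProfile"))
  ci <- stats::approx(control$l, control$P, xout = P$l, rule = 1)$y
  cs <- stats::approx(control$l, control$sem, xout = P$l, rule = 1)$y
  keep <- is.finite(ci)
  if (!any(keep)) stop("empty result: profile grids are disjoint")
  structure(list(l = P$l[keep], P = P$P[keep] - ci[keep],
                 sem = sqrt(P$sem[keep]^2 + cs[keep]^2),
                 n = P$n[keep]),
            class = "MeanProfile")
}

#' Correct a mean profile for depth-dependent signal attenuation
#'
#' Fluorescence drops roughly linearly with imaging depth (distance from
#' the objective). The correction factor is estimated from the far-anterior
#' window -- where the true signal is flat, so any intensity variation
#' reflects depth -- by a least-squares linear fit of intensity against
#' depth. With fitted intensity `b0 * (1 + s * depth)`, the corrected
#' profile is `P / (1 + s * depth)` with the divisor floored at
#' `divisor_floor`.
#'
#' @param P a `MeanProfile`.
#' @param depth numeric vector, per-position depth of the quantified signal
#'   in um (same length/order as `P$l`); typically the band-center depth.
#' @param anterior_threshold_um left edge of the far-anterior fitting
#'   window on l' (default 40).
#' @param min_points,min_depth_range_um minimal window size (default 10
#'   positions) and depth span (default 2 um) for a trustworthy fit;
#'   otherwise the profile is returned unchanged with a warning and
#'   `slope = 0`.
#' @param divisor_floor lower bound for the correction divisor
#'   (default 0.1).
#' @return list with `profile` (corrected `MeanProfile`) and `slope` (the
#'   fitted fractional attenuation per um, `s`).
#' @export
depth_correction <- function(P, depth, anterior_threshold_um = 40,
                             min_points = 10L, min_depth_range_um = 2,
                             divisor_floor = 0.1) {
  stopifnot(inherits(P, "MeanProfile"), length(depth) == length(P$l))
  win <- which(P$l > anterior_threshold_um & is.finite(depth) &
                 is.finite(P$P))
  if (length(win) < min_points ||
      diff(range(depth[win])) < min_depth_range_um) {
    warning("insufficient depth variation in the far-anterior window; ",
            "depth correction skipped")
    return(list(profile = P, slope = 0))
  }
  fit <- stats::lm(P$P[win] ~ depth[win])
  b <- unname(stats::coef(fit))
  s <- b[2] / b[1]
  div <- pmax(1 + s * depth, divisor_floor)
  out <- P
  out$P <- P$P / div
  out$sem <- P$sem / div
  list(profile = out, slope = s)
}

#' Normalize a mean profile between source plateau and far-anterior floor
#'
#' Computes `P_norm(l') = (P(l') - P_A) / (mean_source(P) - P_A)`, where
#' `P_A` is the average intensity in the far anterior of the region of
#' interest (`l' > anterior_threshold_um`) and the source window is the
#' posterior compartment (`l' < source_threshold_um`, or an arbitrary
#' predicate). After normalization the source-window mean is 1 and the far
#' anterior is ~0, making profiles comparable across replicates.
#'
#' @param P a `MeanProfile`.
#' @param anterior_threshold_um far-anterior window `l' >` this value
#'   (default 40; the clone analysis uses 20).
#' @param source_window either a numeric threshold `t` meaning `l' < t`
#'   (default 0; the clone analysis uses -15) or a predicate
#'   `function(l)` returning the window mask.
#' @param tol minimum |denominator| before the normalization is declared
#'   degenerate (default 1e-8).
#' @return a `NormalizedProfile`: a `MeanProfile` with extra fields
#'   `P_A`, `source_mean`, `anterior_threshold_um`, `source_threshold_um`.
#' @export
normalize_profile <- function(P, anterior_threshold_um = 40,
                              source_window = 0, tol = 1e-8) {
  stopifnot(inherits(P, "MeanProfile"))
  ant <- P$l > anterior_threshold_um
  src <- if (is.function(source_window)) source_window(P$l)
         else P$l < source_window
  if (!any(ant)) stop("far-anterior window is empty")
  if (!any(src)) stop("source window is empty")
  P_A <- mean(P$P[ant])
  s_mean <- mean(P$P[src])
  denom <- s_mean - P_A
  if (abs(denom) < tol)
    stop("degenerate normalization: source mean equals anterior baseline")
  structure(list(l = P$l, P = (P$P - P_A) / denom, sem = P$sem / abs(denom),
                 n = P$n, P_A = P_A, source_mean = s_mean,
                 anterior_threshold_um = anterior_threshold_um,
                 source_threshold_um =
                   if (is.numeric(source_window)) source_window
                   else NA_real_),
            class = c("NormalizedProfile", "MeanProfile"))
}
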