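#' Tissue geometry specification for the synthetic generator
#'
#' Describes the geometry of a synthetic single-cell-layer epithelium imaged
#' in a 3D stack: a flat apical surface at `surface_base_z`, optionally
#' deformed by one Gaussian-shaped fold (the eye-disc morphogenetic-furrow
#' case), and a quantification band of fixed physical depth below the
#' surface. Defaults mirror the confocal acquisition settings the pipeline
#' was designed for (0.21 x 0.21 x 0.45 um voxels).
#'
#' @param nx,ny,nz image extents in pixels (x, y, z).
#' @param dx,dy,dz voxel size in micrometers.
#' @param surface_base_z flat apical height in (0-based, fractional) z
#'   pixels.
#' @param fold_center_x,fold_depth_px,fold_sigma_px Gaussian fold: apex
#'   location (x pixels), depth (z pixels; 0 disables the fold) and standard
#'   deviation (x pixels). The fold displaces the surface toward higher z.
#' @param tilt_px total linear z-drop of the surface from `x = 0` to
#'   `x = nx - 1` in pixels (default 0); emulates a mounted disc that is
#'   not perfectly level, giving the far anterior a depth range for the
#'   depth-attenuation correction to fit.
#' @param roi_height_um depth of the quantified band below the apical
#'   surface, in micrometers.
#' @param seed integer RNG seed; fully determines the generated stack.
#' @return a `TissueSpec` list.
#' @export
tissue_spec <- function(nx = 512L, ny = 8L, nz = 80L,
                        dx = 0.21, dy = 0.21, dz = 0.45,
                        surface_base_z = 15,
                        fold_center_x = 160, fold_depth_px = 0,
                        fold_sigma_px = 12, tilt_px = 0,
                        roi_height_um = 15, seed = 1L) {
  spec <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
               dx = dx, dy = dy, dz = dz,
               surface_base_z = surface_base_z,
               fold_center_x = fold_center_x,
               fold_depth_px = fold_depth_px,
               fold_sigma_px = fold_sigma_px,
               tilt_px = tilt_px,
               roi_height_um = roi_height_um,
               seed = as.integer(seed))
  class(spec) <- "TissueSpec"
  validate_tissue_spec(spec)
  spec
}

validate_tissue_spec <- function(spec) {
  with(spec, {
    if (nx < 1 || ny < 1 || nz < 1) stop("image extents must be >= 1")
    if (dx <= 0 || dy <= 0 || dz <= 0) stop("voxel sizes must be > 0")
    if (fold_depth_px < 0) stop("fold_depth_px must be >= 0")
    if (fold_sigma_px <= 0) stop("fold_sigma_px must be > 0")
    if (roi_height_um <= 0) stop("roi_height_um must be > 0")
    peak <- surface_base_z + abs(tilt_px) + fold_depth_px
    if (surface_base_z < 0 || peak > nz - 1)
      stop("geometry error: fold profile exceeds the z-range [0, nz-1]")
  })
  invisible(spec)
}

#' Signal specification for the synthetic generator
#'
#' Describes the four emulated channels along the apical contour:
#' a junctional marker (Gaussian blob of sigma = 1 z-pixel on the true
#' surface), a morphogen decaying exponentially with contour length anterior
#' to a source boundary, a sigmoidal reference reporter marking the source
#' compartment, and an F-actin channel with optional amplified clone
#' patches. All channels sit on a common background, are painted inside the
#' quantification band (the junctional blob on the surface itself), can be
#' attenuated linearly with absolute z-depth, and receive additive Gaussian
#' noise.
#'
#' @param decay_rate_mu exponential decay constant in 1/um along the apical
#'   contour (>= 0).
#' @param source_boundary_l contour-length position of the source/target
#'   boundary in um; the morphogen plateaus for `l < source_boundary_l` and
#'   decays beyond it.
#' @param sigmoid_steepness reference-reporter steepness in 1/um.
#' @param clone_intervals list of 0-based pixel intervals `c(x_start,
#'   x_end)` with elevated F-actin; must lie in `[0, nx-1]` and not overlap.
#' @param clone_factor multiplicative F-actin amplification inside clones.
#' @param noise_sigma additive Gaussian noise standard deviation as a
#'   fraction of the peak (unit) signal; >= 0.
#' @param depth_attenuation_slope fractional intensity change per um of
#'   absolute z-depth; negative values attenuate with depth (factor
#'   `max(1 + slope * z * dz, 0.1)`), 0 disables.
#' @param background baseline intensity of all channels.
#' @param amplitude peak signal amplitude above background for the morphogen
#'   and reporter channels.
#' @return a `SignalSpec` list.
#' @export
signal_spec <- function(decay_rate_mu = 0.1, source_boundary_l = 33.6,
                        sigmoid_steepness = 0.5,
                        clone_intervals = NULL, clone_factor = 2,
                        noise_sigma = 0.05, depth_attenuation_slope = 0,
                        background = 0.05, amplitude = 0.75) {
  if (decay_rate_mu < 0) stop("decay_rate_mu must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(clone_intervals)) {
    ci <- do.call(rbind, lapply(clone_intervals, function(iv) {
      stopifnot(length(iv) == 2L, iv[1] <= iv[2])
      as.numeric(iv)
    }))
    o <- order(ci[, 1])
    ci <- ci[o, , drop = FALSE]
    if (nrow(ci) > 1 && any(ci[-1, 1] <= ci[-nrow(ci), 2]))
      stop("clone intervals must not overlap")
    clone_intervals <- lapply(seq_len(nrow(ci)), function(i) ci[i, ])
  }
  structure(list(decay_rate_mu = decay_rate_mu,
                 source_boundary_l = source_boundary_l,
                 sigmoid_steepness = sigmoid_steepness,
                 clone_intervals = clone_intervals,
                 clone_factor = clone_factor,
                 noise_sigma = noise_sigma,
                 depth_attenuation_slope = depth_attenuation_slope,
                 background = background,
                 amplitude = amplitude),
            class = "SignalSpec")
}

## true apical height per column, 0-based fractional z pixels
true_surface <- function(tissue) {
  x <- seq_len(tissue$nx) - 1
  tissue$surface_base_z +
    tissue$tilt_px * (1 - x / (tissue$nx - 1)) +
    tissue$fold_depth_px *
    exp(-(x - tissue$fold_center_x)^2 / (2 * tissue$fold_sigma_px^2))
}

## discrete arc length along a fractional profile, in um
arc_length <- function(a, dx, dz) {
  if (length(a) == 1L) return(0)
  d <- sqrt(dx^2 + (diff(a) * dz)^2)
  c(0, cumsum(d))
}

#' Generate a synthetic multi-channel stack with ground truth
#'
#' Renders a 4-channel stack (`junctional`, `morphogen`, `reference`,
#' `factin`) from a [tissue_spec()] and a [signal_spec()]. The morphogen
#' band-mean at each column equals
#' `background + amplitude * exp(-mu * max(l - l0, 0))` before noise, where
#' `l` is the true apical contour length, so every downstream stage can be
#' checked against a closed form. Identical seeds give identical stacks.
#'
#' @param tissue a [tissue_spec()].
#' @param signal a [signal_spec()].
#' @param quantize16 if `TRUE`, quantize intensities to 16-bit integers
#'   (clipped to `[0, 1]` first) and rescale back to `[0, 1]`; off by
#'   default so closed-form oracles are exact.
#' @return list with elements `stack` (an [image_stack()]) and `truth`, a
#'   `GroundTruth` list carrying the true surface `a` (0-based z pixels),
#'   contour map `l` (um), `mu`, `l0`, band row range per column (0-based,
#'   inclusive), fold descriptors and clone extents in x pixels and um.
#' @export
generate_stack <- function(tissue, signal, quantize16 = FALSE) {
  validate_tissue_spec(tissue)
  stopifnot(inherits(signal, "SignalSpec"))
  if (!is.null(signal$clone_intervals)) {
    hi <- max(vapply(signal$clone_intervals, max, 0))
    if (hi > tissue$nx - 1) stop("clone interval outside [0, nx-1]")
  }
  nx <- tissue$nx; ny <- tissue$ny; nz <- tissue$nz
  a <- true_surface(tissue)
  l <- arc_length(a, tissue$dx, tissue$dz)
  band_px <- as.integer(ceiling(tissue$roi_height_um / tissue$dz))
  z0 <- as.integer(round(a))                     # first band row, 0-based
  if (any(z0 + band_px - 1L > nz - 1L))
    stop("geometry error: quantification band exceeds the z-range")

  zc <- seq_len(nz) - 1                          # 0-based z per row
  in_band <- outer(zc, z0, function(z, s) z >= s & z < s + band_px)

  bg <- signal$background; A <- signal$amplitude
  lp <- pmax(l - signal$source_boundary_l, 0)
  morph_x <- A * exp(-signal$decay_rate_mu * lp)
  ref_x <- A / (1 + exp(signal$sigmoid_steepness *
                          (l - signal$source_boundary_l)))
  in_clone <- rep(FALSE, nx)
  for (iv in signal$clone_intervals %||% list())
    in_clone[(seq_len(nx) - 1) >= iv[1] & (seq_len(nx) - 1) <= iv[2]] <- TRUE
  factin_x <- 0.25 * A * ifelse(in_clone, signal$clone_factor, 1)

  ## junctional blob: sigma 1.6 z-px so that exactly the 5 pixels nearest
  ## the surface stay above the noise floor at 5% additive noise
  junc <- bg + 0.9 * exp(-outer(zc, a, "-")^2 / (2 * 1.6^2))
  morph <- bg + in_band * rep(morph_x, each = nz)
  refc <- bg + in_band * rep(ref_x, each = nz)
  fact <- bg + in_band * rep(factin_x, each = nz)

  att <- pmax(1 + signal$depth_attenuation_slope * zc * tissue$dz, 0.1)
  chans <- lapply(list(junc, morph, refc, fact), function(m) m * att)

  set.seed(tissue$seed)
  data <- array(0, dim = c(nz, nx, ny, 4L))
  for (ch in 1:4) for (y in seq_len(ny)) {
    plane <- chans[[ch]]
    if (signal$noise_sigma > 0)
      plane <- plane + matrix(stats::rnorm(nz * nx, 0, signal$noise_sigma),
                              nz, nx)
    data[, , y, ch] <- plane
  }
  if (quantize16) {
    data <- pmin(pmax(data, 0), 1)
    data <- round(data * 65535) / 65535
  }
  stack <- image_stack(data, c(tissue$dx, tissue$dy, tissue$dz),
                       c("junctional", "morphogen", "reference", "factin"))

  half_w <- tissue$fold_sigma_px * sqrt(2 * log(2))
  truth <- list(
    a = a, l = l, mu = signal$decay_rate_mu,
    l0 = signal$source_boundary_l,
    band_rows = cbind(start = z0, end = z0 + band_px - 1L),
    band_px = band_px,
    attenuation_slope = signal$depth_attenuation_slope,
    background = bg, amplitude = A,
    fold = if (tissue$fold_depth_px > 0)
      list(x_F = tissue$fold_center_x,
           x_S = tissue$fold_center_x - half_w,
           x_E = tissue$fold_center_x + half_w,
           depth = tissue$fold_depth_px,
           sigma = tissue$fold_sigma_px)
    else NULL,
    clones_x = signal$clone_intervals,
    clones_l = lapply(signal$clone_intervals %||% list(), function(iv) {
      stats::approx(seq_len(nx) - 1, l, xout = iv)$y
    }))
  class(truth) <- "GroundTruth"
  list(stack = stack, truth = truth)
}

#' Built-in synthetic presets
#'
#' Named parameterizations of the generator corresponding to the tissue
#' types the pipeline targets:
#' \describe{
#'   \item{`wing_wt`}{flat wing-disc-like tissue (no fold), sharp reporter
#'     boundary, 15 um band.}
#'   \item{`eye_wt`}{eye-disc-like tissue with a morphogenetic-furrow-like
#'     fold at the source boundary and a graded reporter, 15 um band.}
#'   \item{`wing_fold`}{wing disc with an ectopic fold at the boundary,
#'     10 um band (the cadherin-overexpression configuration).}
#'   \item{`eye_no_furrow_clone`}{eye disc carrying one F-actin-amplified
#'     clone patch covering the furrow area.}
#'   \item{`hh_reference`}{eye-disc-like geometry with the decay rate set to
#'     the reference Hedgehog value of 0.1 um^-1; used for decay-rate
#'     recovery benchmarks.}
#' }
#'
#' @param name preset name.
#' @param seed integer RNG seed stored in the returned tissue spec.
#' @return list with elements `tissue` and `signal`.
#' @export
preset <- function(name = c("wing_wt", "eye_wt", "wing_fold",
                            "eye_no_furrow_clone", "hh_reference"),
                   seed = 1L) {
  name <- match.arg(name)
  switch(name,
    wing_wt = list(
      tissue = tissue_spec(nz = 60L, fold_depth_px = 0, roi_height_um = 15,
                           seed = seed),
      signal = signal_spec(decay_rate_mu = 0.1, sigmoid_steepness = 1.5)),
    eye_wt = list(
      tissue = tissue_spec(nz = 80L, fold_depth_px = 15, fold_sigma_px = 12,
                           fold_center_x = 160, roi_height_um = 15,
                           seed = seed),
      signal = signal_spec(decay_rate_mu = 0.1, sigmoid_steepness = 0.3,
                           source_boundary_l = 35)),
    wing_fold = list(
      tissue = tissue_spec(nz = 70L, fold_depth_px = 12, fold_sigma_px = 12,
                           fold_center_x = 160, roi_height_um = 10,
                           seed = seed),
      signal = signal_spec(decay_rate_mu = 0.1, sigmoid_steepness = 1.5,
                           source_boundary_l = 34.5)),
    eye_no_furrow_clone = list(
      tissue = tissue_spec(nz = 80L, fold_depth_px = 15, fold_sigma_px = 12,
                           fold_center_x = 160, roi_height_um = 15,
                           seed = seed),
      signal = signal_spec(decay_rate_mu = 0.1, sigmoid_steepness = 0.3,
                           source_boundary_l = 35,
                           clone_intervals = list(c(140, 190)),
                           clone_factor = 2)),
    hh_reference = list(
      tissue = tissue_spec(nz = 80L, fold_depth_px = 15, fold_sigma_px = 12,
                           fold_center_x = 160, roi_height_um = 15,
                           seed = seed),
      signal = signal_spec(decay_rate_mu = 0.1, sigmoid_steepness = 0.3,
                           source_boundary_l = 35, noise_sigma = 0.05)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
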