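#' Extract the apical profile from an x-z plane
#'
#' For each image column, the apical surface height is estimated as the mean
#' z-location of the `k` brightest pixels of that column in the junctional
#' (adherens-junction marker) channel. Ties among the k-th brightest pixels
#' are broken deterministically toward lower z (closer to the objective).
#' Columns whose brightest pixel falls below `intensity_floor` are flagged
#' invalid (no tissue under the column).
#'
#' @param plane `nz x nx` matrix, one x-z plane of the junctional channel
#'   (rows are z).
#' @param k number of brightest pixels to average (default 5).
#' @param intensity_floor minimum brightest-pixel intensity for a column to
#'   be considered valid; `NULL` (default) accepts all columns.
#' @param plane_index optional 0-based y index, stored for provenance.
#' @return an `ApicalProfile`: list with `a` (0-based fractional z heights,
#'   length nx), `valid` (logical), `plane_index`, `nz`.
#' @export
extract_apical_profile <- function(plane, k = 5L, intensity_floor = NULL,
                                   plane_index = NA_integer_) {
  stopifnot(is.matrix(plane), k >= 1L)
  nz <- nrow(plane)
  if (nz < k) stop("plane z-extent (", nz, ") is smaller than k = ", k)
  zc <- seq_len(nz) - 1
  a <- apply(plane, 2L, function(col) {
    top <- order(col, zc, decreasing = c(TRUE, FALSE), method = "radix")[1:k]
    mean(zc[top])
  })
  valid <- if (is.null(intensity_floor)) rep(TRUE, ncol(plane))
           else apply(plane, 2L, max) >= intensity_floor
  a[!valid] <- NA_real_
  structure(list(a = a, valid = valid,
                 plane_index = plane_index, nz = nz),
            class = "ApicalProfile")
}

#' Fill invalid profile columns by linear interpolation
#'
#' Columns where surface extraction failed are filled from the nearest valid
#' neighbors (constant extrapolation at the ends) so that flattening and
#' contour-length computation can operate on a complete profile. The
#' `valid` mask is preserved so downstream consumers can still drop these
#' columns from quantification.
#'
#' @param profile an `ApicalProfile`.
#' @return the profile with `a` gap-filled.
#' @export
fill_invalid_profile <- function(profile) {
  stopifnot(inherits(profile, "ApicalProfile"))
  v <- profile$valid
  if (all(v)) return(profile)
  if (!any(v)) stop("no valid columns to interpolate from")
  x <- seq_along(profile$a)
  profile$a <- stats::approx(x[v], profile$a[v], xout = x, rule = 2)$y
  profile
}

## local maxima of a numeric vector (plateaus -> middle sample)
local_maxima <- function(a) {
  n <- length(a)
  if (n < 3) return(integer(0))
  rle_a <- rle(a)
  ends <- cumsum(rle_a$lengths)
  starts <- ends - rle_a$lengths + 1L
  k <- length(rle_a$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i > 1L && rle_a$values[i - 1L] < rle_a$values[i]
    right_ok <- i < k && rle_a$values[i + 1L] < rle_a$values[i]
    if (left_ok && right_ok)
      out <- c(out, as.integer(floor((starts[i] + ends[i]) / 2)))
  }
  out
}

## topographic prominence of peak at index i (1-based)
peak_prominence <- function(a, i) {
  n <- length(a)
  h <- a[i]
  left <- a[seq_len(i - 1L)]
  higher_l <- which(left > h)
  lo_l <- if (length(higher_l)) min(a[(max(higher_l) + 1L):(i - 1L)])
          else min(left)
  right <- a[(i + 1L):n]
  higher_r <- which(right > h)
  lo_r <- if (length(higher_r)) min(a[(i + 1L):(i + min(higher_r) - 1L)])
          else min(right)
  h - max(lo_l, lo_r)
}

#' Detect the tissue fold in an apical profile
#'
#' Finds peaks of the apical profile `a(x)`, restricts them to a window of
#' `window` pixels around the fold center found in the previous x-z plane
#' (or considers all peaks when `prev_center` is `NULL`), and returns the
#' peak with the largest width. Width is measured at half the peak's
#' topographic prominence; the fold start `x_S` and end `x_E` are the
#' nearest columns at which the profile falls to that half height on either
#' side of the apex `x_F`.
#'
#' @param profile an `ApicalProfile` (gap-filled if it has invalid columns).
#' @param prev_center 0-based x position of the fold in the previous plane,
#'   or `NULL` to search the whole profile.
#' @param window half-width of the search window in pixels (default 50).
#' @param min_prominence minimum peak prominence in z-pixels for a peak to
#'   count as a fold (default 1), suppressing noise-level wiggles.
#' @param polarity `"max"` if the fold displaces the surface toward higher
#'   z, `"min"` for the opposite image orientation.
#' @return a `FoldDescriptor` (list with 0-based `x_S`, `x_F`, `x_E`,
#'   `depth` = prominence in z-pixels, `plane_index`), or `NULL` when no
#'   qualifying peak lies in the window.
#' @export
detect_fold <- function(profile, prev_center = NULL, window = 50,
                        min_prominence = 1, polarity = c("max", "min")) {
  stopifnot(inherits(profile, "ApicalProfile"))
  polarity <- match.arg(polarity)
  a <- profile$a
  if (anyNA(a)) a <- fill_invalid_profile(profile)$a
  if (polarity == "min") a <- -a
  peaks <- local_maxima(a)
  if (!length(peaks)) return(NULL)
  proms <- vapply(peaks, function(i) peak_prominence(a, i), 0)
  keep <- proms >= min_prominence
  if (!is.null(prev_center))
    keep <- keep & abs((peaks - 1) - prev_center) <= window
  peaks <- peaks[keep]; proms <- proms[keep]
  if (!length(peaks)) return(NULL)

  measure <- function(i, prom) {
    h <- a[i] - prom / 2
    left <- which(a[seq_len(i)] <= h)
    xs <- if (length(left)) max(left) else 1L
    right <- which(a[i:length(a)] <= h)
    xe <- if (length(right)) i + min(right) - 1L else length(a)
    c(xs = xs, xe = xe, width = xe - xs)
  }
  m <- mapply(measure, peaks, proms)
  best <- which.max(m["width", ])
  structure(list(x_S = as.numeric(m["xs", best] - 1),
                 x_F = as.numeric(peaks[best] - 1),
                 x_E = as.numeric(m["xe", best] - 1),
                 depth = proms[best],
                 plane_index = profile$plane_index),
            class = "FoldDescriptor")
}

#' Track the fold across all x-z planes of a stack
#'
#' Repeats [detect_fold()] plane by plane, centering each plane's search
#' window on the fold center of the previous successfully detected plane.
#' The starting center for the first plane is supplied manually
#' (`seed_center`), mirroring interactive seeding on real data.
#'
#' @param stack an [image_stack()] containing a junctional channel.
#' @param seed_center 0-based x position seeding the search in the first
#'   plane.
#' @param channel junctional channel name or index (default "junctional").
#' @param window,min_prominence,polarity passed to [detect_fold()].
#' @param k,intensity_floor passed to [extract_apical_profile()].
#' @param max_missing_frac maximum tolerated fraction of planes without a
#'   fold before tracking is declared failed (default 0.5).
#' @return list of `FoldDescriptor` (or `NULL` for planes where detection
#'   failed), one per x-z plane.
#' @export
track_fold <- function(stack, seed_center, channel = "junctional",
                       window = 50, min_prominence = 1,
                       polarity = "max", k = 5L, intensity_floor = NULL,
                       max_missing_frac = 0.5) {
  stopifnot(inherits(stack, "ImageStack"))
  ny <- n_planes(stack)
  prev <- seed_center
  out <- vector("list", ny)
  for (y in seq_len(ny)) {
    prof <- extract_apical_profile(xz_plane(stack, y - 1, channel),
                                   k = k, intensity_floor = intensity_floor,
                                   plane_index = y - 1L)
    fd <- detect_fold(prof, prev_center = prev, window = window,
                      min_prominence = min_prominence, polarity = polarity)
    out[[y]] <- fd
    if (!is.null(fd)) prev <- fd$x_F
  }
  missing <- mean(vapply(out, is.null, TRUE))
  if (missing > max_missing_frac)
    stop(sprintf("fold tracking failure: no fold in %.0f%% of planes",
                 100 * missing))
  out
}
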