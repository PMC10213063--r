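#' Computationally flatten an x-z plane along the apical profile
#'
#' Each column is shifted along z by the integer-rounded offset
#' `shift(x) = round(max(a) - a(x))` so that the apical edge aligns to the
#' deepest apical position, taken as the reference. Shifts are integer-pixel
#' with zero padding (the output gains `max(shift)` extra rows), so each
#' column's pixel multiset -- and hence its z-projection (column sum) -- is
#' conserved exactly.
#'
#' @param plane `nz x nx` matrix (any channel; the shift comes from the
#'   profile, which is normally extracted from the junctional channel).
#' @param profile an `ApicalProfile` of the same x-extent; invalid columns
#'   are gap-filled internally for shift computation.
#' @return a `FlattenedPlane`: list with `image` (`(nz + max(shift)) x nx`),
#'   `shift` (integer per column), `roi_top_z` (0-based z row of the
#'   flattened apical edge, `round(max(a))`), `valid` (per-column flag
#'   propagated from the profile), `nz_in`.
#' @export
flatten_plane <- function(plane, profile) {
  stopifnot(is.matrix(plane), inherits(profile, "ApicalProfile"),
            ncol(plane) == length(profile$a))
  prof <- fill_invalid_profile(profile)
  a <- prof$a
  shift <- as.integer(round(max(a) - a))
  nz <- nrow(plane); nx <- ncol(plane)
  out <- matrix(0, nz + max(shift), nx)
  for (x in seq_len(nx))
    out[shift[x] + seq_len(nz), x] <- plane[, x]
  structure(list(image = out, shift = shift,
                 roi_top_z = as.integer(round(max(a))),
                 valid = profile$valid, nz_in = nz),
            class = "FlattenedPlane")
}

#' Crop the fixed-depth quantification band from a flattened plane
#'
#' Returns the rectangle of `ceiling(height_um / dz)` rows whose top side
#' overlaps the flattened apical edge, i.e. the band of tissue of fixed
#' physical depth below the apical surface.
#'
#' @param flat a `FlattenedPlane`.
#' @param height_um band depth in micrometers (> 0).
#' @param dz z voxel size in micrometers.
#' @return numeric matrix of `ceiling(height_um / dz)` rows.
#' @export
crop_band <- function(flat, height_um, dz = 0.45) {
  stopifnot(inherits(flat, "FlattenedPlane"))
  if (height_um <= 0) stop("height_um must be > 0")
  n_rows <- as.integer(ceiling(height_um / dz))
  top <- flat$roi_top_z                    # 0-based row of apical edge
  img <- flat$image
  need <- top + n_rows
  if (need > nrow(img))                    # pad below; padded rows are empty
    img <- rbind(img, matrix(0, need - nrow(img), ncol(img)))
  img[top + seq_len(n_rows), , drop = FALSE]
}

#' Contour length along the apical profile
#'
#' Cumulative arc length of the apical profile with anisotropic voxels:
#' per-step increment `d(x) = sqrt(dx^2 + ((a(x) - a(x-1)) * dz)^2)` and
#' `l(x) = l(x-1) + d(x)`, `l(0) = 0`. For a flat profile this reduces to
#' `l(x) = x * dx`. The raw fractional profile is used as-is (no rounding,
#' no smoothing by default).
#'
#' @param profile an `ApicalProfile` (gap-filled internally if needed) or a
#'   bare numeric vector of heights in z-pixels.
#' @param dx,dz voxel sizes in micrometers.
#' @param smooth_window optional odd window length for a centered running
#'   mean applied to the profile before differencing; `NULL` (default)
#'   disables smoothing.
#' @return a `ContourMap`: list with `l` (length nx, um, `l[1] = 0`) and
#'   `d` (length nx - 1, per-step increments in um).
#' @export
contour_length <- function(profile, dx = 0.21, dz = 0.45,
                           smooth_window = NULL) {
  if (inherits(profile, "ApicalProfile"))
    a <- fill_invalid_profile(profile)$a
  else a <- as.numeric(profile)
  stopifnot(dx > 0, dz > 0, !anyNA(a))
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    stopifnot(w >= 1L, w %% 2L == 1L)
    a <- as.numeric(stats::filter(a, rep(1 / w, w), sides = 2))
    ok <- which(!is.na(a))
    a[seq_len(min(ok) - 1)] <- a[min(ok)]
    if (max(ok) < length(a)) a[(max(ok) + 1):length(a)] <- a[max(ok)]
  }
  da <- diff(a)
  d <- ifelse(da == 0, dx, sqrt(dx^2 + (da * dz)^2))
  structure(list(l = c(0, cumsum(d)), d = d), class = "ContourMap")
}

#' Band-mean intensity profile against the contour coordinate
#'
#' Averages the band over z for each column and pairs the result with the
#' contour-length coordinate, giving the raw (per-plane) intensity profile
#' `p(l)`.
#'
#' @param band matrix from [crop_band()].
#' @param contour a `ContourMap` with `length(l) == ncol(band)`.
#' @param valid optional logical per-column mask; invalid columns are
#'   dropped (with a warning if any).
#' @param plane_index,channel provenance fields.
#' @return a `RawProfile`: list with `p`, `l`, `plane_index`, `channel`.
#' @export
band_profile <- function(band, contour, valid = NULL,
                         plane_index = NA_integer_, channel = NA_character_) {
  stopifnot(is.matrix(band), inherits(contour, "ContourMap"),
            ncol(band) == length(contour$l))
  p <- colMeans(band)
  l <- contour$l
  if (!is.null(valid) && !all(valid)) {
    warning(sum(!valid), " invalid column(s) dropped from band profile")
    p <- p[valid]; l <- l[valid]
  }
  structure(list(p = p, l = l, plane_index = plane_index, channel = channel),
            class = "RawProfile")
}
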