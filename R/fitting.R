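## ---- shared fit machinery ------------------------------------------------

fit_result <- function(model, params, rss, y, domain, converged,
                       extra = list()) {
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(c(list(model = model, params = params,
                   r_squared = r2, rss = rss,
                   domain = range(domain), n = length(y),
                   converged = converged),
              extra),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult <%s>%s  R^2 = %.4f  (n = %d, domain [%.2f, %.2f])\n",
              x$model, if (x$converged) "" else " [NOT CONVERGED]",
              x$r_squared, x$n, x$domain[1], x$domain[2]))
  print(round(x$params, 6))
  invisible(x)
}

## deterministic nonlinear least squares: Nelder-Mead to approach the
## basin, then BFGS to polish. `fn(params, x)` predicts, `start` is a named
## vector. Returns list(params, rss, converged).
nls_or_optim <- function(fn, x, y, start, lower = NULL) {
  rss_of <- function(p) {
    r <- y - fn(p, x)
    if (any(!is.finite(r))) return(1e300)
    sum(r^2)
  }
  o1 <- stats::optim(start, rss_of, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  o2 <- tryCatch(stats::optim(o1$par, rss_of, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-12)),
                 error = function(e) o1)
  best <- if (o2$value <= o1$value) o2 else o1
  p <- best$par
  if (!is.null(lower)) p <- pmax(p, lower[names(p)])
  list(params = p, rss = rss_of(p),
       converged = is.finite(best$value) && best$value < 1e299)
}

profile_xy <- function(profile) {
  if (inherits(profile, c("MeanProfile", "NormalizedProfile")))
    list(x = profile$l, y = profile$P)
  else if (inherits(profile, "RawProfile"))
    list(x = profile$l, y = profile$p)
  else if (is.list(profile) && !is.null(profile$l))
    list(x = profile$l, y = profile$P %||% profile$p)
  else stop("cannot extract (l, intensity) from object of class ",
            paste(class(profile), collapse = "/"))
}

## ---- exponential ---------------------------------------------------------

#' Fit a single exponential decay to a gradient profile
#'
#' Fits `f(l') = A * exp(-mu * l')` by least squares on the restricted
#' domain `l' > domain_start` (by default the receiving/anterior
#' compartment, `l' > 0`). `mu` is the gradient decay rate in 1/um.
#' Initialization: `A` from the first fitted point, `mu` from a log-linear
#' regression on the positive values.
#'
#' @param profile a `NormalizedProfile`, `MeanProfile` or `RawProfile` (or
#'   any list with `l` and `P`/`p`).
#' @param domain_start left edge of the fitted domain in um (default 0).
#' @param min_points minimum number of points beyond `domain_start`
#'   (default 10).
#' @return a `FitResult` with params `A`, `mu`. Negative fitted `mu` is
#'   allowed but flagged with a warning.
#' @export
fit_exponential <- function(profile, domain_start = 0, min_points = 10L) {
  d <- profile_xy(profile)
  keep <- is.finite(d$x) & is.finite(d$y) & d$x > domain_start
  x <- d$x[keep]; y <- d$y[keep]
  if (length(x) < min_points)
    stop("fewer than ", min_points, " points beyond domain_start")
  pos <- y > 0
  mu0 <- if (sum(pos) >= 2)
    -unname(stats::coef(stats::lm(log(y[pos]) ~ x[pos]))[2]) else 0.05
  if (!is.finite(mu0)) mu0 <- 0.05
  A0 <- max(y[which.min(x)], 1e-6)
  fn <- function(p, x) p["A"] * exp(-p["mu"] * x)
  f <- nls_or_optim(fn, x, y, c(A = A0, mu = mu0))
  if (f$params["mu"] < 0)
    warning("fitted decay rate is negative (", signif(f$params["mu"], 3), ")")
  fit_result("exponential", f$params, f$rss, y, x, f$converged)
}

## ---- sigmoids ------------------------------------------------------------

sigmoid_fit_core <- function(x, y, fix_A = FALSE) {
  o <- order(x); x <- x[o]; y <- y[o]
  ylo <- stats::quantile(y, 0.05, names = FALSE)
  yhi <- stats::quantile(y, 0.95, names = FALSE)
  A0 <- if (fix_A) 1 else max(yhi, 1e-6)
  half <- ylo + (yhi - ylo) / 2
  ## decreasing sigmoid: high plateau at low l
  cross <- function(level) {
    i <- which(y <= level)[1]
    if (is.na(i) || i == 1L) stats::median(x) else x[i]
  }
  l00 <- cross(half)
  span <- cross(ylo + 0.25 * (yhi - ylo)) - cross(ylo + 0.75 * (yhi - ylo))
  mu0 <- if (is.finite(span) && span > 0) 2 * log(3) / span else 0.5
  if (fix_A) {
    fn <- function(p, x) 1 / (1 + exp(p["mu"] * (x - p["l0"])))
    start <- c(mu = mu0, l0 = l00)
  } else {
    fn <- function(p, x) p["A"] / (1 + exp(p["mu"] * (x - p["l0"])))
    start <- c(A = A0, mu = mu0, l0 = l00)
  }
  f <- nls_or_optim(fn, x, y, start)
  if (fix_A) f$params <- c(A = 1, f$params)
  list(fit = f, x = x, y = y)
}

#' Fit the reference-reporter sigmoid used for profile alignment
#'
#' Fits `f(l) = A / (1 + exp(mu * (l - l0)))` to a reporter profile (high
#' plateau in the source compartment, low in the receiving tissue). The
#' location parameter `l0` -- the inflection point -- serves as the
#' alignment reference for the plane.
#'
#' @param profile a `RawProfile` or `MeanProfile` covering both plateaus.
#' @param min_dynamic_range minimum `max - min` of the data for a fit to be
#'   attempted (default 0.05 intensity units).
#' @return a `FitResult` with params `A`, `mu`, `l0`. `converged` is
#'   `FALSE` (fit-failure signal) when the optimizer fails or `l0` falls
#'   outside the data range.
#' @export
fit_reference_sigmoid <- function(profile, min_dynamic_range = 0.05) {
  d <- profile_xy(profile)
  keep <- is.finite(d$x) & is.finite(d$y)
  x <- d$x[keep]; y <- d$y[keep]
  if (diff(range(y)) <= min_dynamic_range)
    stop("profile dynamic range below floor; no plateaus to fit")
  s <- sigmoid_fit_core(x, y, fix_A = FALSE)
  ok <- s$fit$converged &&
    s$fit$params["l0"] >= min(x) && s$fit$params["l0"] <= max(x)
  fit_result("sigmoid", s$fit$params, s$fit$rss, y, x, ok)
}

#' Fit the source-boundary sigmoid to a normalized gradient profile
#'
#' Fits `f(l') = 1 / (1 + exp(mu * (l' - l0)))` (unit amplitude; the
#' profile is already normalized) and returns the location parameter `l0`,
#' interpreted as the boundary between source and target tissue.
#'
#' @param profile a `NormalizedProfile` (or compatible list).
#' @return a `FitResult` with params `A` (fixed 1), `mu`, `l0`.
#' @export
fit_boundary_sigmoid <- function(profile) {
  d <- profile_xy(profile)
  keep <- is.finite(d$x) & is.finite(d$y)
  s <- sigmoid_fit_core(d$x[keep], d$y[keep], fix_A = TRUE)
  ok <- s$fit$converged &&
    s$fit$params["l0"] >= min(s$x) && s$fit$params["l0"] <= max(s$x)
  fit_result("sigmoid", s$fit$params, s$fit$rss, s$y, s$x, ok)
}

## ---- F-actin increment and clone Gaussians -------------------------------

#' Standardized F-actin increment of a clone region relative to wild type
#'
#' Pointwise z-like score `(A_clone - A_wt) / sqrt(sem_clone^2 + sem_wt^2)`
#' on the common contour grid, where the standard errors are those of the
#' two averaged profiles. Positions with zero pooled standard error are
#' dropped.
#'
#' @param clone,wt `MeanProfile`s of the F-actin channel on a common grid.
#' @return list with `l` and `increment`.
#' @export
factin_increment <- function(clone, wt) {
  stopifnot(inherits(clone, "MeanProfile"), inherits(wt, "MeanProfile"))
  if (length(clone$l) != length(wt$l) ||
      max(abs(clone$l - wt$l)) > 1e-8)
    stop("profiles are not on a common grid")
  pooled <- sqrt(clone$sem^2 + wt$sem^2)
  keep <- is.finite(pooled) & pooled > 0 &
    is.finite(clone$P) & is.finite(wt$P)
  list(l = clone$l[keep],
       increment = (clone$P[keep] - wt$P[keep]) / pooled[keep])
}

gaussian1_fn <- function(p, x) p["A"] * exp(-p["B"] * (x - p["l0"])^2)
gaussian2_fn <- function(p, x)
  p["A1"] * exp(-p["B1"] * (x - p["l01"])^2) +
  p["A2"] * exp(-p["B2"] * (x - p["l02"])^2)

## peak-based starts for 1 or 2 Gaussians
gaussian_starts <- function(x, y, k) {
  i1 <- which.max(y)
  hw <- function(i) {
    h <- y[i] / 2
    left <- which(y[seq_len(i)] <= h); ls <- if (length(left)) max(left) else 1
    right <- which(y[i:length(y)] <= h)
    rs <- if (length(right)) i + min(right) - 1 else length(y)
    max(x[rs] - x[ls], 2 * stats::median(diff(x)))
  }
  B1 <- log(2) / (hw(i1) / 2)^2
  if (k == 1) return(c(A = y[i1], B = B1, l0 = x[i1]))
  mask <- abs(x - x[i1]) > hw(i1)
  i2 <- if (any(mask)) which(mask)[which.max(y[mask])] else
    if (i1 > length(y) / 2) 1L else length(y)
  c(A1 = y[i1], B1 = B1, l01 = x[i1],
    A2 = max(y[i2], 0.1 * y[i1]), B2 = log(2) / (hw(i2) / 2)^2, l02 = x[i2])
}

#' Fit single and double Gaussians to an F-actin increment profile
#'
#' Both models -- `A * exp(-B (l - l0)^2)` and the sum of two such terms --
#' are fitted to the increment profile; the clone location is taken from
#' the better model. Because the double Gaussian nests the single one, raw
#' goodness of fit always favors the double model, so selection uses a
#' parsimony-penalized comparison (BIC on the residual sum of squares, 3
#' vs 6 parameters); both coefficients of determination are reported. The
#' clone extent is the union of the intervals where each fitted component
#' exceeds half its amplitude.
#'
#' @param increment list with `l` and `increment` from [factin_increment()],
#'   or any list with `l` and `p`/`P`.
#' @param significance_floor minimum peak increment (z-units) for a clone to
#'   be considered present (default 2).
#' @return a `FitResult` (model `gaussian1` or `gaussian2`) with extra
#'   fields `r_squared_g1`, `r_squared_g2`, `bic_g1`, `bic_g2`, `extent`
#'   (um, half-amplitude union) and `components` (per-component half-max
#'   intervals), or `NULL` (with a warning) when no position exceeds the
#'   significance floor or neither model converges.
#' @export
fit_clone_gaussians <- function(increment, significance_floor = 2) {
  x <- increment$l
  y <- increment$increment %||% increment$p %||% increment$P
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!length(y) || max(y) < significance_floor) {
    warning("no position exceeds the significance floor; clone skipped")
    return(NULL)
  }
  lower1 <- c(A = 0, B = 1e-6, l0 = -Inf)
  lower2 <- c(A1 = 0, B1 = 1e-6, l01 = -Inf, A2 = 0, B2 = 1e-6, l02 = -Inf)
  f1 <- nls_or_optim(gaussian1_fn, x, y, gaussian_starts(x, y, 1), lower1)
  f2 <- nls_or_optim(gaussian2_fn, x, y, gaussian_starts(x, y, 2), lower2)
  if (!f1$converged && !f2$converged) {
    warning("neither Gaussian model converged; clone skipped")
    return(NULL)
  }
  n <- length(y)
  bic <- function(rss, k) n * log(max(rss, 1e-12) / n) + k * log(n)
  bic1 <- bic(f1$rss, 3); bic2 <- bic(f2$rss, 6)
  use2 <- f2$converged && (!f1$converged || bic2 < bic1)
  sel <- if (use2) f2 else f1

  comp <- function(A, B, l0) {
    A <- unname(A); B <- unname(B); l0 <- unname(l0)
    hw <- sqrt(log(2) / B)
    c(start = l0 - hw, end = l0 + hw, A = A)
  }
  comps <- if (use2)
    rbind(comp(sel$params["A1"], sel$params["B1"], sel$params["l01"]),
          comp(sel$params["A2"], sel$params["B2"], sel$params["l02"]))
  else rbind(comp(sel$params["A"], sel$params["B"], sel$params["l0"]))
  ## ignore components with negligible amplitude when forming the extent
  big <- comps[, "A"] >= 0.1 * max(comps[, "A"])
  extent <- c(min(comps[big, "start"]), max(comps[big, "end"]))

  tss <- sum((y - mean(y))^2)
  fit_result(if (use2) "gaussian2" else "gaussian1",
             sel$params, sel$rss, y, x, sel$converged,
             extra = list(
               r_squared_g1 = if (tss > 0) 1 - f1$rss / tss else NA_real_,
               r_squared_g2 = if (tss > 0) 1 - f2$rss / tss else NA_real_,
               bic_g1 = bic1, bic_g2 = bic2,
               extent = extent,
               components = comps,
               increment_peak = max(y)))
}

#' Categorize a clone by its position relative to the fold
#'
#' Categories follow the positional rule used for mosaic clones around the
#' morphogenetic furrow, with the fold described in the aligned coordinate
#' frame (fold center at `l' = 0` by construction): `PA` if the clone
#' extent contains the fold center; `A` if the extent lies anterior of the
#' center and overlaps -- or comes within `touch_tol` um of -- the anterior
#' half of the fold interval; `P` otherwise (posterior side).
#'
#' @param extent numeric length-2, clone extent `(l'_start, l'_end)` in um.
#' @param fold list with `x_S`, `x_F`, `x_E` in the same l' units (e.g. the
#'   average wild-type fold descriptor converted to um and centered).
#' @param touch_tol maximum gap in um still counting as "touching"
#'   (default 2).
#' @param analysis_window optional numeric length-2; if given and the
#'   extent lies entirely outside it, `"uncategorized"` is returned.
#' @return one of `"P"`, `"PA"`, `"A"`, `"uncategorized"`.
#' @export
categorize_clone <- function(extent, fold, touch_tol = 2,
                             analysis_window = NULL) {
  stopifnot(length(extent) == 2L, extent[1] < extent[2])
  if (!is.null(analysis_window) &&
      (extent[2] < analysis_window[1] || extent[1] > analysis_window[2]))
    return("uncategorized")
  center <- fold$x_F
  if (extent[1] <= center && extent[2] >= center) return("PA")
  if (extent[1] > center && extent[1] <= fold$x_E + touch_tol) return("A")
  "P"
}

#' Two-sample comparison of decay rates (or any scalar estimates)
#'
#' Two-sided two-sample Student's t-test (equal variances), the test used
#' throughout for comparing decay rates and location parameters between
#' conditions.
#'
#' @param a,b numeric vectors of per-replicate estimates.
#' @return an object of class `htest`.
#' @export
compare_groups <- function(a, b) {
  stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
}
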