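#' Binarize a grayscale image
#'
#' Otsu-thresholded foreground mask (foreground = dot material, assumed
#' brighter than background unless `invert = TRUE`).
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`.
#' @param invert Set `TRUE` when the material is darker than the background.
#' @return Logical mask.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = 0.5,
                     invert = FALSE) {
  method <- match.arg(method)
  if (method == "otsu") threshold <- otsu_threshold(image)
  mask <- image > threshold
  if (invert) mask <- !mask
  mask
}

#' Per-dot radius from a top-view mask
#'
#' Equivalent-circle radius `sqrt(area / pi) * scale` of every connected
#' component, ordered by centroid position (x, then y). Components touching
#' the image border (partial dots) and components below a minimum area are
#' excluded.
#'
#' @param mask Logical top-view mask.
#' @param scale mm per pixel.
#' @param min_area_px Minimum component area (pixels).
#' @return data.frame with `centroid_x`, `centroid_y` (mm) and `radius_mm`;
#'   zero rows (with a warning) when nothing qualifies.
#' @export
radius_from_topview <- function(mask, scale, min_area_px = 9) {
  stopifnot(scale > 0)
  st <- component_stats(label_components(mask), scale)
  st <- st[st$area_px >= min_area_px & !st$touches_border, , drop = FALSE]
  if (nrow(st) == 0) {
    warning("no dot components found in top view")
    return(data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      radius_mm = numeric(0)))
  }
  st <- st[order(st$centroid_x, st$centroid_y), , drop = FALSE]
  data.frame(centroid_x = st$centroid_x, centroid_y = st$centroid_y,
             radius_mm = st$equiv_radius_mm)
}

#' Upper-surface profile of a dot from a side-view mask
#'
#' The side view shows the sample silhouette with the dot protruding from
#' the flat top face. For every column the topmost foreground row gives the
#' surface height; the baseline (sample face) is the most common surface
#' row (longest run heuristic). Returned points are heights above the
#' baseline across the widest contiguous protrusion, including one
#' baseline-level column on each side so the profile ends near z = 0.
#'
#' @param mask Logical side-view mask (row 1 = top of image).
#' @param scale mm per pixel.
#' @param min_rise_px Minimum protrusion (pixels) to count as a dot.
#' @return data.frame with `x` (mm, centered on the dot) and `z` (mm).
#' @export
profile_from_sideview <- function(mask, scale, min_rise_px = 2) {
  stopifnot(scale > 0)
  top <- apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  if (all(is.na(top))) stop("empty profile error: side view has no material")
  baseline <- as.integer(names(which.max(table(top))))
  rise <- baseline - top  # pixels above the face
  cand <- which(!is.na(rise) & rise >= min_rise_px)
  if (length(cand) == 0) {
    stop("empty profile error: no protrusion above the baseline")
  }
  # widest contiguous run of protruding columns
  runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  lo <- max(min(run) - 1, 1)
  hi <- min(max(run) + 1, ncol(mask))
  cols <- lo:hi
  z <- pmax(baseline - top[cols], 0) * scale
  x <- (cols - mean(cols)) * scale
  keep <- !is.na(z)
  data.frame(x = x[keep], z = z[keep])
}

#' Fit a second-degree polynomial to a dot contour
#'
#' Ordinary least squares of `z ~ c2 x^2 + c1 x + c0`, with classical 95%
#' t-intervals per coefficient. With exactly 3 points the interpolation is
#' exact and the confidence half-widths are reported as infinite (zero
#' residual degrees of freedom).
#'
#' @param points data.frame with `x` and `z` (mm), at least 3 rows.
#' @return Object of class `contour_fit`: `coefficients` (`c2`, `c1`, `c0`),
#'   `ci95_halfwidths`, `residual_sd`, `n_points`, and the underlying `lm`
#'   fit.
#' @export
fit_parabola <- function(points) {
  if (nrow(points) < 3) stop("fit error: need at least 3 points")
  if (length(unique(points$x)) < 3) {
    stop("fit error: rank-deficient design (need 3 distinct x values)")
  }
  fit <- stats::lm(z ~ I(x^2) + x, data = points)
  cf <- stats::coef(fit)
  co <- c(c2 = unname(cf[["I(x^2)"]]), c1 = unname(cf[["x"]]),
          c0 = unname(cf[["(Intercept)"]]))
  n <- nrow(points)
  if (n == 3) {
    hw <- c(c2 = Inf, c1 = Inf, c0 = Inf)
    rsd <- 0
  } else {
    sm <- suppressWarnings(summary(fit))  # zero-residual fits are legal
    se <- sm$coefficients[, "Std. Error"]
    hw <- stats::qt(0.975, n - 3) *
      c(c2 = unname(se[["I(x^2)"]]), c1 = unname(se[["x"]]),
        c0 = unname(se[["(Intercept)"]]))
    rsd <- sm$sigma
  }
  structure(list(coefficients = co, ci95_halfwidths = hw,
                 residual_sd = rsd, n_points = n, fit = fit),
            class = "contour_fit")
}

#' Dot geometry from a fitted contour
#'
#' Vertex height and half-width (real roots of the fitted parabola) of a
#' convex-up contour fit, packaged as a paraboloid dot.
#'
#' @param contour_fit A [fit_parabola] result with `c2 < 0`.
#' @return List with `radius_mm`, `height_mm`, `lateral_area_mm2`,
#'   `volume_mm3`.
#' @export
paraboloid_from_fit <- function(contour_fit) {
  co <- contour_fit$coefficients
  if (co[["c2"]] >= 0) {
    stop("fit error: contour is not convex-up (c2 >= 0)")
  }
  h <- co[["c0"]] - co[["c1"]]^2 / (4 * co[["c2"]])
  a <- sqrt(max(h / -co[["c2"]], 0))
  list(radius_mm = a, height_mm = h,
       lateral_area_mm2 = paraboloid_area(a, h),
       volume_mm3 = pi * a^2 * h / 2)
}

#' Lateral surface area of a paraboloid cap
#'
#' Closed-form area of the surface of revolution `z = h (1 - rho^2/a^2)`,
#' `rho` in \[0, a\]:
#' `S = (pi a / (6 h^2)) ((a^2 + 4 h^2)^{3/2} - a^3)`,
#' evaluated in the numerically stable form
#' `pi a^4 / (6 h^2) * expm1(1.5 * log1p(4 h^2 / a^2))` so the flat-disk
#' limit `S -> pi a^2` as `h -> 0` is exact.
#'
#' @param a Base radius, mm (> 0). Vectorized.
#' @param h Apex height, mm (>= 0). Vectorized.
#' @return Lateral area, mm^2.
#' @examples
#' paraboloid_area(0.68, 0.54)  # 2.154
#' paraboloid_area(0.80, 0.32)  # 2.304
#' @export
paraboloid_area <- function(a, h) {
  if (any(a <= 0)) stop("domain error: radius a must be > 0")
  if (any(h < 0)) stop("domain error: height h must be >= 0")
  n <- max(length(a), length(h))
  a <- rep_len(a, n)
  h <- rep_len(h, n)
  out <- pi * a^2
  pos <- h > 0
  out[pos] <- (pi * a[pos]^4 / (6 * h[pos]^2)) *
    expm1(1.5 * log1p(4 * h[pos]^2 / a[pos]^2))
  out
}

#' Stimulus size of a pattern
#'
#' `A_pattern` is the summed lateral dot area over thaumatin-bearing dots
#' (for Layer: the coated top-face area); the stimulus size is the product
#' `A_pattern * C_thaumatin`, summed per ink for mixed-ink patterns.
#'
#' @param pattern A [dot_pattern].
#' @param dot_area_mm2 Per-dot lateral area (single value recycled, or one
#'   per dot), e.g. from [paraboloid_area]. Ignored for Layer.
#' @return List with `A_pattern_mm2`, `product` (mm^2 x mass fraction) and
#'   `per_ink` breakdown.
#' @export
stimulus_size <- function(pattern, dot_area_mm2 = paraboloid_area(0.75, 0.43)) {
  if (!is.null(pattern$layer)) {
    conc <- pattern$inks[[pattern$layer$ink]]$effective_thaumatin
    A <- pattern$layer$area_mm2
    return(list(A_pattern_mm2 = A, product = A * conc,
                per_ink = stats::setNames(A * conc, pattern$layer$ink)))
  }
  n <- nrow(pattern$dots)
  if (n == 0) {
    return(list(A_pattern_mm2 = 0, product = 0, per_ink = numeric(0)))
  }
  area <- rep_len(dot_area_mm2, n)
  conc <- .dot_conc(pattern)
  th <- conc > 0
  per_ink <- tapply(area[th] * conc[th], pattern$dots$ink[th], sum)
  per_ink <- stats::setNames(as.numeric(per_ink), names(per_ink))
  list(A_pattern_mm2 = sum(area[th]), product = sum(per_ink),
       per_ink = per_ink)
}

#' Full dot reconstruction from a top/side image pair
#'
#' Runs the image workflow: binarize both views, take the equivalent-circle
#' radius from the top view and the parabola-vertex height from the side
#' view.
#'
#' @param top_image,side_image Grayscale matrices in \[0, 1\].
#' @param top_scale,side_scale mm per pixel of each view.
#' @return List with `radius_mm`, `height_mm`, `lateral_area_mm2`,
#'   `contour_fit`, `radii` (per-dot top-view table).
#' @export
reconstruct_dot <- function(top_image, side_image, top_scale, side_scale) {
  radii <- radius_from_topview(binarize(top_image), top_scale)
  prof <- profile_from_sideview(binarize(side_image), side_scale)
  cf <- fit_parabola(prof)
  par <- paraboloid_from_fit(cf)
  a <- if (nrow(radii) > 0) mean(radii$radius_mm) else par$radius_mm
  list(radius_mm = a, height_mm = par$height_mm,
       lateral_area_mm2 = paraboloid_area(a, par$height_mm),
       contour_fit = cf, radii = radii)
}
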