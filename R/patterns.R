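#' Sample plate geometry
#'
#' The chocolate plate the dots are printed on: 36 x 24 x 3 mm with tilted
#' edges. Dots may only be placed in the printable region, the face minus a
#' border margin.
#'
#' @param length,width,height Plate dimensions in mm (length > width > height).
#' @param printable_margin Border (mm) kept free of dot centers.
#' @return Object of class `sample_geometry`.
#' @export
sample_geometry <- function(length = 36, width = 24, height = 3,
                            printable_margin = 1) {
  if (!(length > width && width > height && height > 0)) {
    stop("geometry error: need length > width > height > 0")
  }
  if (printable_margin < 0 || 2 * printable_margin >= width) {
    stop("geometry error: printable_margin leaves no printable region")
  }
  structure(list(length = length, width = width, height = height,
                 printable_margin = printable_margin),
            class = "sample_geometry")
}

.printable_region <- function(geom) {
  m <- geom$printable_margin
  list(x = c(m, geom$length - m), y = c(m, geom$width - m))
}

#' Canonical design names
#' @keywords internal
.design_names <- c("Bulk", "Homogeneous", "SpacedFull", "SpacedHalf",
                   "SpacedQuarter", "Centered", "Periphery", "Layer")

.match_design <- function(design_name) {
  key <- tolower(gsub("[ ._]", "", design_name))
  alias <- c(bulk = "Bulk", homogeneous = "Homogeneous",
             spacedfull = "SpacedFull", spfull = "SpacedFull",
             spacedhalf = "SpacedHalf", sphalf = "SpacedHalf",
             spacedquarter = "SpacedQuarter", spquarter = "SpacedQuarter",
             centered = "Centered", periphery = "Periphery",
             layer = "Layer", layered = "Layer")
  if (!key %in% names(alias)) {
    stop("usage error: unknown design '", design_name, "'; expected one of ",
         paste(.design_names, collapse = ", "))
  }
  alias[[key]]
}

# canonical micro lattice: 16 x 12 grid, pitch `pitch`, centered on the face,
# minus 8 corner cells (each corner cell plus its x-neighbor). The removal is
# chosen so the checkerboard subset has 92 cells and the doubled-pitch
# sublattice 46, preserving Quarter subset-of Half subset-of Full.
.micro_lattice <- function(geom, pitch = 2, ncol = 16, nrow = 12) {
  x0 <- (geom$length - (ncol - 1) * pitch) / 2
  y0 <- (geom$width - (nrow - 1) * pitch) / 2
  g <- expand.grid(i = 0:(ncol - 1), j = 0:(nrow - 1))
  corners <- rbind(c(0, 0), c(1, 0), c(ncol - 2, 0), c(ncol - 1, 0),
                   c(0, nrow - 1), c(1, nrow - 1),
                   c(ncol - 2, nrow - 1), c(ncol - 1, nrow - 1))
  drop <- paste(g$i, g$j) %in% paste(corners[, 1], corners[, 2])
  g <- g[!drop, , drop = FALSE]
  data.frame(i = g$i, j = g$j, x = x0 + pitch * g$i, y = y0 + pitch * g$j)
}

# hexagonally packed cluster at minimum pitch: `ncols` columns x `nrows` rows,
# odd rows offset by pitch/2, trimmed to the `n` cells closest to the cluster
# centroid (deterministic tie-break on x then y).
.hex_cluster <- function(x0, ncols, n, geom, pitch = 1.5, nrows = 17) {
  vp <- pitch * sqrt(3) / 2
  y0 <- (geom$width - (nrows - 1) * vp) / 2
  pts <- do.call(rbind, lapply(0:(nrows - 1), function(r) {
    cbind(x = x0 + (0:(ncols - 1)) * pitch + (r %% 2) * pitch / 2,
          y = y0 + r * vp)
  }))
  if (nrow(pts) < n) stop("geometry error: cluster cannot hold ", n, " dots")
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  keep <- order(d, pts[, 1], pts[, 2])[seq_len(n)]
  pts[keep, , drop = FALSE]
}

.meso_clusters <- function(geom, pitch = 1.5) {
  m <- 1.5  # meso designs use the tightest margin that keeps the 8 mm gap
  band_w <- 2 * pitch + pitch / 2
  block_w <- 5 * pitch + pitch / 2
  band_l <- .hex_cluster(m, 3, 46, geom, pitch)
  band_r <- .hex_cluster(geom$length - m - band_w, 3, 46, geom, pitch)
  block <- .hex_cluster((geom$length - block_w) / 2, 6, 92, geom, pitch)
  list(block = block, bands = rbind(band_l, band_r))
}

#' Generate a canonical dot-pattern design
#'
#' Builds one of the eight study designs on the sample face under the
#' constant-total-thaumatin constraint. The four micro designs share a square
#' lattice (pitch 2 mm, 184 cells after corner trimming); `SpacedHalf` is its
#' checkerboard subset (92 dots, ink B) and `SpacedQuarter` the doubled-pitch
#' sublattice (46 dots, ink C). The meso designs `Centered` and `Periphery`
#' place 92 ink-B dots and 92 contrasting ink-D dots in hexagonally packed
#' clusters separated by more than 8 mm along the long axis. `Bulk` carries
#' 184 thaumatin-free ink-D dots plus a bulk thaumatin fraction matching the
#' dotted samples' load; `Layer` has no dots, only a uniform ink-A coat.
#'
#' @param design_name One of `r paste(.design_names, collapse=", ")`
#'   (case/spacing-insensitive, `"Sp. Quarter"` style aliases accepted).
#' @param geometry A [sample_geometry].
#' @param inks Named list of [ink_formulation]s (needs `A`-`D`).
#' @param pitch Micro-lattice pitch, mm.
#' @param nominal_diameter Nominal printed dot diameter, mm.
#' @param drop_mass_ug Nominal drop mass, used to size the Bulk thaumatin
#'   fraction and the Layer coat mass so all designs carry the same load.
#' @param plate_mass_g Plate mass, g (Bulk bookkeeping).
#' @return Object of class `dot_pattern`: list with `design_name`, `dots`
#'   (data.frame `x`, `y`, `ink`, `diameter`), `scale_class`,
#'   `bulk_thaumatin_frac`, `layer` (coat descriptor or `NULL`), `geometry`,
#'   `inks`.
#' @examples
#' p <- generate_pattern("SpacedQuarter")
#' nrow(p$dots)       # 46
#' p$scale_class      # "micro"
#' @export
generate_pattern <- function(design_name, geometry = sample_geometry(),
                             inks = canonical_inks(), pitch = 2,
                             nominal_diameter = 1.5, drop_mass_ug = 390,
                             plate_mass_g = 2.34) {
  design <- .match_design(design_name)
  reference_load_ug <- 184 * drop_mass_ug * inks$A$effective_thaumatin
  bulk_frac <- 0
  layer <- NULL
  if (design == "Layer") {
    dots <- data.frame(x = numeric(0), y = numeric(0),
                       ink = character(0), diameter = numeric(0))
    layer <- list(ink = "A",
                  coat_mass_ug = reference_load_ug /
                    inks$A$effective_thaumatin,
                  area_mm2 = geometry$length * geometry$width)
  } else if (design %in% c("Centered", "Periphery")) {
    cl <- .meso_clusters(geometry)
    b_ink <- if (design == "Centered") "B" else "D"
    e_ink <- if (design == "Centered") "D" else "B"
    dots <- data.frame(
      x = c(cl$block[, 1], cl$bands[, 1]),
      y = c(cl$block[, 2], cl$bands[, 2]),
      ink = c(rep(b_ink, nrow(cl$block)), rep(e_ink, nrow(cl$bands))),
      diameter = nominal_diameter)
  } else {
    lat <- .micro_lattice(geometry, pitch)
    keep <- switch(design,
      Bulk = ,
      Homogeneous = ,
      SpacedFull = rep(TRUE, nrow(lat)),
      SpacedHalf = (lat$i + lat$j) %% 2 == 0,
      SpacedQuarter = lat$i %% 2 == 0 & lat$j %% 2 == 0)
    ink <- switch(design, Bulk = "D", Homogeneous = "A", SpacedFull = "A",
                  SpacedHalf = "B", SpacedQuarter = "C")
    lat <- lat[keep, , drop = FALSE]
    dots <- data.frame(x = lat$x, y = lat$y, ink = ink,
                       diameter = nominal_diameter)
    if (design == "Bulk") {
      bulk_frac <- reference_load_ug / (plate_mass_g * 1e6)
    }
  }
  reg <- .printable_region(geometry)
  if (nrow(dots) > 0 &&
      (any(dots$x < reg$x[1] - 1e-9 | dots$x > reg$x[2] + 1e-9) ||
       any(dots$y < reg$y[1] - 1e-9 | dots$y > reg$y[2] + 1e-9))) {
    stop("geometry error: design '", design,
         "' does not fit the printable region")
  }
  pat <- structure(list(design_name = design, dots = dots,
                        scale_class = "none", bulk_thaumatin_frac = bulk_frac,
                        layer = layer, geometry = geometry, inks = inks),
                   class = "dot_pattern")
  pat$scale_class <- classify_scale(pat)
  pat
}

.dot_conc <- function(pattern) {
  if (nrow(pattern$dots) == 0) return(numeric(0))
  vapply(pattern$dots$ink,
         function(k) pattern$inks[[k]]$effective_thaumatin, numeric(1))
}

#' Nearest-neighbor dot distances
#'
#' One nearest-neighbor distance per dot, either center-to-center or
#' edge-to-edge (center distance minus the mean nominal diameter of the
#' pair, floored at zero).
#'
#' @param pattern A [dot_pattern].
#' @param metric `"edge"` (default) or `"center"`.
#' @param subset Optional logical/integer index restricting the dots
#'   considered (neighbors are searched within the subset).
#' @return Numeric vector, one value per dot; empty for < 2 dots.
#' @export
dot_distances <- function(pattern, metric = c("edge", "center"),
                          subset = NULL) {
  metric <- match.arg(metric)
  dots <- pattern$dots
  if (!is.null(subset)) dots <- dots[subset, , drop = FALSE]
  n <- nrow(dots)
  if (n < 2) return(numeric(0))
  D <- as.matrix(stats::dist(dots[, c("x", "y")]))
  diag(D) <- Inf
  if (metric == "edge") {
    dia <- outer(dots$diameter, dots$diameter, function(a, b) (a + b) / 2)
    D <- pmax(D - dia, 0)
  }
  unname(apply(D, 1, min))
}

#' Long-axis gap between contrasting dot clusters
#'
#' Minimum distance, measured along the sample's long (x) axis, between any
#' thaumatin-bearing dot and any contrasting (thaumatin-free) dot. `NA` when
#' the pattern has no contrasting clusters.
#'
#' @param pattern A [dot_pattern].
#' @return Single numeric (mm) or `NA`.
#' @export
cluster_gap <- function(pattern) {
  conc <- .dot_conc(pattern)
  th <- which(conc > 0)
  other <- which(conc == 0)
  if (length(th) == 0 || length(other) == 0) return(NA_real_)
  min(abs(outer(pattern$dots$x[th], pattern$dots$x[other], "-")))
}

#' Classify a pattern as micro-, meso-structured or neither
#'
#' A pattern with contrasting (thaumatin vs thaumatin-free) dot clusters
#' whose long-axis gap exceeds `meso_gap` is mesoscale. Otherwise it is
#' microscale when the maximum nearest-neighbor edge-to-edge gap over its
#' thaumatin-bearing dots (all dots, if none carry thaumatin) is at most
#' `micro_gap`. Dot-free patterns (Layer) are `"none"`.
#'
#' @param pattern A [dot_pattern].
#' @param micro_gap Maximum micro edge gap, mm (default 2.5).
#' @param meso_gap Minimum meso cluster gap, mm (default 8).
#' @return `"micro"`, `"meso"` or `"none"`.
#' @export
classify_scale <- function(pattern, micro_gap = 2.5, meso_gap = 8) {
  if (nrow(pattern$dots) == 0) return("none")
  gap <- cluster_gap(pattern)
  if (!is.na(gap) && gap > meso_gap) return("meso")
  conc <- .dot_conc(pattern)
  idx <- if (any(conc > 0)) which(conc > 0) else seq_along(conc)
  gaps <- dot_distances(pattern, "edge", subset = idx)
  if (length(gaps) > 0 && max(gaps) <= micro_gap + 1e-9) "micro" else "none"
}

#' Total thaumatin load of a pattern
#'
#' Sums drop mass x effective ink concentration over all dots, plus the bulk
#' plate contribution (Bulk) or the coat contribution (Layer).
#'
#' @param pattern A [dot_pattern].
#' @param drop_mass_ug Drop mass per dot, ug.
#' @param plate_mass_g Plate mass, g (Bulk contribution).
#' @return List with `total_ug` and `by_ink` (named vector, ug; bulk/coat
#'   contributions itemized as `"bulk"` / `"coat"`).
#' @examples
#' tastant_load(generate_pattern("Homogeneous"))$total_ug  # 64.584
#' @export
tastant_load <- function(pattern, drop_mass_ug = 390, plate_mass_g = 2.34) {
  if (drop_mass_ug <= 0) stop("parameter error: drop_mass_ug must be > 0")
  conc <- .dot_conc(pattern)
  by_ink <- c()
  if (nrow(pattern$dots) > 0) {
    per_dot <- drop_mass_ug * conc
    by_ink <- tapply(per_dot, pattern$dots$ink, sum)
    by_ink <- stats::setNames(as.numeric(by_ink), names(by_ink))
  }
  if (pattern$bulk_thaumatin_frac > 0) {
    by_ink <- c(by_ink, bulk = pattern$bulk_thaumatin_frac * plate_mass_g * 1e6)
  }
  if (!is.null(pattern$layer)) {
    coat_ink <- pattern$inks[[pattern$layer$ink]]
    by_ink <- c(by_ink,
                coat = pattern$layer$coat_mass_ug * coat_ink$effective_thaumatin)
  }
  list(total_ug = sum(by_ink), by_ink = by_ink)
}

#' Render a pattern to a binary bitmap
#'
#' White (`TRUE`) pixels mark dots to print, black empty space. The bitmap
#' covers the whole sample face; pixel `(r, c)` has its center at
#' `((c - 0.5) * pitch, (r - 0.5) * pitch)` with row 1 at the y = 0 edge.
#'
#' @param pattern A [dot_pattern].
#' @param pixel_pitch mm per pixel (default 2, which puts the canonical
#'   micro lattice exactly on pixel centers).
#' @return Logical matrix (rows = y, cols = x).
#' @export
render_bitmap <- function(pattern, pixel_pitch = 2) {
  if (pixel_pitch <= 0) stop("parameter error: pixel_pitch must be > 0")
  geom <- pattern$geometry
  nc <- ceiling(geom$length / pixel_pitch)
  nr <- ceiling(geom$width / pixel_pitch)
  bmp <- matrix(FALSE, nr, nc)
  if (nrow(pattern$dots) > 0) {
    cc <- pmin(pmax(floor(pattern$dots$x / pixel_pitch) + 1, 1), nc)
    rr <- pmin(pmax(floor(pattern$dots$y / pixel_pitch) + 1, 1), nr)
    idx <- cbind(rr, cc)
    if (anyDuplicated(idx)) {
      warning("bitmap pixel pitch ", pixel_pitch,
              " mm merges dots; use a finer pitch")
    }
    bmp[idx] <- TRUE
  }
  bmp
}

#' @export
print.dot_pattern <- function(x, ...) {
  cat("<dot_pattern>", x$design_name, "-", nrow(x$dots), "dots,",
      x$scale_class, "scale\n")
  if (x$bulk_thaumatin_frac > 0) {
    cat("  bulk thaumatin fraction:",
        format(x$bulk_thaumatin_frac, digits = 4), "\n")
  }
  if (!is.null(x$layer)) {
    cat("  coated layer:", x$layer$coat_mass_ug, "ug of ink",
        x$layer$ink, "\n")
  }
  invisible(x)
}

#' Export / import a pattern as JSON
#'
#' @param pattern A [dot_pattern].
#' @param path Output / input file path.
#' @return `pattern_from_json` returns a [dot_pattern].
#' @export
pattern_to_json <- function(pattern, path) {
  obj <- list(
    design_name = pattern$design_name,
    geometry = unclass(pattern$geometry),
    scale_class = pattern$scale_class,
    bulk_thaumatin_frac = pattern$bulk_thaumatin_frac,
    layer = pattern$layer,
    inks = lapply(pattern$inks, function(k) {
      list(name = k$name,
           seeded_cocoa_butter_frac = k$seeded_cocoa_butter_frac,
           emulsion_frac = k$emulsion_frac,
           emulsion_composition = as.list(k$emulsion_composition))
    }),
    dots = pattern$dots)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pattern_to_json
#' @export
pattern_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- do.call(sample_geometry, as.list(obj$geometry))
  inks <- lapply(obj$inks, function(k) {
    comp <- unlist(k$emulsion_composition)
    ink_formulation(k$name, comp[["thaumatin"]], k$emulsion_frac, comp,
                    k$seeded_cocoa_butter_frac)
  })
  dots <- as.data.frame(obj$dots)
  if (nrow(dots) == 0) {
    dots <- data.frame(x = numeric(0), y = numeric(0),
                       ink = character(0), diameter = numeric(0))
  }
  layer <- if (length(obj$layer) == 0) NULL else obj$layer
  structure(list(design_name = obj$design_name, dots = dots,
                 scale_class = obj$scale_class,
                 bulk_thaumatin_frac = obj$bulk_thaumatin_frac,
                 layer = layer, geometry = geom, inks = inks),
            class = "dot_pattern")
}
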