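#' Papilla specification
#'
#' Geometry of a single papilla type. Defaults follow the measured human
#' values: filiform radius 180 um and height 195 um; fungiform height
#' 390 um (fungiform radius is not reported with them and defaults to
#' 400 um, a mid-literature value).
#'
#' @param kind `"filiform"` or `"fungiform"`.
#' @param radius_um,height_um Papilla radius and height, um.
#' @return Object of class `papilla_spec` (radius/height also kept in mm).
#' @export
papilla_spec <- function(kind = c("filiform", "fungiform"),
                         radius_um = if (kind == "filiform") 180 else 400,
                         height_um = if (kind == "filiform") 195 else 390) {
  kind <- match.arg(kind)
  if (radius_um <= 0 || height_um <= 0) {
    stop("domain error: papilla radius and height must be > 0")
  }
  structure(list(kind = kind, radius_um = radius_um, height_um = height_um,
                 radius_mm = radius_um / 1000, height_mm = height_um / 1000),
            class = "papilla_spec")
}

#' Theoretical filiform number density
#'
#' Filiform papillae cannot be counted individually in stained images; the
#' number density is derived by dividing the areal coverage fraction by
#' both the filiform radius and the minimum papilla-to-papilla distance.
#'
#' @param area_fraction Areal coverage fraction of filiform papillae, (0, 1].
#' @param r_fi_mm Filiform radius, mm.
#' @param min_dist_mm Minimum papilla-to-papilla distance, mm.
#' @return Number density, mm^-2.
#' @examples
#' filiform_number_density(0.3, 0.18, 0.36)  # 4.63 per mm^2
#' @export
filiform_number_density <- function(area_fraction, r_fi_mm, min_dist_mm) {
  if (area_fraction <= 0 || area_fraction > 1) {
    stop("domain error: area_fraction must be in (0, 1]")
  }
  if (r_fi_mm <= 0 || min_dist_mm <= 0) {
    stop("domain error: r_fi_mm and min_dist_mm must be > 0")
  }
  area_fraction / (r_fi_mm * min_dist_mm)
}

#' Randomly place papillae with a minimum separation
#'
#' Seeded dart-throwing: candidate centers are drawn uniformly over the
#' bounding box and rejected when closer than `min_distance` to an accepted
#' center. Fungiform papillae (fewer, larger) are placed first.
#'
#' @param counts Named integer vector, e.g. `c(fungiform = 12, filiform = 80)`.
#' @param bbox Numeric length-2: box width and height, mm.
#' @param min_distance Minimum center-to-center distance, mm.
#' @param seed Integer seed.
#' @param specs Named list of [papilla_spec]s per kind.
#' @param max_attempts Total candidate budget (default `1000 * sum(counts)`).
#' @return Object of class `papillae_field`: `papillae` data.frame
#'   (`x`, `y`, `kind`, `radius_mm`, `height_mm`), `bbox`, `min_distance`,
#'   `seed`, `specs`.
#' @export
place_papillae <- function(counts, bbox, min_distance, seed = 1,
                           specs = list(fungiform = papilla_spec("fungiform"),
                                        filiform = papilla_spec("filiform")),
                           max_attempts = NULL) {
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  if (is.null(max_attempts)) max_attempts <- max(1000 * n_total, 1)
  kinds <- names(counts)
  ord <- order(match(kinds, c("fungiform", "filiform")))
  kinds <- kinds[ord]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xs <- numeric(0); ys <- numeric(0); ks <- character(0)
  attempts <- 0
  for (k in kinds) {
    placed <- 0
    while (placed < counts[[k]]) {
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        stop("packing error: placed ", length(xs), " of ", n_total,
             " papillae (", sprintf("%.0f%%", 100 * length(xs) / n_total),
             ") before exhausting max_attempts")
      }
      cx <- stats::runif(1, 0, bbox[1])
      cy <- stats::runif(1, 0, bbox[2])
      if (length(xs) == 0 ||
          min((xs - cx)^2 + (ys - cy)^2) >= min_distance^2) {
        xs <- c(xs, cx); ys <- c(ys, cy); ks <- c(ks, k)
        placed <- placed + 1
      }
    }
  }
  pap <- data.frame(
    x = xs, y = ys, kind = ks,
    radius_mm = vapply(ks, function(k) specs[[k]]$radius_mm, numeric(1)),
    height_mm = vapply(ks, function(k) specs[[k]]$height_mm, numeric(1)))
  structure(list(papillae = pap, bbox = bbox, min_distance = min_distance,
                 seed = seed, specs = specs),
            class = "papillae_field")
}

#' Height of a papilla surface at an offset from its apex
#'
#' The papilla shape template is a paraboloid of revolution scaled so the
#' bump rises to the papilla's measured height at its center and meets the
#' base circle at its radius:
#' `z = height * max(0, 1 - (x^2 + y^2) / radius^2)`.
#'
#' @param x,y Offsets from the papilla center, mm. Vectorized.
#' @param spec A [papilla_spec].
#' @return Height z, mm.
#' @export
papilla_height <- function(x, y, spec) {
  spec$height_mm * pmax(0, 1 - (x^2 + y^2) / spec$radius_mm^2)
}

#' Build a height-field mesh from a papillae field
#'
#' Samples the field on a regular grid, combining overlapping papillae by
#' pointwise maximum, and returns a structured tongue-surface mesh.
#'
#' @param field A [papillae_field].
#' @param resolution Grid cell size, mm; must be at most half the smallest
#'   papilla radius (Nyquist check).
#' @return Object of class `tongue_mesh`: `z` matrix (rows = y), `x`, `y`
#'   grid coordinates, `resolution`, `field`.
#' @export
build_mesh <- function(field, resolution) {
  pap <- field$papillae
  if (nrow(pap) > 0 && resolution > min(pap$radius_mm) / 2) {
    stop("sampling error: resolution ", resolution,
         " mm exceeds half the smallest papilla radius (",
         min(pap$radius_mm) / 2, " mm)")
  }
  x <- seq(0, field$bbox[1], by = resolution)
  y <- seq(0, field$bbox[2], by = resolution)
  z <- matrix(0, length(y), length(x))
  for (i in seq_len(nrow(pap))) {
    r <- pap$radius_mm[i]
    xi <- which(abs(x - pap$x[i]) <= r)
    yi <- which(abs(y - pap$y[i]) <= r)
    if (length(xi) == 0 || length(yi) == 0) next
    zz <- outer(y[yi] - pap$y[i], x[xi] - pap$x[i],
                function(dy, dx) pap$height_mm[i] *
                  pmax(0, 1 - (dx^2 + dy^2) / r^2))
    z[yi, xi] <- pmax(z[yi, xi], zz)
  }
  structure(list(z = z, x = x, y = y, resolution = resolution,
                 field = field),
            class = "tongue_mesh")
}

#' Export / import a tongue mesh as Wavefront OBJ
#'
#' Triangulated height field (each grid quad split into two triangles),
#' vertices in mm. `read_obj` returns the vertices and faces.
#'
#' @param mesh A [build_mesh] result.
#' @param path File path.
#' @export
write_obj <- function(mesh, path) {
  nx <- length(mesh$x); ny <- length(mesh$y)
  vid <- function(ix, iy) (iy - 1) * nx + ix
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sweetdot tongue-surface height field", con)
  for (iy in seq_len(ny)) {
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$x, mesh$y[iy],
                       mesh$z[iy, ]), con)
  }
  for (iy in seq_len(ny - 1)) {
    for (ix in seq_len(nx - 1)) {
      a <- vid(ix, iy); b <- vid(ix + 1, iy)
      c_ <- vid(ix + 1, iy + 1); d <- vid(ix, iy + 1)
      writeLines(c(sprintf("f %d %d %d", a, b, c_),
                   sprintf("f %d %d %d", a, c_, d)), con)
    }
  }
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t) {
    as.numeric(t[2:4])
  }))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t) {
    as.integer(sub("/.*", "", t[2:4]))
  }))
  colnames(verts) <- c("x", "y", "z")
  list(vertices = as.data.frame(verts), faces = faces)
}

#' Oscillatory-shear kinematics
#'
#' Parameters of the in-vitro consumption rig: shear velocity, normal force
#' and sample-to-tongue half amplitude. Only the half amplitude enters the
#' smear kernel; velocity and force are carried as rig metadata.
#'
#' @param velocity_mm_s Shear velocity v_T, mm/s.
#' @param normal_force_N Normal force F_N, N.
#' @param half_amplitude_mm Sample-to-tongue half amplitude A/2, mm.
#' @param axis Oscillation axis, `"x"` (long axis) or `"y"`.
#' @return Object of class `shear_kinematics`.
#' @export
shear_kinematics <- function(velocity_mm_s = 10, normal_force_N = 1,
                             half_amplitude_mm = 5, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (velocity_mm_s <= 0 || normal_force_N <= 0 || half_amplitude_mm < 0) {
    stop("parameter error: kinematics must be positive")
  }
  structure(list(velocity_mm_s = velocity_mm_s,
                 normal_force_N = normal_force_N,
                 half_amplitude_mm = half_amplitude_mm, axis = axis),
            class = "shear_kinematics")
}

#' Tastant exposure map under oscillatory shear
#'
#' Each dot's thaumatin mass is spread uniformly over a segment of full
#' length `2 * (A/2)` along the oscillation axis, centered on the dot (1-D
#' box kernel), and accumulated on a regular grid of the tongue-contact
#' plane. The map extends `A/2` beyond the sample face along the shear axis
#' so total mass is conserved. For the Layer design the coat mass is spread
#' uniformly over the face before smearing.
#'
#' @param pattern A [dot_pattern].
#' @param kinematics A [shear_kinematics].
#' @param drop_mass_ug Drop mass, ug.
#' @param grid_resolution Map cell size, mm.
#' @param boundary Anterior/posterior boundary coordinate along the long
#'   axis, mm; defaults to mid-length of the contact map.
#' @return Object of class `exposure_map`: `density` matrix (ug/mm^2, rows =
#'   y), `x`, `y` cell centers, `cell_area`, `total_ug`, `boundary`, `axis`.
#' @export
smear_exposure <- function(pattern, kinematics = shear_kinematics(),
                           drop_mass_ug = 390, grid_resolution = 0.25,
                           boundary = NULL) {
  geom <- pattern$geometry
  A2 <- kinematics$half_amplitude_mm
  if (!is.null(pattern$layer)) {
    # uniform sheet: represent as a fine lattice of virtual point deposits
    nx <- ceiling(geom$length); ny <- ceiling(geom$width)
    gx <- (seq_len(nx) - 0.5) * geom$length / nx
    gy <- (seq_len(ny) - 0.5) * geom$width / ny
    pts <- expand.grid(x = gx, y = gy)
    conc <- pattern$inks[[pattern$layer$ink]]$effective_thaumatin
    mass <- rep(pattern$layer$coat_mass_ug * conc / nrow(pts), nrow(pts))
  } else {
    conc <- .dot_conc(pattern)
    keep <- conc > 0
    pts <- pattern$dots[keep, c("x", "y"), drop = FALSE]
    mass <- drop_mass_ug * conc[keep]
  }
  flip <- kinematics$axis == "y"
  if (flip) {
    pts <- data.frame(x = pts$y, y = pts$x)
    dims <- c(geom$width, geom$length)
  } else {
    dims <- c(geom$length, geom$width)
  }
  x0 <- -A2
  x1 <- dims[1] + A2
  nx <- ceiling((x1 - x0) / grid_resolution)
  ny <- ceiling(dims[2] / grid_resolution)
  dens <- matrix(0, ny, nx)
  cell_area <- grid_resolution^2
  xc <- x0 + (seq_len(nx) - 0.5) * grid_resolution
  yc <- (seq_len(ny) - 0.5) * grid_resolution
  for (i in seq_len(nrow(pts))) {
    ry <- min(max(ceiling((pts$y[i]) / grid_resolution), 1), ny)
    lo <- pts$x[i] - A2
    hi <- pts$x[i] + A2
    if (hi == lo) {  # A/2 = 0: point deposit
      cx <- min(max(ceiling((lo - x0) / grid_resolution), 1), nx)
      dens[ry, cx] <- dens[ry, cx] + mass[i] / cell_area
      next
    }
    # overlap of [lo, hi] with each x-cell
    cl <- xc - grid_resolution / 2
    ch <- xc + grid_resolution / 2
    ov <- pmax(pmin(ch, hi) - pmax(cl, lo), 0)
    dens[ry, ] <- dens[ry, ] + mass[i] * (ov / (hi - lo)) / cell_area
  }
  if (is.null(boundary)) boundary <- (x0 + x1) / 2
  structure(list(density = dens, x = xc, y = yc, cell_area = cell_area,
                 total_ug = sum(dens) * cell_area, boundary = boundary,
                 axis = kinematics$axis),
            class = "exposure_map")
}

#' Coefficient of variation of the along-axis exposure profile
#'
#' Collapses the exposure map across the transverse axis and returns
#' sd/mean of the resulting 1-D mass profile. Lower values mean the tastant
#' is spread more evenly along the shear axis.
#'
#' @param map An [smear_exposure] result.
#' @return Single numeric CV.
#' @export
exposure_cv <- function(map) {
  prof <- colSums(map$density)
  stats::sd(prof) / mean(prof)
}

#' Anterior/posterior mass split of an exposure map
#'
#' Mass fractions on each side of the boundary plane along the shear axis
#' (cells are assigned by center). Fractions sum to 1 for nonzero maps.
#'
#' @param map An [smear_exposure] result.
#' @param boundary Boundary coordinate, mm; defaults to the map's stored
#'   boundary (mid-length).
#' @return Named vector `c(anterior =, posterior =)`; `NA`s (with a
#'   warning) when the map holds no mass.
#' @export
region_split <- function(map, boundary = map$boundary) {
  prof <- colSums(map$density)
  tot <- sum(prof)
  if (tot <= 0) {
    warning("zero total mass: region fractions undefined")
    return(c(anterior = NA_real_, posterior = NA_real_))
  }
  ant <- sum(prof[map$x <= boundary]) / tot
  c(anterior = ant, posterior = 1 - ant)
}
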