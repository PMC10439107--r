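#' Panel configuration for synthetic ratings
#'
#' @param samples Character vector of design names.
#' @param cell_means Matrix (samples x 3 timepoints, dimnames required) of
#'   mean intensities on the 0-100 scale.
#' @param n_assessors,n_sessions Panel size and replicate sessions.
#' @param assessor_sd,session_sd,residual_sd Gaussian effect sds (intensity
#'   units).
#' @param seed Integer seed.
#' @return Object of class `panel_config`.
#' @export
panel_config <- function(samples, cell_means, n_assessors = 14,
                         n_sessions = 2, assessor_sd = 8, session_sd = 0,
                         residual_sd = 10, seed = 1) {
  stopifnot(is.matrix(cell_means),
            identical(rownames(cell_means), samples),
            identical(colnames(cell_means), c("t_start", "t_max", "t_end")))
  if (any(cell_means < 0 | cell_means > 100)) {
    stop("cell means must lie within the 0-100 scale")
  }
  if (any(c(assessor_sd, session_sd, residual_sd) < 0)) {
    stop("effect sds must be >= 0")
  }
  structure(list(samples = samples, cell_means = cell_means,
                 n_assessors = n_assessors, n_sessions = n_sessions,
                 assessor_sd = assessor_sd, session_sd = session_sd,
                 residual_sd = residual_sd, seed = seed),
            class = "panel_config")
}

#' Default study panel configurations
#'
#' Declared fixtures encoding the study's printed effect ratios, not
#' digitized figure values. Micro part (14 assessors): the four dotted
#' designs score 4x the Bulk reference at t_start and t_max and 3x at
#' t_end (i.e. amplification 300%, 300%, 200%), anchored at a dotted
#' t_max of 50 (the warm-up maximum-intensity anchor); the coated Layer
#' design sits below the dotted samples. Meso part (17 assessors):
#' Centered scores 0.76x Periphery at t_max (the printed 24% deficit).
#'
#' @param part `"micro"` or `"meso"`.
#' @param seed Integer seed stored in the config.
#' @return A [panel_config].
#' @export
default_study_config <- function(part = c("micro", "meso"), seed = 1) {
  part <- match.arg(part)
  tp <- c("t_start", "t_max", "t_end")
  if (part == "micro") {
    samples <- c("Bulk", "Homogeneous", "SpacedFull", "SpacedHalf",
                 "SpacedQuarter", "Layer")
    dotted <- c(40, 50, 30)
    m <- rbind(Bulk = c(10, 12.5, 10), Homogeneous = dotted,
               SpacedFull = dotted, SpacedHalf = dotted,
               SpacedQuarter = dotted, Layer = c(25, 32, 20))
    n <- 14
  } else {
    samples <- c("Bulk", "Homogeneous", "Centered", "Periphery")
    m <- rbind(Bulk = c(10, 12.5, 10), Homogeneous = c(40, 50, 30),
               Centered = c(30, 38, 24), Periphery = c(38, 50, 28))
    n <- 17
  }
  colnames(m) <- tp
  panel_config(samples, m, n_assessors = n, seed = seed)
}

#' Generate synthetic panel ratings
#'
#' Full factorial assessor x sample x timepoint x session table:
#' `intensity = cell_mean + assessor effect + session effect + residual`,
#' all Gaussian, clipped to the 0-100 scale. The clipped-record fraction is
#' attached as attribute `"clipped_fraction"` so heavy-clipping
#' configurations can be excluded from calibration runs.
#'
#' @param config A [panel_config].
#' @return Ratings data.frame (`assessor`, `sample`, `session`,
#'   `timepoint`, `intensity`).
#' @export
gen_ratings <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tp <- colnames(config$cell_means)
  a_eff <- stats::rnorm(config$n_assessors, 0, config$assessor_sd)
  s_eff <- stats::rnorm(config$n_sessions, 0, config$session_sd)
  d <- expand.grid(assessor = seq_len(config$n_assessors),
                   sample = config$samples, timepoint = tp,
                   session = seq_len(config$n_sessions),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- config$cell_means[cbind(d$sample, d$timepoint)]
  raw <- mu + a_eff[d$assessor] + s_eff[d$session] +
    stats::rnorm(nrow(d), 0, config$residual_sd)
  d$intensity <- pmin(pmax(raw, 0), 100)
  d <- d[, c("assessor", "sample", "session", "timepoint", "intensity")]
  attr(d, "clipped_fraction") <- mean(raw < 0 | raw > 100)
  d
}

#' Render a synthetic dot image pair with known geometry
#'
#' Top view: a bright disk of radius `a`. Side view: the silhouette of the
#' paraboloid `z = h (1 - rho^2 / a^2)` protruding from a flat baseline.
#' Optional additive Gaussian noise (sd as a fraction of the
#' foreground-background contrast) and a linear illumination gradient.
#'
#' @param a,h Dot radius and height, mm.
#' @param scale mm per pixel.
#' @param noise_sd Noise sd as a fraction of contrast.
#' @param illumination_gradient Left-to-right brightness ramp as a fraction
#'   of contrast.
#' @param seed Integer seed.
#' @param bg,fg Background / foreground gray levels.
#' @return List with `top` / `side` (each `image` + `scale`), and `truth`
#'   (`a`, `h`, `top_mask`, `side_mask`).
#' @export
render_dot <- function(a, h, scale = 0.01, noise_sd = 0,
                       illumination_gradient = 0, seed = 1,
                       bg = 0.2, fg = 0.8) {
  if (a / scale < 2 || h / scale < 2) {
    stop("resolution error: a and h must span at least 2 px at this scale")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  contrast <- fg - bg
  noisy <- function(img) {
    if (illumination_gradient > 0) {
      ramp <- seq(0, illumination_gradient * contrast,
                  length.out = ncol(img))
      img <- img + matrix(ramp, nrow(img), ncol(img), byrow = TRUE)
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd * contrast),
                          nrow(img))
    }
    pmin(pmax(img, 0), 1)
  }
  # top view
  half <- ceiling(1.5 * a / scale)
  n <- 2 * half + 1
  cx <- half + 1
  dx <- (col(matrix(0, n, n)) - cx) * scale
  dy <- (row(matrix(0, n, n)) - cx) * scale
  top_mask <- dx^2 + dy^2 <= a^2
  top <- matrix(bg, n, n)
  top[top_mask] <- fg
  # side view: columns across 3a, baseline with h of headroom above
  wc <- ceiling(1.5 * a / scale)
  nc <- 2 * wc + 1
  hpx <- ceiling(h / scale)
  base_depth <- max(ceiling(0.5 * h / scale), 4)
  nr <- hpx + base_depth + ceiling(0.5 * hpx) + 2
  baseline_row <- nr - base_depth + 1
  xs <- (seq_len(nc) - (wc + 1)) * scale
  zprof <- ifelse(abs(xs) <= a, h * (1 - xs^2 / a^2), 0)
  side_mask <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc)) {
    top_row <- baseline_row - round(zprof[j] / scale)
    side_mask[top_row:nr, j] <- TRUE
  }
  side <- matrix(bg, nr, nc)
  side[side_mask] <- fg
  list(top = list(image = noisy(top), scale = scale),
       side = list(image = noisy(side), scale = scale),
       truth = list(a = a, h = h, top_mask = top_mask,
                    side_mask = side_mask))
}

#' Render a synthetic stained-tongue image with known papillae
#'
#' Two disk populations (fungiform: few, large; filiform: many, small) at
#' distinct sizes on a uniform background, placed by seeded dart-throwing,
#' with optional Gaussian noise.
#'
#' @param bbox Image extent, mm (width, height).
#' @param n_fungiform,n_filiform Papillae counts.
#' @param r_fungiform_mm,r_filiform_mm Disk radii, mm.
#' @param scale mm per pixel.
#' @param noise_sd Noise sd as a fraction of contrast.
#' @param seed Integer seed.
#' @param bg,fg Background / papilla gray levels.
#' @return List with `image`, `scale`, and `truth` (a [place_papillae]
#'   field of the drawn centers).
#' @export
render_tongue <- function(bbox = c(12, 9), n_fungiform = 12,
                          n_filiform = 80, r_fungiform_mm = 0.4,
                          r_filiform_mm = 0.18, scale = 0.02,
                          noise_sd = 0, seed = 1, bg = 0.15, fg = 0.85) {
  specs <- list(
    fungiform = papilla_spec("fungiform", r_fungiform_mm * 1000),
    filiform = papilla_spec("filiform", r_filiform_mm * 1000))
  min_dist <- 2 * max(r_fungiform_mm, r_filiform_mm) + 2 * scale
  field <- place_papillae(c(fungiform = n_fungiform,
                            filiform = n_filiform),
                          bbox, min_dist, seed = seed, specs = specs)
  # clamp centers inward so no disk crosses the border (border components
  # are excluded downstream)
  pap <- field$papillae
  if (nrow(pap) > 0) {
    pad <- pap$radius_mm + 2 * scale
    pap$x <- pmin(pmax(pap$x, pad), bbox[1] - pad)
    pap$y <- pmin(pmax(pap$y, pad), bbox[2] - pad)
    field$papillae <- pap
  }
  nc <- round(bbox[1] / scale)
  nr <- round(bbox[2] / scale)
  img <- matrix(bg, nr, nc)
  px <- (col(img) - 0.5) * scale
  py <- (row(img) - 0.5) * scale
  for (i in seq_len(nrow(pap))) {
    hit <- (px - pap$x[i])^2 + (py - pap$y[i])^2 <= pap$radius_mm[i]^2
    img[hit] <- fg
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed + 1L)
    img <- pmin(pmax(img + matrix(stats::rnorm(length(img), 0,
                                               noise_sd * (fg - bg)),
                                  nrow(img)), 0), 1)
  }
  list(image = img, scale = scale, truth = field)
}

#' Segment papillae in a stained-tongue image
#'
#' Threshold-based segmentation; connected components are classified by
#' equivalent radius (at or above the cutoff: fungiform, below: filiform).
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param scale mm per pixel.
#' @param cutoff_radius_mm Fungiform/filiform size cutoff.
#' @param min_area_px Minimum component area (speckle filter).
#' @return List with `counts` (named: fungiform, filiform), `densities`
#'   (per mm^2), `components` (per-component table with `kind`), and the
#'   masks per kind.
#' @export
segment_papillae <- function(image, scale, cutoff_radius_mm = 0.28,
                             min_area_px = 5) {
  mask <- binarize(image)
  labels <- label_components(mask)
  st <- component_stats(labels, scale)
  st <- st[st$area_px >= min_area_px, , drop = FALSE]
  if (nrow(st) == 0) {
    warning("no papillae components found")
    st$kind <- character(0)
    area <- prod(dim(image)) * scale^2
    return(list(counts = c(fungiform = 0, filiform = 0),
                densities = c(fungiform = 0, filiform = 0),
                components = st,
                fungiform_mask = mask & FALSE, filiform_mask = mask & FALSE))
  }
  st$kind <- ifelse(st$equiv_radius_mm >= cutoff_radius_mm,
                    "fungiform", "filiform")
  counts <- c(fungiform = sum(st$kind == "fungiform"),
              filiform = sum(st$kind == "filiform"))
  area <- prod(dim(image)) * scale^2
  fu_ids <- st$label[st$kind == "fungiform"]
  list(counts = counts, densities = counts / area, components = st,
       fungiform_mask = matrix(labels %in% fu_ids, nrow(labels)),
       filiform_mask = mask & !matrix(labels %in% c(0L, fu_ids),
                                      nrow(labels)))
}
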