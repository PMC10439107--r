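# Plain-text Netpbm I/O and basic image primitives. Images are numeric
# matrices in [0, 1] (rows = y, row 1 at the top edge); binary masks are
# logical matrices.

#' Read / write plain (ASCII) PBM and PGM images
#'
#' `write_pbm`/`read_pbm` handle binary P1 bitmaps (1 = white = print, per
#' the bitmap convention used for pattern designs); `write_pgm`/`read_pgm`
#' handle P2 grayscale at maxval 255.
#'
#' @param x Logical matrix (PBM) or numeric matrix in \[0, 1\] (PGM).
#' @param path File path.
#' @return Readers return a logical (PBM) or numeric (PGM) matrix.
#' @export
write_pbm <- function(x, path) {
  stopifnot(is.matrix(x))
  # P1 convention: 1 = black. We store print pixels (TRUE/white) as 0 so
  # viewers show dots as white, and invert on read.
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(x), nrow(x))), con)
  write.table(matrix(as.integer(!x), nrow(x), ncol(x)), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pbm
#' @export
read_pbm <- function(path) {
  tok <- .pnm_tokens(path, "P1")
  nc <- tok$dims[1]; nr <- tok$dims[2]
  matrix(tok$values == 0, nr, nc, byrow = TRUE)
}

#' @rdname write_pbm
#' @export
write_pgm <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  v <- round(pmin(pmax(x, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), "255"), con)
  write.table(matrix(as.integer(v), nrow(x), ncol(x)), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pbm
#' @export
read_pgm <- function(path) {
  tok <- .pnm_tokens(path, "P2")
  nc <- tok$dims[1]; nr <- tok$dims[2]
  matrix(tok$values / tok$maxval, nr, nc, byrow = TRUE)
}

.pnm_tokens <- function(path, magic) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  tok <- scan(text = sub("^P[12]", "", paste(lines, collapse = " ")),
              quiet = TRUE)
  if (!startsWith(trimws(lines[1]), magic)) {
    stop("format error: expected ", magic, " file at ", path)
  }
  if (magic == "P1") {
    list(dims = tok[1:2], values = tok[-(1:2)], maxval = 1)
  } else {
    list(dims = tok[1:2], maxval = tok[3], values = tok[-(1:3)])
  }
}

#' Otsu threshold of a grayscale image
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param nbins Histogram bins.
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(image, nbins = 256) {
  v <- as.vector(image)
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    stop("thresholding error: image has no contrast (uniform)")
  }
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * nbins) + 1, nbins),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Label 4-connected components of a binary mask
#'
#' Iterative minimum-label propagation (vectorized over the whole image), so
#' labels are stable and deterministic: components are renumbered 1..k in
#' raster order of their first pixel.
#'
#' @param mask Logical matrix.
#' @return Integer matrix, 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  work <- matrix(seq_len(nr * nc), nr, nc)
  work[!mask] <- Inf  # background never donates a label
  pad <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- pmin(work, pad(work, 1, 0), pad(work, -1, 0),
                pad(work, 0, 1), pad(work, 0, -1))
    new[!mask] <- Inf
    if (all(new[mask] == work[mask])) break
    work <- new
  }
  lab <- matrix(0L, nr, nc)
  lab[mask] <- match(work[mask], sort(unique(work[mask])))
  lab
}

#' Per-component summary of a labeled mask
#'
#' @param labels Integer label matrix from [label_components].
#' @param scale mm per pixel.
#' @return data.frame with `label`, `area_px`, `centroid_x`, `centroid_y`
#'   (mm), `equiv_radius_mm`, `touches_border`.
#' @export
component_stats <- function(labels, scale = 1) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      equiv_radius_mm = numeric(0),
                      touches_border = logical(0)))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  rr <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  ll <- labels[idx]
  area <- tabulate(ll, max(ids))[ids]
  cx <- tapply(cc, ll, mean)[as.character(ids)]
  cy <- tapply(rr, ll, mean)[as.character(ids)]
  border <- tapply(rr == 1 | rr == nr | cc == 1 | cc == nc, ll,
                   any)[as.character(ids)]
  data.frame(label = ids, area_px = area,
             centroid_x = (as.numeric(cx) - 0.5) * scale,
             centroid_y = (as.numeric(cy) - 0.5) * scale,
             equiv_radius_mm = sqrt(area / pi) * scale,
             touches_border = as.logical(border))
}
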