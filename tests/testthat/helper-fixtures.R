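# Shared fixtures built in code.

micro_designs <- c("Homogeneous", "SpacedFull", "SpacedHalf", "SpacedQuarter")
dotted_designs <- c(micro_designs, "Centered", "Periphery")

# independent brute-force nearest-neighbor oracle (double loop, no dist())
brute_nn <- function(xy, diameter = NULL) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
      if (!is.null(diameter)) d <- max(d - diameter, 0)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# numerical surface-of-revolution oracle for the paraboloid cap
quad_area <- function(a, h) {
  if (h == 0) return(pi * a^2)
  f <- function(rho) 2 * pi * rho * sqrt(1 + (2 * h * rho / a^2)^2)
  stats::integrate(f, 0, a, rel.tol = 1e-12)$value
}

# draw a filled disk mask (pixel centers within radius_px of center)
disk_mask <- function(n, cx, cy, radius_px) {
  dx <- col(matrix(0, n, n)) - cx
  dy <- row(matrix(0, n, n)) - cy
  dx^2 + dy^2 <= radius_px^2
}
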