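# Independent oracles used by unit and acceptance tests.

# Brute-force two-sided Mann-Whitney p: enumerate every C(N, na) assignment
# of the pooled (mid)ranks to group A and count assignments at least as far
# from the null mean as the observed U.
perm_mwu_p <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  subsets <- utils::combn(length(r), na)
  U_all <- colSums(matrix(r[subsets], nrow = na)) - na * (na + 1) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Rasterization oracle for polygon membership: fill the polygon (even-odd
# rule, no antialiasing) on a fine grid (`scale` samples per unit) through
# the cairo renderer and look up pixels. Returns a logical matrix indexed
# [row, col] with row 1 at the TOP (image convention, y increasing
# downward). Supersampling keeps the raster's placement error well inside
# the half-pixel exclusion band used by the comparisons.
rasterize_polygon <- function(vertices, W = 100, H = 100, scale = 4) {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  grDevices::png(f, width = W * scale, height = H * scale, type = "cairo",
                 antialias = "none")
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  # flip y so that the device matches image convention (origin top-left)
  graphics::plot.window(xlim = c(0, W), ylim = c(H, 0))
  graphics::rect(0, 0, W, H, col = "white", border = NA)
  graphics::polypath(vertices[, 1], vertices[, 2], col = "black", border = NA,
                     rule = "evenodd")
  grDevices::dev.off()
  arr <- png::readPNG(f)
  arr[, , 1] < 0.5
}

# Random simple (star-shaped) polygon around (cx, cy).
random_star_polygon <- function(n_vertices = 12, cx = 50, cy = 50,
                                rmin = 8, rmax = 42) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, rmin, rmax)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# Minimum distance from points (x, y) to the closed polygon boundary.
dist_to_polygon_edges <- function(x, y, vertices) {
  v <- rbind(vertices, vertices[1, ])
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(v) - 1)) {
    ax <- v[i, 1]; ay <- v[i, 2]; bx <- v[i + 1, 1]; by <- v[i + 1, 2]
    len2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(pmax(((x - ax) * (bx - ax) + (y - ay) * (by - ay)) / len2, 0), 1)
    d <- pmin(d, sqrt((x - (ax + t * (bx - ax)))^2 + (y - (ay + t * (by - ay)))^2))
  }
  d
}

# Compare point_in_polygon against the rasterization oracle at pixel
# centers, excluding points within `exclude` px of the boundary.
# Returns c(n_compared, n_mismatch).
geometry_oracle_check <- function(poly, n_points = 200, W = 100, H = 100,
                                  exclude = 0.5, scale = 4) {
  mask <- rasterize_polygon(poly$vertices, W = W, H = H, scale = scale)
  i <- sample.int(W, n_points, replace = TRUE) - 1L
  j <- sample.int(H, n_points, replace = TRUE) - 1L
  px <- i + 0.5; py <- j + 0.5
  keep <- dist_to_polygon_edges(px, py, poly$vertices) > exclude
  got <- point_in_polygon(px[keep], py[keep], poly)
  want <- mask[cbind(ceiling(py[keep] * scale), ceiling(px[keep] * scale))]
  c(sum(keep), sum(got != want))
}
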