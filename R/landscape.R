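# Lightweight raster-stack container for landscape covariates: named
# matrices on a shared regular grid in a projected metric CRS. Row i of a
# layer is the i-th cell row from ymin upward; column j from xmin rightward.

#' Construct a covariate stack
#'
#' @param layers named list of numeric matrices (ny rows x nx columns), all
#'   the same dimension.
#' @param extent numeric length-4: xmin, xmax, ymin, ymax (m).
#' @param resolution cell size (m); must divide both spans.
#' @param features optional list of the generating vector features.
#' @return object of class \code{cov_stack}.
#' @export
cov_stack <- function(layers, extent, resolution, features = list()) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  nx <- round((extent[2] - extent[1]) / resolution)
  ny <- round((extent[4] - extent[3]) / resolution)
  if (abs(nx * resolution - (extent[2] - extent[1])) > 1e-6 ||
      abs(ny * resolution - (extent[4] - extent[3])) > 1e-6)
    stop("resolution must divide the extent spans")
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == c(ny, nx)))
      stop("layer ", nm, " does not match the grid (", ny, " x ", nx, ")")
  }
  structure(list(layers = layers, extent = extent, resolution = resolution,
                 nx = nx, ny = ny, features = features),
            class = "cov_stack")
}

#' @method print cov_stack
#' @export
print.cov_stack <- function(x, ...) {
  cat("covariate stack:", x$nx, "x", x$ny, "cells at", x$resolution, "m\n")
  cat("  extent: [", paste(x$extent, collapse = ", "), "]\n")
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

cell_centers <- function(stack) {
  xs <- stack$extent[1] + (seq_len(stack$nx) - 0.5) * stack$resolution
  ys <- stack$extent[3] + (seq_len(stack$ny) - 0.5) * stack$resolution
  list(x = xs, y = ys)
}

# smoothed standardized white-noise field (separable gaussian blur with
# replicated edges), mean 0 / sd 1 over cells
gaussian_field <- function(ny, nx, sigma = 5) {
  z <- matrix(rnorm(ny * nx), ny, nx)
  hw <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  blur1 <- function(m) {   # along rows (y direction)
    out <- matrix(0, nrow(m), ncol(m))
    for (o in seq(-hw, hw)) {
      idx <- pmin(pmax(seq_len(nrow(m)) + o, 1L), nrow(m))
      out <- out + kern[o + hw + 1] * m[idx, , drop = FALSE]
    }
    out
  }
  z <- blur1(z)
  z <- t(blur1(t(z)))
  (z - mean(z)) / sd(z)
}

random_polyline <- function(extent, n_vertices = 7) {
  # a feature crossing the extent along a random principal direction with
  # lateral wander
  th <- runif(1, 0, pi)
  cx <- mean(extent[1:2]); cy <- mean(extent[3:4])
  half <- sqrt((extent[2] - extent[1])^2 + (extent[4] - extent[3])^2) / 2
  s <- seq(-half, half, length.out = n_vertices)
  lat <- cumsum(rnorm(n_vertices, 0, (extent[2] - extent[1]) / 15))
  lat <- lat - mean(lat)
  cbind(x = cx + s * cos(th) - lat * sin(th),
        y = cy + s * sin(th) + lat * cos(th))
}

min_dist_to_polyline <- function(px, py, verts) {
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(verts) - 1)) {
    d <- pmin(d, dist_point_segment(px, py, verts[k, 1], verts[k, 2],
                                    verts[k + 1, 1], verts[k + 1, 2]))
  }
  d
}

#' Simulate a synthetic landscape
#'
#' Generates the covariate roster used by the habitat analyses on a shared
#' grid: smooth standardized random fields (elevation, ruggedness,
#' snow_depth, heat_load, crown_cover, slope) plus Euclidean distance
#' rasters to random synthetic polylines (dist_road, dist_trail) and to
#' random circular patches (dist_escape, dist_barren, dist_herbaceous) --
#' eleven covariates in all.
#'
#' @param extent numeric length-4 xmin, xmax, ymin, ymax (m); area must be
#'   at least 1 km2.
#' @param resolution cell size (m).
#' @param seed optional integer seed.
#' @param smoothness gaussian blur sigma, in cells.
#' @return a [cov_stack()].
#' @export
simulate_landscape <- function(extent = c(0, 10000, 0, 10000),
                               resolution = 100, seed = NULL,
                               smoothness = 5) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent")
  if ((extent[2] - extent[1]) * (extent[4] - extent[3]) < 1e6)
    stop("extent area must be at least 1 km^2")
  if (!is.null(seed)) set.seed(seed)
  nx <- round((extent[2] - extent[1]) / resolution)
  ny <- round((extent[4] - extent[3]) / resolution)
  cc <- list(x = extent[1] + (seq_len(nx) - 0.5) * resolution,
             y = extent[3] + (seq_len(ny) - 0.5) * resolution)
  px <- rep(cc$x, each = ny); py <- rep(cc$y, nx)  # column-major over (y, x)

  continuous <- c("elevation", "ruggedness", "snow_depth", "heat_load",
                  "crown_cover", "slope")
  layers <- setNames(
    lapply(continuous, function(nm) gaussian_field(ny, nx, smoothness)),
    continuous)

  road <- random_polyline(extent)
  trail <- random_polyline(extent)
  layers$dist_road <- matrix(min_dist_to_polyline(px, py, road), ny, nx)
  layers$dist_trail <- matrix(min_dist_to_polyline(px, py, trail), ny, nx)

  patches <- lapply(c(escape = "escape", barren = "barren",
                      herbaceous = "herbaceous"), function(nm) {
    k <- 4
    cbind(x = runif(k, extent[1], extent[2]),
          y = runif(k, extent[3], extent[4]),
          r = runif(k, 200, 600))
  })
  for (nm in names(patches)) {
    p <- patches[[nm]]
    d <- rep(Inf, length(px))
    for (k in seq_len(nrow(p)))
      d <- pmin(d, pmax(0, sqrt((px - p[k, 1])^2 + (py - p[k, 2])^2) - p[k, 3]))
    layers[[paste0("dist_", nm)]] <- matrix(d, ny, nx)
  }

  cov_stack(layers, extent, resolution,
            features = list(road = road, trail = trail, patches = patches))
}

#' Extract covariate values at point locations
#'
#' Looks up the raster cell containing each coordinate (no interpolation).
#'
#' @param stack a [cov_stack()].
#' @param pts tibble/data frame with \code{x}, \code{y} (m).
#' @param layers layer names to extract; default all.
#' @return tibble of extracted values, one row per point.
#' @export
extract_covariates <- function(stack, pts, layers = names(stack$layers)) {
  stopifnot(inherits(stack, "cov_stack"))
  jx <- floor((pts$x - stack$extent[1]) / stack$resolution) + 1L
  iy <- floor((pts$y - stack$extent[3]) / stack$resolution) + 1L
  # points exactly on the max edge belong to the last cell
  jx[pts$x == stack$extent[2]] <- stack$nx
  iy[pts$y == stack$extent[4]] <- stack$ny
  bad <- which(jx < 1 | jx > stack$nx | iy < 1 | iy > stack$ny)
  if (length(bad) > 0)
    stop("fix/point ", bad[1], " at (", pts$x[bad[1]], ", ", pts$y[bad[1]],
         ") lies outside the raster extent")
  idx <- cbind(iy, jx)
  tibble::as_tibble(lapply(setNames(layers, layers),
                           function(nm) stack$layers[[nm]][idx]))
}

#' Simulate habitat-selected points with known coefficients
#'
#' Samples \code{n_used} point locations over a domain with probability
#' proportional to \code{exp(x . beta)}, by weighted resampling from the
#' dense grid of cell centres inside the domain (with uniform within-cell
#' jitter). Ground truth for validating RSF coefficient recovery.
#'
#' @param stack a [cov_stack()].
#' @param true_betas named numeric vector keyed to layer names; layers not
#'   named get coefficient 0.
#' @param n_used number of used points.
#' @param domain optional polygon (data frame with \code{x}, \code{y}
#'   vertices); default the full extent.
#' @param seed optional integer seed.
#' @return tibble of \code{x}, \code{y} used locations.
#' @export
simulate_selected_points <- function(stack, true_betas, n_used,
                                     domain = NULL, seed = NULL) {
  stopifnot(inherits(stack, "cov_stack"))
  miss <- setdiff(names(true_betas), names(stack$layers))
  if (length(miss) > 0)
    stop("betas reference unknown layer(s): ", paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  cc <- cell_centers(stack)
  px <- rep(cc$x, each = stack$ny); py <- rep(cc$y, stack$nx)
  keep <- rep(TRUE, length(px))
  if (!is.null(domain)) {
    keep <- sp::point.in.polygon(px, py, domain$x, domain$y) > 0
    if (!any(keep)) stop("domain contains no grid cells")
  }
  px <- px[keep]; py <- py[keep]
  eta <- rep(0, length(px))
  for (nm in names(true_betas)) {
    v <- stack$layers[[nm]][cbind(
      floor((py - stack$extent[3]) / stack$resolution) + 1L,
      floor((px - stack$extent[1]) / stack$resolution) + 1L)]
    eta <- eta + true_betas[[nm]] * v
  }
  w <- exp(eta - max(eta))
  if (all(w == 0) || !any(is.finite(w))) stop("all candidate weights are zero")
  pick <- sample.int(length(px), n_used, replace = TRUE, prob = w)
  half <- stack$resolution / 2
  tibble::tibble(x = px[pick] + runif(n_used, -half, half),
                 y = py[pick] + runif(n_used, -half, half))
}
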