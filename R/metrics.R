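# Movement metrics forming the HMM observation vector: step length (DIST, m),
# residence time within a 100 m radius (RT100, h), and rolling 24-h 95% MCP
# home-range area (HR, ha).

#' Step lengths between successive fixes
#'
#' \code{dist[i]} is the Euclidean distance (m) from fix i to fix i+1
#' (forward convention); the final element is NA.
#'
#' @param traj single-animal trajectory tibble.
#' @return numeric vector, length \code{nrow(traj)}.
#' @export
step_lengths <- function(traj) {
  assert_trajectory(traj)
  c(sqrt(diff(traj$x)^2 + diff(traj$y)^2), NA_real_)
}

# s-parameters in (0,1) where segment (x1,y1)-(x2,y2) crosses the circle
seg_circle_crossings <- function(x1, y1, x2, y2, cx, cy, r) {
  vx <- x2 - x1; vy <- y2 - y1
  a <- vx^2 + vy^2
  if (a < .Machine$double.eps) return(numeric(0))
  b <- 2 * ((x1 - cx) * vx + (y1 - cy) * vy)
  c0 <- (x1 - cx)^2 + (y1 - cy)^2 - r^2
  disc <- b^2 - 4 * a * c0
  if (disc <= 0) return(numeric(0))
  sq <- sqrt(disc)
  ss <- sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
  ss[ss > 1e-12 & ss < 1 - 1e-12]
}

# Directional residence time from fix i (times tx in hours, increasing).
# Walks forward accumulating elapsed time until the path leaves the circle
# centred on fix i for longer than max_gap (strictly); brief excursions are
# tolerated and their duration counts. Returns the time from tx[i] to the
# exit that begins the terminal excursion, or to track end (truncated).
rt_directional <- function(tx, X, Y, i, r, max_gap) {
  n <- length(tx)
  if (i >= n) return(list(time = 0, truncated = TRUE))
  cx <- X[i]; cy <- Y[i]
  d2 <- (X - cx)^2 + (Y - cy)^2
  inside <- d2 <= r^2 * (1 + 1e-12)
  out_after <- which(!inside & seq_len(n) > i)
  status_in <- TRUE
  pending_exit <- NA_real_
  j <- i
  while (j < n) {
    if (status_in && inside[j] && inside[j + 1]) {
      # both endpoints inside a convex region: the whole chord is inside
      nxt <- out_after[out_after > j]
      if (length(nxt) == 0) return(list(time = tx[n] - tx[i], truncated = TRUE))
      j <- nxt[1] - 1L
    }
    if (!status_in && tx[j] - pending_exit > max_gap) {
      return(list(time = pending_exit - tx[i], truncated = FALSE))
    }
    for (s in seg_circle_crossings(X[j], Y[j], X[j + 1], Y[j + 1], cx, cy, r)) {
      t_cross <- tx[j] + s * (tx[j + 1] - tx[j])
      if (status_in) {
        pending_exit <- t_cross
        status_in <- FALSE
      } else {
        if (t_cross - pending_exit > max_gap)
          return(list(time = pending_exit - tx[i], truncated = FALSE))
        status_in <- TRUE
        pending_exit <- NA_real_
      }
    }
    # reconcile with the endpoint in case a boundary touch eluded the solver
    if (status_in != inside[j + 1]) {
      if (status_in) {
        pending_exit <- tx[j + 1]
        status_in <- FALSE
      } else {
        if (tx[j + 1] - pending_exit > max_gap)
          return(list(time = pending_exit - tx[i], truncated = FALSE))
        status_in <- TRUE
        pending_exit <- NA_real_
      }
    }
    j <- j + 1L
  }
  if (status_in) return(list(time = tx[n] - tx[i], truncated = TRUE))
  gap <- tx[n] - pending_exit
  list(time = pending_exit - tx[i], truncated = gap <= max_gap)
}

#' Residence time within a radius
#'
#' For each fix, the sum of the forward and backward time before the animal
#' exits a circle of \code{radius} centred on that fix for a period greater
#' than \code{max_gap} hours (strictly). Entry/exit times between fixes are
#' obtained by linear interpolation along each segment; excursions outside
#' the circle no longer than \code{max_gap} do not stop accumulation and
#' their duration counts. Accumulation truncated by the track ends is
#' reported as computed and flagged.
#'
#' @param traj single-animal trajectory tibble.
#' @param radius circle radius, m.
#' @param max_gap excursion tolerance, hours.
#' @return tibble with columns \code{rt} (hours) and \code{rt_truncated}.
#' @export
residence_time <- function(traj, radius = 100, max_gap = 2) {
  assert_trajectory(traj)
  if (radius <= 0) stop("radius must be positive")
  n <- nrow(traj)
  tx <- as.numeric(traj$timestamp) / 3600
  X <- traj$x; Y <- traj$y
  rtx <- rev(-tx); rX <- rev(X); rY <- rev(Y)
  rt <- numeric(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    fw <- rt_directional(tx, X, Y, i, radius, max_gap)
    bw <- rt_directional(rtx, rX, rY, n - i + 1L, radius, max_gap)
    rt[i] <- fw$time + bw$time
    trunc[i] <- fw$truncated || bw$truncated
  }
  tibble::tibble(rt = rt, rt_truncated = trunc)
}

# area (ha) of the mcp_level MCP over points, trimming the floor((1-level)*n)
# points farthest from the arithmetic centroid; among tied distances the
# later timestamps are removed first (earlier fixes retained)
mcp_area <- function(x, y, ts, mcp_level) {
  n <- length(x)
  k <- floor((1 - mcp_level) * n)
  if (k > 0) {
    d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
    ord <- order(-d, -as.numeric(ts))
    drop <- ord[seq_len(k)]
    x <- x[-drop]; y <- y[-drop]
  }
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(list(area = 0, degenerate = TRUE))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  list(area = polygon_area(pts[h, 1], pts[h, 2]) / 1e4, degenerate = FALSE)
}

#' Rolling day home-range area
#'
#' For each fix, collects all fixes within \code{window/2} hours of its
#' timestamp, removes the \code{floor((1 - mcp_level) * n)} fixes farthest
#' from the window centroid, and reports the convex-hull area of the rest in
#' hectares. The 24-h default smooths over diurnal variation in movement.
#' Windows with fewer than 3 distinct retained points get area 0 and a flag.
#'
#' @param traj single-animal trajectory tibble.
#' @param window full window span, hours.
#' @param mcp_level MCP level in (0, 1].
#' @return tibble with columns \code{hr} (ha) and \code{hr_degenerate}.
#' @export
day_home_range <- function(traj, window = 24, mcp_level = 0.95) {
  assert_trajectory(traj)
  if (window <= 0) stop("window must be positive")
  if (mcp_level <= 0 || mcp_level > 1) stop("mcp_level must be in (0, 1]")
  n <- nrow(traj)
  tx <- as.numeric(traj$timestamp) / 3600
  half <- window / 2 + 1e-9
  hr <- numeric(n); degen <- logical(n)
  lo <- 1L
  for (i in seq_len(n)) {
    while (tx[lo] < tx[i] - half) lo <- lo + 1L
    hi <- i
    while (hi < n && tx[hi + 1L] <= tx[i] + half) hi <- hi + 1L
    idx <- lo:hi
    res <- mcp_area(traj$x[idx], traj$y[idx], traj$timestamp[idx], mcp_level)
    hr[i] <- res$area
    degen[i] <- res$degenerate
  }
  tibble::tibble(hr = hr, hr_degenerate = degen)
}

#' Compute the three movement metrics per fix
#'
#' Appends \code{dist} (step length, m; the final fix's missing value is
#' imputed from the preceding one and flagged), \code{rt100} (residence time,
#' h) and \code{hr} (rolling MCP home range, ha) plus validity flags to a
#' screened trajectory. Multiple animals are handled per animal.
#'
#' @param traj trajectory tibble.
#' @param radius residence-time radius, m.
#' @param max_gap residence-time excursion tolerance, hours.
#' @param window home-range window, hours.
#' @param mcp_level home-range MCP level.
#' @return the input tibble with metric and flag columns appended.
#' @export
movement_metrics <- function(traj, radius = 100, max_gap = 2,
                             window = 24, mcp_level = 0.95) {
  assert_trajectory(traj, min_fixes = 3L)
  parts <- split_animals(traj)
  if (length(parts) > 1) {
    return(dplyr::bind_rows(lapply(
      parts, movement_metrics,
      radius = radius, max_gap = max_gap,
      window = window, mcp_level = mcp_level)))
  }
  n <- nrow(traj)
  d <- step_lengths(traj)
  imput <- c(rep(FALSE, n - 1), TRUE)
  d[n] <- d[n - 1]
  rt_tbl <- residence_time(traj, radius = radius, max_gap = max_gap)
  hr_tbl <- day_home_range(traj, window = window, mcp_level = mcp_level)
  dplyr::mutate(traj,
                dist = d, dist_imputed = imput,
                rt100 = rt_tbl$rt, rt_truncated = rt_tbl$rt_truncated,
                hr = hr_tbl$hr, hr_degenerate = hr_tbl$hr_degenerate)
}
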