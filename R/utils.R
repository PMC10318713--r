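# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

hours_between <- function(t1, t0) as.numeric(difftime(t1, t0, units = "hours"))

# split a multi-animal tibble into an ordered list of per-animal tibbles
split_animals <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"animal_id" %in% names(df)) return(list(df))
  split(df, factor(df$animal_id, levels = unique(df$animal_id)))
}

assert_trajectory <- function(traj, min_fixes = 1L) {
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(traj))
  if (length(miss) > 0)
    stop("trajectory is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(traj$x)) || !all(is.finite(traj$y)))
    stop("trajectory coordinates must be finite")
  if (nrow(traj) < min_fixes)
    stop("trajectory has ", nrow(traj), " fixes; at least ", min_fixes, " required")
  for (a in split_animals(traj)) {
    dt <- diff(as.numeric(a$timestamp))
    if (any(dt <= 0))
      stop("timestamps must be strictly increasing within animal ", a$animal_id[1])
  }
  invisible(traj)
}

# shoelace polygon area (vertices in order, not closed), m^2
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# minimum distance from points (px, py) to segment (ax,ay)-(bx,by)
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  if (len2 < .Machine$double.eps)
    return(sqrt((px - ax)^2 + (py - ay)^2))
  s <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - ax - s * vx)^2 + (py - ay - s * vy)^2)
}

# wrapped Cauchy deviates centred on 0 with concentration rho in [0, 1)
rwrappedcauchy <- function(n, rho) {
  u <- runif(n)
  if (rho <= 0) return(runif(n, -pi, pi))
  th <- 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
  ((th + pi) %% (2 * pi)) - pi
}

# gamma shape from weighted sufficient statistic s = log(wmean) - wmean(log x),
# via the usual initialization + Newton steps on log(a) - digamma(a) = s
solve_gamma_shape <- function(s, lower = 1e-3, upper = 1e4) {
  if (!is.finite(s) || s <= 1e-12) return(upper)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in seq_len(60)) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * max(1, a)) { a <- a_new; break }
    a <- a_new
  }
  min(max(a, lower), upper)
}
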