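#' Simulation settings for a synthetic ewe-season
#'
#' Bundles every knob of the correlated-random-walk trajectory generator.
#' Defaults emulate a two-hour fix schedule over a May 15 - July 15 lambing
#' season with three movement regimes (non-movement, low movement, high
#' movement). Per-regime step lengths are gamma distributed and turning
#' angles wrapped Cauchy; regime switching follows a row-stochastic Markov
#' chain. A parturient ewe receives a deterministic near-stationary bout of
#' \code{bout_duration} hours at \code{event_time}, preceded by 24 h of
#' elevated movement (\code{pre_event_boost} on the step-length mean).
#'
#' Default step-length means (30 / 150 / 600 m per 2-h step) are chosen so
#' that daily average step length during a bout falls well below, and normal
#' ranging well above, the ~60 m daily minimum typical of postpartum ewes.
#'
#' @param season_start,season_end POSIXct season bounds (UTC).
#' @param fix_interval hours between fixes.
#' @param step_mean,step_shape,turn_concentration length-3 per-regime
#'   parameters, ordered non-movement, low, high. Step means must be strictly
#'   increasing in that order.
#' @param transition_matrix 3x3 row-stochastic regime transition matrix.
#'   The default makes the non-movement regime rare outside forced bouts,
#'   as observed for non-parturient ewes.
#' @param parturient logical; inject a lambing bout?
#' @param event_time POSIXct bout start, or \code{"random"} to draw it
#'   uniformly within the season (leaving room for the bout itself).
#' @param bout_duration bout length in hours.
#' @param pre_event_boost multiplier on the step-length mean for the 24 h
#'   preceding the bout.
#' @param p_2d,p_spike per-fix probabilities of an injected 2D-class fix and
#'   of an injected positional spike (see [inject_gps_errors()]).
#' @param seed optional integer seed consumed by [simulate_ewe()].
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(season_start = as.POSIXct("2022-05-15 00:00:00", tz = "UTC"),
                       season_end = as.POSIXct("2022-07-15 00:00:00", tz = "UTC"),
                       fix_interval = 2,
                       step_mean = c(30, 150, 600),
                       step_shape = c(1.5, 2.5, 2.5),
                       turn_concentration = c(0.1, 0.5, 0.8),
                       transition_matrix = NULL,
                       parturient = TRUE,
                       event_time = "random",
                       bout_duration = 48,
                       pre_event_boost = 2,
                       p_2d = 0.001,
                       p_spike = 0.001,
                       seed = NULL) {
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(c(
      0.50, 0.40, 0.10,
      0.003, 0.847, 0.15,
      0.003, 0.297, 0.70
    ), nrow = 3, byrow = TRUE)
  }
  cfg <- list(
    season_start = season_start, season_end = season_end,
    fix_interval = fix_interval,
    step_mean = step_mean, step_shape = step_shape,
    turn_concentration = turn_concentration,
    transition_matrix = transition_matrix,
    parturient = parturient, event_time = event_time,
    bout_duration = bout_duration, pre_event_boost = pre_event_boost,
    p_2d = p_2d, p_spike = p_spike, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  tm <- cfg$transition_matrix
  if (!is.matrix(tm) || any(dim(tm) != 3) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-12))
    stop("transition_matrix must be 3x3 row-stochastic (rows sum to 1)")
  if (!(cfg$step_mean[1] < cfg$step_mean[2] && cfg$step_mean[2] < cfg$step_mean[3]))
    stop("step means must be strictly ordered: non-movement < low < high")
  if (cfg$bout_duration <= 0) stop("bout_duration must be positive")
  if (any(c(cfg$p_2d, cfg$p_spike) < 0) || any(c(cfg$p_2d, cfg$p_spike) >= 0.2))
    stop("error rates must lie in [0, 0.2)")
  if (hours_between(cfg$season_end, cfg$season_start) < 20 * 24)
    stop("season must span at least 20 days")
  if (any(cfg$step_shape <= 0)) stop("step shapes must be positive")
  if (any(cfg$turn_concentration < 0 | cfg$turn_concentration >= 1))
    stop("turn concentrations must lie in [0, 1)")
  invisible(cfg)
}

regime_labels <- c("non-movement", "low-movement", "high-movement")

stationary_dist <- function(tm) {
  e <- eigen(t(tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Simulate one collared ewe-season
#'
#' Generates a correlated random walk at the configured fix interval: per-fix
#' regimes from the Markov chain, gamma step lengths and wrapped-Cauchy
#' turning angles from the regime parameters. For a parturient ewe the regime
#' is forced to non-movement for \code{bout_duration} hours from the event
#' time, and the step-length mean is multiplied by \code{pre_event_boost}
#' over the preceding 24 h. Reproducible under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param animal_id identifier written into the trajectory.
#' @param origin numeric length-2 start coordinates (m, projected CRS).
#' @return A list with elements \code{trajectory} (tibble: animal_id,
#'   timestamp, x, y, fix_class), \code{truth} (tibble: timestamp,
#'   true_state, error_flag) and \code{event_time} (POSIXct or NULL).
#' @export
simulate_ewe <- function(config = sim_config(), animal_id = "ewe01",
                         origin = c(0, 0)) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  times <- seq(config$season_start, config$season_end,
               by = config$fix_interval * 3600)
  n <- length(times)

  event <- NULL
  if (isTRUE(config$parturient)) {
    if (identical(config$event_time, "random")) {
      lo <- as.numeric(config$season_start) + 2 * 86400
      hi <- as.numeric(config$season_end) - config$bout_duration * 3600 - 2 * 86400
      event <- as.POSIXct(runif(1, lo, hi), origin = "1970-01-01", tz = "UTC")
    } else {
      event <- as.POSIXct(config$event_time, tz = "UTC")
      if (event < config$season_start ||
          as.numeric(event) + config$bout_duration * 3600 > as.numeric(config$season_end))
        stop("event_time (plus bout) must fall inside the season")
    }
  }

  # regime chain
  states <- integer(n)
  states[1] <- sample.int(3, 1, prob = stationary_dist(config$transition_matrix))
  u <- runif(n)
  cum <- t(apply(config$transition_matrix, 1, cumsum))
  for (i in 2:n) {
    states[i] <- findInterval(u[i], cum[states[i - 1], ], left.open = TRUE) + 1L
  }

  if (!is.null(event)) {
    tt <- as.numeric(times)
    in_bout <- tt >= as.numeric(event) & tt < as.numeric(event) + config$bout_duration * 3600
    states[in_bout] <- 1L
  }

  # steps: step i runs from fix i to fix i+1, governed by the regime at fix i
  st <- states[-n]
  mu <- config$step_mean[st]
  if (!is.null(event)) {
    tt <- as.numeric(times[-n])
    boosted <- tt >= as.numeric(event) - 24 * 3600 & tt < as.numeric(event)
    mu[boosted] <- mu[boosted] * config$pre_event_boost
  }
  shp <- config$step_shape[st]
  len <- rgamma(n - 1, shape = shp, scale = mu / shp)
  turn <- numeric(n - 1)
  for (k in 1:3) {
    idx <- which(st == k)
    if (length(idx) > 0) turn[idx] <- rwrappedcauchy(length(idx), config$turn_concentration[k])
  }
  heading <- cumsum(c(runif(1, -pi, pi), turn[-1]))
  x <- origin[1] + cumsum(c(0, len * cos(heading)))
  y <- origin[2] + cumsum(c(0, len * sin(heading)))

  traj <- tibble::tibble(
    animal_id = animal_id, timestamp = times,
    x = x, y = y, fix_class = "3D"
  )
  truth <- tibble::tibble(
    timestamp = times,
    true_state = factor(regime_labels[states], levels = regime_labels),
    error_flag = FALSE
  )
  list(trajectory = traj, truth = truth, event_time = event)
}

#' Inject GPS errors into a simulated trajectory
#'
#' Two error classes: with probability \code{p_2d} a fix is downgraded to a
#' 2D fix class; with probability \code{p_spike} an interior fix is displaced
#' 7--9 km so that its incoming and outgoing speeds land in (2, 5] km/h and
#' its turning-angle cosine falls below -0.975 (the displacement is redrawn
#' until the realized geometry carries that signature, so injected spikes are
#' exactly the out-and-back artefacts the screening rules target).
#' \code{truth$error_flag} marks every corrupted fix.
#'
#' @param sim a list as returned by [simulate_ewe()].
#' @param p_2d,p_spike override the rates stored in \code{config}; defaults
#'   taken from \code{config} if supplied, else 0.
#' @param config optional [sim_config()] supplying the rates.
#' @param seed optional integer seed.
#' @return A list with the same structure as \code{sim}, positions/classes
#'   corrupted and \code{error_flag} updated.
#' @export
inject_gps_errors <- function(sim, config = NULL, p_2d = NULL, p_spike = NULL,
                              seed = NULL) {
  p_2d <- p_2d %||% config$p_2d %||% 0
  p_spike <- p_spike %||% config$p_spike %||% 0
  if (p_2d < 0 || p_spike < 0 || p_2d >= 0.2 || p_spike >= 0.2)
    stop("error rates must lie in [0, 0.2)")
  if (!is.null(seed)) set.seed(seed)
  traj <- sim$trajectory
  truth <- sim$truth
  n <- nrow(traj)
  if (p_2d == 0 && p_spike == 0) return(sim)

  flag2d <- runif(n) < p_2d
  traj$fix_class[flag2d] <- "2D"

  cand <- runif(n) < p_spike
  cand[c(1, n)] <- FALSE
  spike_idx <- which(cand)
  # keep spikes non-adjacent so each retains clean neighbours
  if (length(spike_idx) > 1) {
    keep <- c(TRUE, diff(spike_idx) > 2)
    spike_idx <- spike_idx[keep]
  }
  dt_h <- diff(as.numeric(traj$timestamp)) / 3600
  for (i in spike_idx) {
    for (attempt in seq_len(200)) {
      d <- runif(1, 7000, 9000)
      th <- runif(1, -pi, pi)
      nx <- traj$x[i] + d * cos(th)
      ny <- traj$y[i] + d * sin(th)
      v1 <- c(nx - traj$x[i - 1], ny - traj$y[i - 1])
      v2 <- c(traj$x[i + 1] - nx, traj$y[i + 1] - ny)
      sp_in <- sqrt(sum(v1^2)) / 1000 / dt_h[i - 1]
      sp_out <- sqrt(sum(v2^2)) / 1000 / dt_h[i]
      cosv <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      if (sp_in > 2 && sp_out > 2 && sp_in <= 5 && sp_out <= 5 && cosv < -0.975) {
        traj$x[i] <- nx; traj$y[i] <- ny
        break
      }
    }
  }
  truth$error_flag <- truth$error_flag | flag2d
  truth$error_flag[spike_idx] <- TRUE
  list(trajectory = traj, truth = truth, event_time = sim$event_time)
}

#' Simulate a herd of ewe-seasons
#'
#' Convenience wrapper generating several parturient and non-parturient
#' animals under one base configuration, with per-animal seeds derived from
#' \code{seed}. Returns combined trajectories, per-fix truth and a truth
#' table of event times.
#'
#' @param n_parturient,n_nonparturient animal counts.
#' @param config base [sim_config()]; \code{parturient}/\code{seed} fields
#'   are overridden per animal.
#' @param seed integer base seed.
#' @param inject_errors logical; corrupt fixes at the configured rates?
#' @return list with \code{trajectories} (one tibble, all animals),
#'   \code{truth} (per-fix tibble with animal_id) and \code{events}
#'   (tibble: animal_id, parturient, event_time).
#' @export
simulate_herd <- function(n_parturient = 13, n_nonparturient = 8,
                          config = sim_config(), seed = 1,
                          inject_errors = FALSE) {
  ids <- c(sprintf("P%02d", seq_len(n_parturient)),
           sprintf("N%02d", seq_len(n_nonparturient)))
  part <- c(rep(TRUE, n_parturient), rep(FALSE, n_nonparturient))
  out <- purrr::map(seq_along(ids), function(i) {
    cfg <- config
    cfg$parturient <- part[i]
    cfg$seed <- as.integer((as.double(seed) * 1000 + i) %% 2147483647)
    sim <- simulate_ewe(cfg, animal_id = ids[i])
    if (inject_errors)
      sim <- inject_gps_errors(
        sim, config = cfg,
        seed = as.integer((as.double(seed) * 1000 + i + 500) %% 2147483647))
    sim
  })
  trajectories <- dplyr::bind_rows(purrr::map(out, "trajectory"))
  truth <- dplyr::bind_rows(purrr::map2(out, ids, function(s, id)
    dplyr::mutate(s$truth, animal_id = id, .before = 1)))
  events <- tibble::tibble(
    animal_id = ids, parturient = part,
    event_time = as.POSIXct(
      purrr::map_dbl(out, function(s) {
        if (is.null(s$event_time)) NA_real_ else as.numeric(s$event_time)
      }),
      origin = "1970-01-01", tz = "UTC")
  )
  list(trajectories = trajectories, truth = truth, events = events)
}
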