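# Independent oracle implementations and shared fixtures. Oracles are
# deliberately written without reference to the package internals they
# check: brute-force scans, path enumeration, closed forms.

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# ---- brute-force residence time -------------------------------------------
# O(n^2): for each focal fix, scan every segment of the path, solve the
# segment/circle intersection inline, list all boundary events in time
# order, then apply the gap rule to the event list. No skipping, no early
# termination.
oracle_residence_time <- function(traj, radius = 100, max_gap = 2) {
  tx <- as.numeric(traj$timestamp) / 3600
  X <- traj$x; Y <- traj$y
  n <- length(tx)

  events_along <- function(idx, cx, cy) {
    # boundary-crossing times walking fixes in the order given by idx
    ev <- numeric(0)
    for (q in seq_len(length(idx) - 1)) {
      a <- idx[q]; b <- idx[q + 1]
      vx <- X[b] - X[a]; vy <- Y[b] - Y[a]
      A <- vx^2 + vy^2
      if (A < 1e-300) next
      B <- 2 * ((X[a] - cx) * vx + (Y[a] - cy) * vy)
      C <- (X[a] - cx)^2 + (Y[a] - cy)^2 - radius^2
      disc <- B^2 - 4 * A * C
      if (disc <= 0) next
      for (s in c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))) {
        if (s > 1e-12 && s < 1 - 1e-12)
          ev <- c(ev, tx[a] + s * (tx[b] - tx[a]))
      }
    }
    sort(ev)
  }

  one_side <- function(idx) {
    # idx: fix indices in walking order starting at the focal fix
    i0 <- idx[1]
    ev <- events_along(idx, X[i0], Y[i0])
    t0 <- tx[i0]
    tend <- tx[idx[length(idx)]]
    dir_ev <- sort(abs(ev - t0))          # event offsets, walking direction
    inside <- TRUE
    exit_at <- NA_real_
    for (e in dir_ev) {
      if (inside) {
        exit_at <- e
        inside <- FALSE
      } else {
        if (e - exit_at > max_gap) return(exit_at)
        inside <- TRUE
        exit_at <- NA_real_
      }
    }
    span <- abs(tend - t0)
    if (inside) span else exit_at
  }

  vapply(seq_len(n), function(i) {
    fw <- if (i < n) one_side(i:n) else 0
    bw <- if (i > 1) one_side(i:1) else 0
    fw + bw
  }, numeric(1))
}

# exhaustive enumeration over all K^T hidden paths
oracle_enumerate_hmm <- function(logpi, logA, logB) {
  Tn <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- logpi[paths[, 1]] + logB[cbind(1, paths[, 1])]
  if (Tn > 1) {
    for (t in 2:Tn) {
      lp <- lp + logA[cbind(paths[, t - 1], paths[, t])] +
        logB[cbind(t, paths[, t])]
    }
  }
  best <- which.max(lp)
  list(path = as.integer(paths[best, ]), max_logprob = lp[best],
       total_loglik = logsumexp(lp))
}

# ---- small track builders --------------------------------------------------
make_track <- function(x, y, dt_h = 2, id = "T01",
                       start = as.POSIXct("2022-06-01", tz = "UTC")) {
  tibble::tibble(animal_id = id,
                 timestamp = start + 3600 * dt_h * (seq_along(x) - 1),
                 x = x, y = y, fix_class = "3D")
}

stationary_track <- function(n = 25, dt_h = 2) {
  make_track(rep(1000, n), rep(1000, n), dt_h = dt_h)
}

straight_track <- function(n = 20, step = 200, dt_h = 2) {
  make_track(step * (seq_len(n) - 1), rep(0, n), dt_h = dt_h)
}

# 12 fixes on the boundary of a 100 m square plus its centre
square_track <- function() {
  cx <- c(0, 50, 100, 100, 100, 50, 0, 0, 25, 75, 25, 75, 50)
  cy <- c(0, 0, 0, 50, 100, 100, 100, 50, 0, 0, 100, 100, 50)
  make_track(cx, cy)
}

# a random 3-state gamma HMM over three channels (means well separated)
random_gamma_hmm <- function(K = 3, channels = c("dist", "rt100", "hr")) {
  pi0 <- as.numeric(stats::rgamma(K, 1) + 0.2); pi0 <- pi0 / sum(pi0)
  A <- matrix(stats::rgamma(K * K, 1) + 0.1, K, K)
  A <- A / rowSums(A)
  mu <- matrix(exp(stats::runif(K * length(channels), log(5), log(500))),
               K, length(channels), dimnames = list(NULL, channels))
  shape <- matrix(stats::runif(K * length(channels), 0.8, 5),
                  K, length(channels), dimnames = list(NULL, channels))
  list(init = pi0, trans = A, mu = mu, shape = shape, channels = channels)
}

sample_hmm_data <- function(par, Tn) {
  K <- length(par$init)
  s <- integer(Tn)
  s[1] <- sample.int(K, 1, prob = par$init)
  for (t in seq_len(Tn)[-1])
    s[t] <- sample.int(K, 1, prob = par$trans[s[t - 1], ])
  obs <- sapply(seq_along(par$channels), function(j)
    rgamma(Tn, shape = par$shape[s, j], rate = par$shape[s, j] / par$mu[s, j]))
  colnames(obs) <- par$channels
  list(states = s, data = tibble::as_tibble(obs))
}

# wrap parameters into a decodable model object (floors tiny so no flooring)
as_lamb_hmm <- function(par) {
  structure(list(
    n_states = length(par$init), channels = par$channels,
    init = par$init, trans = par$trans, mu = par$mu, shape = par$shape,
    floors = setNames(rep(1e-12, length(par$channels)), par$channels),
    state_labels = NULL, loglik = NA_real_, ll_trace = NULL,
    n_iter = NA_integer_, converged = TRUE, n_sequences = 1L,
    n_obs = NA_integer_, seed = NULL), class = "lamb_hmm")
}

# logistic mixed-model design table with known coefficients
make_glmm_table <- function(n_animals, n_per, betas, sigma, seed,
                            intercept = 0) {
  set.seed(seed)
  u <- rnorm(n_animals, 0, sigma)
  X <- matrix(rnorm(n_animals * n_per * length(betas)), ncol = length(betas))
  colnames(X) <- names(betas)
  eta <- intercept + as.numeric(X %*% betas) + rep(u, each = n_per)
  dplyr::bind_cols(
    tibble::tibble(response = rbinom(length(eta), 1, stats::plogis(eta)),
                   animal_id = rep(sprintf("A%02d", seq_len(n_animals)),
                                   each = n_per)),
    tibble::as_tibble(X))
}

# ---- shared heavy fixture ---------------------------------------------------
.fixture <- new.env(parent = emptyenv())

herd_fixture <- function() {
  if (!is.null(.fixture$herd)) return(.fixture$herd)
  herd <- simulate_herd(n_parturient = 13, n_nonparturient = 8, seed = 101)
  scr <- screen_fixes(herd$trajectories)
  met <- movement_metrics(scr$trajectory)
  part_ids <- herd$events$animal_id[herd$events$parturient]
  model <- label_states(fit_hmm(met[met$animal_id %in% part_ids, ],
                                n_restarts = 10, seed = 102))
  .fixture$herd <- list(herd = herd, metrics = met, model = model,
                        part_ids = part_ids,
                        nonpart_ids = setdiff(herd$events$animal_id, part_ids))
  .fixture$herd
}
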