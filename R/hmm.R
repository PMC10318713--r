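# 3-state hidden Markov model with independent gamma emissions per channel
# (DIST, RT100, HR), fitted by Baum-Welch EM across animal-seasons with
# shared parameters, decoded by Viterbi.

as_metric_sets <- function(data, channels) {
  if (is.data.frame(data)) data <- split_animals(data)
  stopifnot(is.list(data), length(data) >= 1)
  for (d in data) {
    miss <- setdiff(channels, names(d))
    if (length(miss) > 0)
      stop("metric data missing channel(s): ", paste(miss, collapse = ", "))
  }
  data
}

# per-channel floor: gamma support excludes 0 but DIST can be 0 at stationary
# fixes; floor at floor_frac * smallest positive observed value per channel
compute_floors <- function(mats, channels, floor_frac) {
  vapply(channels, function(ch) {
    v <- unlist(lapply(mats, function(m) m[[ch]]), use.names = FALSE)
    pos <- v[is.finite(v) & v > 0]
    if (length(pos) == 0) stop("channel ", ch, " has no positive values")
    floor_frac * min(pos)
  }, numeric(1))
}

floor_channels <- function(d, channels, floors) {
  m <- as.matrix(d[, channels, drop = FALSE])
  if (any(!is.finite(m))) stop("non-finite metric values; screen and impute first")
  for (j in seq_along(channels)) m[, j] <- pmax(m[, j], floors[j])
  m
}

# T x K log emission densities for one floored observation matrix
emission_logdens <- function(obs, mu, shape) {
  K <- nrow(mu)
  out <- matrix(0, nrow(obs), K)
  for (k in seq_len(K)) {
    for (j in seq_len(ncol(obs))) {
      out[, k] <- out[, k] +
        dgamma(obs[, j], shape = shape[k, j], rate = shape[k, j] / mu[k, j],
               log = TRUE)
    }
  }
  out
}

init_params <- function(obs_all, channels, n_states, jitter = FALSE) {
  # provisional states from a quantile split of RT100 (or the first channel)
  key <- if ("rt100" %in% channels) "rt100" else channels[1]
  v <- obs_all[, match(key, channels)]
  qs <- quantile(v, probs = seq_len(n_states - 1) / n_states, names = FALSE)
  g <- findInterval(v, unique(qs)) + 1L
  g <- pmin(g, n_states)
  mu <- matrix(0, n_states, length(channels),
               dimnames = list(NULL, channels))
  shape <- mu
  for (k in seq_len(n_states)) {
    sel <- if (sum(g == k) >= 5) g == k else rep(TRUE, nrow(obs_all))
    for (j in seq_along(channels)) {
      m <- mean(obs_all[sel, j]); s2 <- var(obs_all[sel, j])
      mu[k, j] <- max(m, 1e-8)
      shape[k, j] <- min(max(if (is.finite(s2) && s2 > 0) m^2 / s2 else 1, 0.05), 500)
    }
  }
  if (jitter) {
    mu <- mu * exp(matrix(rnorm(length(mu), 0, 0.4), nrow(mu)))
    shape <- pmin(pmax(shape * exp(matrix(rnorm(length(shape), 0, 0.4),
                                          nrow(shape))), 0.05), 500)
  }
  trans <- matrix(0.1 / max(1, n_states - 1), n_states, n_states)
  diag(trans) <- if (n_states > 1) 0.9 else 1
  list(init = rep(1 / n_states, n_states), trans = trans, mu = mu, shape = shape)
}

em_once <- function(obs_list, par, tol, max_iter) {
  K <- length(par$init)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g1 <- numeric(K); xi <- matrix(0, K, K)
    sw <- matrix(0, K, ncol(par$mu)); swx <- sw; swlx <- sw
    colsums_g <- numeric(K)
    for (obs in obs_list) {
      fb <- hmm_forward_backward(emission_logdens(obs, par$mu, par$shape),
                                 par$init, par$trans)
      if (!is.finite(fb$loglik))
        stop("non-finite likelihood during EM; check metric channels for ",
             "zeros or extreme values")
      ll <- ll + fb$loglik
      g1 <- g1 + fb$gamma1
      xi <- xi + fb$xi
      for (k in seq_len(K)) {
        w <- fb$gamma[, k]
        sw[k, ] <- sw[k, ] + rep(sum(w), ncol(obs))
        swx[k, ] <- swx[k, ] + colSums(w * obs)
        swlx[k, ] <- swlx[k, ] + colSums(w * log(obs))
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    par$init <- g1 / sum(g1)
    if (K > 1) {
      rs <- rowSums(xi)
      for (k in seq_len(K)) {
        par$trans[k, ] <- if (rs[k] > 0) xi[k, ] / rs[k] else rep(1 / K, K)
      }
    }
    for (k in seq_len(K)) {
      for (j in seq_len(ncol(par$mu))) {
        if (sw[k, j] <= 0) next
        m <- swx[k, j] / sw[k, j]
        s <- log(m) - swlx[k, j] / sw[k, j]
        par$mu[k, j] <- max(m, 1e-10)
        par$shape[k, j] <- solve_gamma_shape(s)
      }
    }
  }
  list(par = par, loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       n_iter = length(ll_trace), converged = converged)
}

#' Fit a gamma-emission hidden Markov model to movement metrics
#'
#' Baum-Welch EM maximizing the joint likelihood over all training
#' animal-seasons: each sequence contributes its own forward-backward pass
#' while the initial distribution, transition matrix and per-state gamma
#' emission parameters (mean on the positive scale, shape via the digamma
#' Newton update on weighted sufficient statistics) are shared. The three
#' channels are conditionally independent given the state. Channels are
#' floored at \code{floor_frac} times the smallest positive observed value
#' so zero step lengths stay inside the gamma support; the floors are stored
#' in the model and re-applied when decoding. The best of \code{n_restarts}
#' initializations (quantile-split initialization, jittered thereafter) by
#' final log-likelihood is returned.
#'
#' @param data tibble with the metric channels (and \code{animal_id} to split
#'   sequences), or a list of per-animal tibbles.
#' @param channels character vector of metric column names.
#' @param n_states number of latent states.
#' @param n_restarts EM restarts.
#' @param seed integer seed (required for reproducible restarts).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param floor_frac positive-support floor fraction.
#' @return object of class \code{lamb_hmm}: probabilities, emission
#'   parameters, floors, labels (once [label_states()] is applied),
#'   log-likelihood trace and convergence record.
#' @export
fit_hmm <- function(data, channels = c("dist", "rt100", "hr"), n_states = 3,
                    n_restarts = 10, seed = NULL, tol = 1e-6, max_iter = 500,
                    floor_frac = 0.5) {
  sets <- as_metric_sets(data, channels)
  n_total <- sum(vapply(sets, nrow, 0L))
  if (length(sets) < 2 && n_total < 500)
    stop("need at least 2 animals or 500 total fixes to fit the HMM")
  if (!is.null(seed)) set.seed(seed)
  floors <- compute_floors(sets, channels, floor_frac)
  obs_list <- lapply(sets, floor_channels, channels = channels, floors = floors)
  obs_all <- do.call(rbind, obs_list)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    par0 <- init_params(obs_all, channels, n_states, jitter = r > 1)
    fit <- tryCatch(em_once(obs_list, par0, tol, max_iter),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts failed")
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best iterate")
  structure(list(
    n_states = n_states, channels = channels,
    init = best$par$init, trans = best$par$trans,
    mu = best$par$mu, shape = best$par$shape,
    floors = floors, state_labels = NULL,
    loglik = best$loglik, ll_trace = best$ll_trace,
    n_iter = best$n_iter, converged = best$converged,
    n_sequences = length(sets), n_obs = n_total, seed = seed
  ), class = "lamb_hmm")
}

#' Label HMM states semantically
#'
#' The non-movement state is the one with the highest RT100 emission mean;
#' among the remaining two, the high-movement state has the higher DIST
#' mean; the last is low-movement. Errors on (near-)tied means, which signal
#' degenerate states needing a refit.
#'
#' @param model a fitted [fit_hmm()] model with 3 states.
#' @return the model with \code{state_labels} filled in.
#' @export
label_states <- function(model) {
  stopifnot(inherits(model, "lamb_hmm"))
  if (model$n_states != 3) stop("state labelling is defined for 3-state models")
  if (!all(c("dist", "rt100") %in% model$channels))
    stop("labelling needs 'dist' and 'rt100' channels")
  rt <- model$mu[, "rt100"]
  if (min(diff(sort(rt))) < 1e-9)
    stop("tied RT100 emission means: degenerate states, refit the model")
  nm <- which.max(rt)
  rest <- setdiff(1:3, nm)
  dd <- model$mu[rest, "dist"]
  if (abs(diff(dd)) < 1e-9)
    stop("tied DIST emission means: degenerate states, refit the model")
  hi <- rest[which.max(dd)]
  lo <- setdiff(rest, hi)
  labels <- character(3)
  labels[nm] <- "non-movement"
  labels[hi] <- "high-movement"
  labels[lo] <- "low-movement"
  model$state_labels <- labels
  model
}

#' Decode the most probable state path
#'
#' Log-space Viterbi dynamic programming under a fitted model; ties break
#' toward the lower state index. The model's channel floors are applied to
#' the observations before evaluating emission densities.
#'
#' @param model a fitted [fit_hmm()] model.
#' @param data metric tibble for one animal (or several; decoded per animal).
#' @return the input tibble with \code{state} (integer) and, if the model is
#'   labelled, \code{state_label} appended.
#' @export
viterbi <- function(model, data) {
  stopifnot(inherits(model, "lamb_hmm"))
  if (is.data.frame(data) && "animal_id" %in% names(data) &&
      length(unique(data$animal_id)) > 1) {
    return(dplyr::bind_rows(lapply(split_animals(data), viterbi, model = model)))
  }
  obs <- floor_channels(data, model$channels, model$floors)
  logB <- emission_logdens(obs, model$mu, model$shape)
  path <- hmm_viterbi_path(logB, log(model$init), log(model$trans))
  out <- dplyr::mutate(data, state = as.integer(path))
  if (!is.null(model$state_labels))
    out$state_label <- model$state_labels[out$state]
  out
}

#' Total observation log-likelihood under the model
#'
#' Forward-algorithm log-likelihood of one or more metric sequences.
#'
#' @inheritParams viterbi
#' @return scalar log-likelihood (nats).
#' @export
forward_loglik <- function(model, data) {
  stopifnot(inherits(model, "lamb_hmm"))
  sets <- as_metric_sets(data, model$channels)
  sum(vapply(sets, function(d) {
    obs <- floor_channels(d, model$channels, model$floors)
    fb <- hmm_forward_backward(emission_logdens(obs, model$mu, model$shape),
                               model$init, model$trans)
    fb$loglik
  }, numeric(1)))
}

#' @method print lamb_hmm
#' @export
print.lamb_hmm <- function(x, ...) {
  cat(x$n_states, "-state gamma-emission HMM (", paste(x$channels, collapse = ", "),
      ")\n", sep = "")
  cat("log-likelihood:", format(x$loglik), "after", x$n_iter, "EM iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  lab <- x$state_labels %||% paste("state", seq_len(x$n_states))
  for (k in seq_len(x$n_states)) {
    cat(sprintf("  %-14s means: %s\n", lab[k],
                paste(sprintf("%s=%.3g", x$channels, x$mu[k, ]), collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn fit_hmm tidy emission parameters: one row per state x channel.
#' @param x a \code{lamb_hmm} object.
#' @param ... unused.
#' @export
tidy.lamb_hmm <- function(x, ...) {
  K <- x$n_states
  tibble::tibble(
    state = rep(seq_len(K), each = length(x$channels)),
    label = rep(x$state_labels %||% rep(NA_character_, K),
                each = length(x$channels)),
    channel = rep(x$channels, K),
    mean = as.vector(t(x$mu)),
    shape = as.vector(t(x$shape))
  )
}

#' @describeIn fit_hmm one-row model summary.
#' @export
glance.lamb_hmm <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, n_obs = x$n_obs,
                 n_sequences = x$n_sequences)
}
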