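# Habitat-use (latent selection difference) and habitat-selection (resource
# selection function) designs, fitted as random-intercept logistic
# regressions.

#' Exponential decay transform for distance-to-feature covariates
#'
#' \code{exp(-3 d / range)}: value 1 at the feature, about 5\% at
#' \code{range} metres, effectively zero beyond, capturing the diminishing
#' influence of linear disturbance features with distance.
#'
#' @param d distance in metres (non-negative).
#' @param range saturation range in metres.
#' @return values in (0, 1].
#' @export
decay_transform <- function(d, range = 500) {
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  exp(-3 * d / range)
}

#' Minimum convex polygon of a point set
#'
#' Discards the \code{floor((1 - level) * n)} points farthest from the
#' arithmetic centroid, then returns the convex hull of the rest.
#'
#' @param pts data frame with \code{x}, \code{y}.
#' @param level MCP level in (0, 1].
#' @return tibble of hull vertices (counter-ordered, not closed).
#' @export
mcp_polygon <- function(pts, level = 0.95) {
  stopifnot(all(c("x", "y") %in% names(pts)))
  if (nrow(unique(pts[, c("x", "y")])) < 3)
    stop("need at least 3 distinct locations for an MCP")
  x <- pts$x; y <- pts$y
  k <- floor((1 - level) * length(x))
  if (k > 0) {
    d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
    drop <- order(-d)[seq_len(k)]
    x <- x[-drop]; y <- y[-drop]
  }
  h <- grDevices::chull(x, y)
  if (length(h) < 3) stop("MCP polygon is degenerate (collinear points)")
  tibble::tibble(x = x[h], y = y[h])
}

standardize_covariates <- function(tbl, cols) {
  for (cc in cols) {
    v <- tbl[[cc]]
    s <- sd(v)
    tbl[[cc]] <- if (is.finite(s) && s > 0) (v - mean(v)) / s else v - mean(v)
  }
  tbl
}

covariate_columns <- function(tbl) {
  setdiff(names(tbl), c("response", "animal_id", "timestamp", "x", "y",
                        "weight", "design", "status", "period"))
}

#' Build the latent selection difference (LSD) design table
#'
#' For each parturient animal with a detected call, rows are its fixes in a
#' \code{span}-day window before (response 0, prepartum) and after
#' (response 1, postpartum) the called lambing time; the call timestamp
#' itself belongs to the postpartum window. Covariates are extracted at fix
#' coordinates; distance-to-road/trail layers pass through
#' [decay_transform()]; continuous covariates are z-scored over the pooled
#' table (so coefficient magnitudes are comparable across covariates).
#' Animals with an empty window side are flagged in the
#' \code{"unbalanced_animals"} attribute.
#'
#' @param traj trajectory tibble covering all animals.
#' @param calls [detect_lambing()] output (only detected rows are used).
#' @param stack a [cov_stack()].
#' @param span window half-width, days (15 before + 15 after by default).
#' @param decay_layers layer names transformed with [decay_transform()].
#' @param decay_range see [decay_transform()].
#' @param standardize z-score covariates over the pooled table?
#' @return tibble: \code{response}, \code{animal_id}, covariate columns.
#' @export
build_lsd_table <- function(traj, calls, stack, span = 15,
                            decay_layers = c("dist_road", "dist_trail"),
                            decay_range = 500, standardize = TRUE) {
  assert_trajectory(traj)
  calls <- calls[calls$detected, , drop = FALSE]
  if (nrow(calls) == 0) stop("no detected lambing calls to build an LSD table")
  rows <- purrr::map(seq_len(nrow(calls)), function(i) {
    id <- calls$animal_id[i]
    t0 <- calls$lambing_datetime[i]
    a <- traj[traj$animal_id == id, , drop = FALSE]
    pre <- a[a$timestamp >= t0 - span * 86400 & a$timestamp < t0, , drop = FALSE]
    post <- a[a$timestamp >= t0 & a$timestamp < t0 + span * 86400, , drop = FALSE]
    dplyr::bind_rows(
      dplyr::mutate(pre, response = 0L, .before = 1),
      dplyr::mutate(post, response = 1L, .before = 1)
    )
  })
  tbl <- dplyr::bind_rows(rows)
  unbalanced <- vapply(split(tbl$response, tbl$animal_id),
                       function(r) !all(c(0L, 1L) %in% r), logical(1))
  covs <- extract_covariates(stack, tbl)
  for (nm in intersect(decay_layers, names(covs)))
    covs[[nm]] <- decay_transform(covs[[nm]], range = decay_range)
  out <- dplyr::bind_cols(
    tbl[, c("response", "animal_id", "timestamp", "x", "y"), drop = FALSE],
    covs)
  if (standardize) out <- standardize_covariates(out, names(covs))
  attr(out, "design") <- "LSD"
  attr(out, "unbalanced_animals") <- names(unbalanced)[unbalanced]
  out
}

#' Build the resource selection function (RSF) design table
#'
#' Used sites (response 1) are the supplied fixes; availability is defined
#' by a \code{mcp_level} MCP pooled over ALL supplied animals (the same
#' habitat is considered available to every ewe), within which
#' \code{ratio} available points (response 0) per used point are sampled
#' uniformly by rejection from the polygon's bounding box. Available points
#' are allocated to animals in proportion to their used counts so the
#' random-intercept structure is preserved. Covariate extraction, decay and
#' pooled standardization mirror [build_lsd_table()].
#'
#' @param traj used fixes (all animals of one reproductive status).
#' @param stack a [cov_stack()].
#' @param ratio available:used sampling ratio.
#' @param mcp_level home-range MCP level.
#' @param seed optional integer seed for availability sampling.
#' @inheritParams build_lsd_table
#' @return tibble: \code{response}, \code{animal_id}, covariate columns;
#'   the pooled MCP polygon is attached as attribute \code{"home_range"}.
#' @export
build_rsf_table <- function(traj, stack, ratio = 10, mcp_level = 0.95,
                            seed = NULL,
                            decay_layers = c("dist_road", "dist_trail"),
                            decay_range = 500, standardize = TRUE) {
  assert_trajectory(traj)
  if (!is.null(seed)) set.seed(seed)
  hr <- mcp_polygon(traj[, c("x", "y")], level = mcp_level)
  used <- dplyr::mutate(traj[, c("animal_id", "x", "y")], response = 1L)

  sample_in_polygon <- function(n) {
    out_x <- numeric(0); out_y <- numeric(0)
    while (length(out_x) < n) {
      m <- max(1000, 2 * (n - length(out_x)))
      cx <- runif(m, min(hr$x), max(hr$x))
      cy <- runif(m, min(hr$y), max(hr$y))
      ok <- sp::point.in.polygon(cx, cy, hr$x, hr$y) > 0
      out_x <- c(out_x, cx[ok]); out_y <- c(out_y, cy[ok])
    }
    tibble::tibble(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
  }

  n_by_animal <- table(used$animal_id)
  avail <- purrr::map(names(n_by_animal), function(id) {
    p <- sample_in_polygon(ratio * n_by_animal[[id]])
    dplyr::mutate(p, animal_id = id, response = 0L)
  })
  tbl <- dplyr::bind_rows(used, dplyr::bind_rows(avail))
  covs <- extract_covariates(stack, tbl)
  for (nm in intersect(decay_layers, names(covs)))
    covs[[nm]] <- decay_transform(covs[[nm]], range = decay_range)
  out <- dplyr::bind_cols(
    tbl[, c("response", "animal_id", "x", "y"), drop = FALSE], covs)
  if (standardize) out <- standardize_covariates(out, names(covs))
  attr(out, "design") <- "RSF"
  attr(out, "home_range") <- hr
  out
}

#' Random-intercept logistic regression for LSD/RSF tables
#'
#' Maximum-likelihood fit of a logistic model with one Gaussian random
#' intercept per animal via \code{lme4::glmer} with adaptive Gauss-Hermite
#' quadrature (\code{nAGQ} nodes). Fixed effects get 95\% Wald confidence
#' intervals. A coefficient with an absurd standard error triggers a
#' complete-separation error naming the covariate.
#'
#' @param table a design table from [build_lsd_table()] or
#'   [build_rsf_table()] (needs \code{response}, \code{animal_id} and
#'   covariate columns).
#' @param nAGQ quadrature nodes (>= 10 recommended).
#' @param conf_level Wald CI level.
#' @return object of class \code{lamb_glmm}: coefficient tibble,
#'   random-intercept SD, convergence flag, and the underlying fit.
#' @export
fit_random_intercept_logistic <- function(table, nAGQ = 10, conf_level = 0.95) {
  stopifnot(all(c("response", "animal_id") %in% names(table)))
  if (length(unique(table$animal_id)) < 2)
    stop("need at least 2 animals for a random-intercept model")
  covs <- covariate_columns(table)
  if (length(covs) == 0) stop("no covariate columns found")
  fml <- as.formula(paste("response ~",
                          paste(sprintf("`%s`", covs), collapse = " + "),
                          "+ (1 | animal_id)"))
  fit <- suppressMessages(lme4::glmer(fml, data = table, family = binomial(),
                                      nAGQ = nAGQ))
  converged <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  if (any(se > 50)) {
    worst <- names(est)[which.max(se)]
    stop("possible complete separation on covariate ", worst,
         " (SE = ", format(max(se), digits = 3), ")")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  coef_tbl <- tibble::tibble(
    term = gsub("`", "", names(est)),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se)
  )
  vc <- lme4::VarCorr(fit)
  structure(list(
    coefficients = coef_tbl,
    sigma_animal = attr(vc$animal_id, "stddev")[[1]],
    n_obs = nrow(table),
    n_animals = length(unique(table$animal_id)),
    converged = converged,
    design = attr(table, "design") %||% NA_character_,
    conf_level = conf_level,
    fit = fit
  ), class = "lamb_glmm")
}

#' @method print lamb_glmm
#' @export
print.lamb_glmm <- function(x, ...) {
  cat("Random-intercept logistic regression",
      if (!is.na(x$design)) paste0("(", x$design, " design)"), "\n")
  cat("  ", x$n_obs, "observations,", x$n_animals, "animals; sigma_animal =",
      format(x$sigma_animal, digits = 3),
      if (!x$converged) "[convergence warning]", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @describeIn fit_random_intercept_logistic fixed-effect coefficient table.
#' @param x a \code{lamb_glmm} object.
#' @param ... unused.
#' @export
tidy.lamb_glmm <- function(x, ...) x$coefficients

#' @describeIn fit_random_intercept_logistic one-row fit summary.
#' @export
glance.lamb_glmm <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_animals = x$n_animals,
                 sigma_animal = x$sigma_animal,
                 logLik = as.numeric(logLik(x$fit)),
                 converged = x$converged)
}

#' Compare selection coefficients between two fitted models
#'
#' Per covariate: both estimates with confidence intervals, their
#' difference, and whether the intervals overlap -- the criterion used to
#' flag selection differences between reproductive statuses.
#'
#' @param fit_a,fit_b two [fit_random_intercept_logistic()] fits on the
#'   same covariate roster (e.g. parturient vs non-parturient RSFs).
#' @param labels length-2 character labels for the two fits.
#' @return tibble of class \code{lamb_selection_comparison}, sorted by term.
#' @export
compare_selection <- function(fit_a, fit_b,
                              labels = c("parturient", "non_parturient")) {
  ta <- tidy(fit_a); tb <- tidy(fit_b)
  if (!setequal(ta$term, tb$term))
    stop("covariate rosters differ between the two fits")
  ta <- ta[order(ta$term), ]
  tb <- tb[match(ta$term, tb$term), ]
  out <- tibble::tibble(
    term = ta$term,
    estimate_a = ta$estimate, conf.low_a = ta$conf.low, conf.high_a = ta$conf.high,
    estimate_b = tb$estimate, conf.low_b = tb$conf.low, conf.high_b = tb$conf.high,
    difference = ta$estimate - tb$estimate,
    ci_overlap = ta$conf.low <= tb$conf.high & tb$conf.low <= ta$conf.high
  )
  attr(out, "labels") <- labels
  class(out) <- c("lamb_selection_comparison", class(out))
  out
}
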