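# Collar CSV readers/writers, model serialization and the end-to-end
# pipeline driver. Timestamps are stored as ISO-8601 UTC; CSVs are
# comma-separated with a header row and unquoted numerics.

fmt_ts <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read a collar CSV
#'
#' Expects columns \code{animal_id, timestamp, x, y, fix_class} (timestamp
#' ISO-8601 UTC). Rows are grouped by animal and sorted by timestamp (with a
#' notice if re-ordering was needed); duplicate timestamps within an animal
#' are rejected with the offending row number.
#'
#' @param path file path.
#' @return trajectory tibble.
#' @export
read_collar_csv <- function(path) {
  wanted <- list(animal_id = readr::col_character(),
                 timestamp = readr::col_character(),
                 x = readr::col_double(), y = readr::col_double(),
                 fix_class = readr::col_character())
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  spec <- do.call(readr::cols,
                  c(wanted[intersect(names(wanted), trimws(hdr))],
                    .default = list(readr::col_guess())))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = spec)
  need <- c("animal_id", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("collar CSV missing column(s): ", paste(miss, collapse = ", "))
  if (!"fix_class" %in% names(df)) df$fix_class <- "3D"
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  if (any(is.na(ts)))
    stop("unparseable timestamp at row ", which(is.na(ts))[1])
  df$timestamp <- ts
  df$animal_id <- as.character(df$animal_id)
  for (a in split(seq_len(nrow(df)), df$animal_id)) {
    dup <- duplicated(df$timestamp[a])
    if (any(dup))
      stop("duplicate timestamp for animal ", df$animal_id[a[1]],
           " at row ", a[dup][1])
  }
  ord <- order(match(df$animal_id, unique(df$animal_id)), df$timestamp)
  if (!identical(ord, seq_len(nrow(df)))) {
    message("collar CSV rows were out of order; sorted by animal and timestamp")
    df <- df[ord, ]
  }
  tibble::as_tibble(df[, c(need, "fix_class")])
}

#' Write a trajectory as collar CSV
#'
#' @param traj trajectory tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_collar_csv <- function(traj, path) {
  out <- dplyr::mutate(traj, timestamp = fmt_ts(.data$timestamp))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Serialize / restore a fitted HMM as JSON
#'
#' All probabilities, gamma parameters, channel floors, labels,
#' log-likelihood and seed survive a round trip.
#'
#' @param model a \code{lamb_hmm}.
#' @param path JSON path.
#' @return \code{write_hmm_json}: the path, invisibly;
#'   \code{read_hmm_json}: the restored \code{lamb_hmm}.
#' @export
write_hmm_json <- function(model, path) {
  stopifnot(inherits(model, "lamb_hmm"))
  payload <- list(
    n_states = model$n_states, channels = model$channels,
    init = model$init, trans = model$trans,
    mu = model$mu, shape = model$shape,
    floors = model$floors, state_labels = model$state_labels,
    loglik = model$loglik, n_iter = model$n_iter,
    converged = model$converged, seed = model$seed
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- as.matrix(p$mu); colnames(mu) <- p$channels
  shape <- as.matrix(p$shape); colnames(shape) <- p$channels
  structure(list(
    n_states = p$n_states, channels = p$channels,
    init = as.numeric(p$init), trans = as.matrix(p$trans),
    mu = mu, shape = shape,
    floors = setNames(as.numeric(p$floors), p$channels),
    state_labels = p$state_labels,
    loglik = p$loglik, ll_trace = NULL, n_iter = p$n_iter,
    converged = p$converged, n_sequences = NA_integer_,
    n_obs = NA_integer_, seed = p$seed
  ), class = "lamb_hmm")
}

#' Write a covariate stack as plain-text CSV (long format) + metadata JSON
#'
#' @param stack a [cov_stack()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_stack_csv <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cc <- cell_centers(stack)
  grid <- tibble::tibble(x = rep(cc$x, each = stack$ny),
                         y = rep(cc$y, stack$nx))
  vals <- tibble::as_tibble(lapply(stack$layers, as.vector))
  readr::write_csv(dplyr::bind_cols(grid, vals),
                   file.path(dir, "covariates.csv"), progress = FALSE)
  jsonlite::write_json(list(extent = stack$extent,
                            resolution = stack$resolution,
                            layers = names(stack$layers)),
                       file.path(dir, "stack_meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read pipeline settings from a YAML file
#'
#' The file holds any subset of [run_pipeline()]'s scalar arguments plus an
#' optional \code{sim:} block whose entries override [sim_config()] defaults
#' (scalar fields only; season bounds as ISO dates).
#'
#' @param path YAML file path.
#' @return named list of arguments ready for \code{do.call(run_pipeline, .)}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  for (f in c("season_start", "season_end")) {
    if (!is.null(sim_args[[f]]))
      sim_args[[f]] <- as.POSIXct(sim_args[[f]], tz = "UTC")
  }
  if (!is.null(sim_args$event_time) && !identical(sim_args$event_time, "random"))
    sim_args$event_time <- as.POSIXct(sim_args$event_time, tz = "UTC")
  y$config <- do.call(sim_config, sim_args)
  y
}

#' Run the full synthetic pipeline
#'
#' Simulation -> screening -> metrics -> HMM fit on parturient animals ->
#' decoding and lambing calls for every animal -> (optionally) LSD and RSF
#' habitat analyses on a simulated landscape. Every intermediate artifact is
#' written to \code{out_dir} along with a machine-readable manifest that
#' fully determines a rerun. Byte-identical outputs under a fixed seed.
#'
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @param n_parturient,n_nonparturient herd composition.
#' @param config base [sim_config()].
#' @param habitat run the LSD/RSF stages? (skipped with a notice otherwise).
#' @param n_restarts EM restarts for the HMM stage.
#' @param window,threshold decision-rule settings.
#' @param span LSD window half-width, days.
#' @param ratio RSF available:used ratio.
#' @param decay_range [decay_transform()] range, m.
#' @param tz reporting timezone for calendar dates.
#' @return invisible list of the main in-memory results and artifact paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_parturient = 13,
                         n_nonparturient = 8, config = sim_config(),
                         habitat = TRUE, n_restarts = 5, window = 48,
                         threshold = 0.5, span = 15, ratio = 10,
                         decay_range = 500, tz = "UTC") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    artifacts <<- c(artifacts, name)
    p
  }

  message("stage: simulate (", n_parturient, " parturient + ",
          n_nonparturient, " non-parturient)")
  herd <- simulate_herd(n_parturient, n_nonparturient, config = config,
                        seed = seed, inject_errors = TRUE)
  write_collar_csv(herd$trajectories, emit("collar.csv"))
  truth_out <- dplyr::mutate(herd$truth, timestamp = fmt_ts(.data$timestamp))
  readr::write_csv(truth_out, emit("truth.csv"), progress = FALSE)
  readr::write_csv(dplyr::mutate(herd$events,
                                 event_time = fmt_ts(.data$event_time)),
                   emit("events.csv"), progress = FALSE)

  message("stage: screening")
  scr <- screen_fixes(herd$trajectories)
  write_collar_csv(scr$trajectory, emit("clean.csv"))
  jsonlite::write_json(
    list(n_input = scr$report$n_input,
         n_removed_by_rule = as.list(scr$report$n_removed_by_rule),
         fraction_removed = scr$report$fraction_removed),
    emit("screening_report.json"), digits = NA, auto_unbox = TRUE)

  message("stage: metrics")
  met <- movement_metrics(scr$trajectory)
  readr::write_csv(dplyr::mutate(met, timestamp = fmt_ts(.data$timestamp)),
                   emit("metrics.csv"), progress = FALSE)

  message("stage: HMM fit (parturient training set)")
  part_ids <- herd$events$animal_id[herd$events$parturient]
  model <- label_states(fit_hmm(met[met$animal_id %in% part_ids, ],
                                n_restarts = n_restarts, seed = seed))
  write_hmm_json(model, emit("model.json"))

  message("stage: decode + detect")
  states <- viterbi(model, met)
  readr::write_csv(dplyr::mutate(states, timestamp = fmt_ts(.data$timestamp)),
                   emit("states.csv"), progress = FALSE)
  calls <- detect_lambing(states, window = window, threshold = threshold,
                          tz = tz)
  readr::write_csv(dplyr::mutate(calls,
                                 lambing_datetime = fmt_ts(.data$lambing_datetime)),
                   emit("calls.csv"), progress = FALSE)

  lsd_fit <- rsf_cmp <- NULL
  if (isTRUE(habitat)) {
    message("stage: habitat (LSD + RSF)")
    pad <- 1000
    ext <- c(floor(min(scr$trajectory$x)) - pad, ceiling(max(scr$trajectory$x)) + pad,
             floor(min(scr$trajectory$y)) - pad, ceiling(max(scr$trajectory$y)) + pad)
    res <- 100
    ext[2] <- ext[1] + ceiling((ext[2] - ext[1]) / res) * res
    ext[4] <- ext[3] + ceiling((ext[4] - ext[3]) / res) * res
    stack <- simulate_landscape(extent = ext, resolution = res,
                                seed = seed + 7777)
    write_stack_csv(stack, file.path(out_dir, "landscape"))
    artifacts <- c(artifacts, "landscape/covariates.csv", "landscape/stack_meta.json")

    part_calls <- calls[calls$animal_id %in% part_ids & calls$detected, ]
    lsd_tbl <- build_lsd_table(scr$trajectory, part_calls, stack, span = span,
                               decay_range = decay_range)
    readr::write_csv(lsd_tbl, emit("lsd_table.csv"), progress = FALSE)
    lsd_fit <- fit_random_intercept_logistic(lsd_tbl)
    jsonlite::write_json(list(design = "LSD", coefficients = tidy(lsd_fit),
                              sigma_animal = lsd_fit$sigma_animal),
                         emit("lsd_fit.json"), digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")

    rsf_fit <- function(ids, sd) {
      tbl <- build_rsf_table(scr$trajectory[scr$trajectory$animal_id %in% ids, ],
                             stack, ratio = ratio, seed = sd,
                             decay_range = decay_range)
      fit_random_intercept_logistic(tbl)
    }
    nonpart_ids <- herd$events$animal_id[!herd$events$parturient]
    fit_p <- rsf_fit(part_ids, seed + 11)
    fit_n <- rsf_fit(nonpart_ids, seed + 12)
    rsf_cmp <- compare_selection(fit_p, fit_n)
    readr::write_csv(rsf_cmp, emit("rsf_comparison.csv"), progress = FALSE)
    jsonlite::write_json(
      list(parturient = tidy(fit_p), non_parturient = tidy(fit_n)),
      emit("rsf_fits.json"), digits = NA, auto_unbox = TRUE,
      dataframe = "rows")
  } else {
    message("habitat stages skipped (habitat = FALSE); ",
            "pipeline complete through lambing calls")
  }

  manifest <- list(
    package = "lambwatch",
    version = as.character(utils::packageVersion("lambwatch")),
    seed = seed,
    parameters = list(n_parturient = n_parturient,
                      n_nonparturient = n_nonparturient,
                      n_restarts = n_restarts, window = window,
                      threshold = threshold, span = span, ratio = ratio,
                      decay_range = decay_range, tz = tz,
                      habitat = isTRUE(habitat)),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(model = model, calls = calls, lsd_fit = lsd_fit,
                 rsf_comparison = rsf_cmp, manifest = manifest,
                 out_dir = out_dir))
}
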