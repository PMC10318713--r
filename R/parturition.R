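# Two-day / >50% decision rule on decoded state sequences, plus the
# leave-one-out cross-validation and out-of-sample evaluation protocols.

#' Call a lambing event from a decoded state sequence
#'
#' Slides a window of \code{window} hours across the sequence, advancing one
#' fix at a time; for each window the proportion of fixes decoded as
#' non-movement is computed over fix counts. The maximum-proportion window
#' (earliest on ties) yields a detection iff its proportion strictly exceeds
#' \code{threshold}; the reported lambing time is the window's start fix.
#' Windows extending past the end of the track are not scanned.
#'
#' @param states tibble with \code{timestamp} and \code{state_label} (and
#'   optionally \code{animal_id}; several animals are processed per animal).
#' @param window window span, hours.
#' @param threshold strict detection threshold on the non-movement
#'   proportion.
#' @param tz timezone used to report the calendar date.
#' @return one-row tibble per animal: \code{animal_id}, \code{detected},
#'   \code{lambing_datetime}, \code{lambing_date}, \code{window_proportion},
#'   \code{window_span}. All windows above threshold are attached as the
#'   \code{"windows"} attribute (diagnostics).
#' @export
detect_lambing <- function(states, window = 48, threshold = 0.5, tz = "UTC") {
  stopifnot(is.data.frame(states), "state_label" %in% names(states),
            "timestamp" %in% names(states))
  parts <- split_animals(states)
  if (length(parts) > 1) {
    res <- lapply(parts, detect_lambing, window = window,
                  threshold = threshold, tz = tz)
    out <- dplyr::bind_rows(res)
    attr(out, "windows") <- dplyr::bind_rows(lapply(res, attr, "windows"))
    return(out)
  }
  s <- parts[[1]]
  n <- nrow(s)
  tt <- as.numeric(s$timestamp)
  span_s <- window * 3600
  starts <- which(tt + span_s <= tt[n] + 1e-6)
  if (length(starts) == 0)
    stop("sequence shorter than one ", window, "-h window")
  is_nm <- as.integer(s$state_label == "non-movement")
  cs <- c(0L, cumsum(is_nm))
  ends <- findInterval(tt[starts] + span_s - 1e-6, tt)
  prop <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  best <- which.max(prop)           # first index on ties = earliest window
  detected <- prop[best] > threshold
  aid <- if ("animal_id" %in% names(s)) s$animal_id[1] else NA_character_
  call_time <- if (detected) s$timestamp[starts[best]] else
    as.POSIXct(NA, tz = "UTC")
  out <- tibble::tibble(
    animal_id = aid,
    detected = detected,
    lambing_datetime = call_time,
    lambing_date = as.Date(call_time, tz = tz),
    window_proportion = prop[best],
    window_span = window
  )
  above <- which(prop > threshold)
  attr(out, "windows") <- tibble::tibble(
    animal_id = aid,
    window_start = s$timestamp[starts[above]],
    proportion = prop[above]
  )
  out
}

#' Leave-one-out cross-validation of the lambing detector
#'
#' For each animal: fit the HMM on all other animals, label its states,
#' decode the held-out animal with Viterbi and apply the decision rule. A
#' fold succeeds iff an event is detected and its date lies inside the
#' animal's validation window. A full-data model is also fitted once and its
#' calls compared with the fold predictions (agreement within ±6 h).
#' Per-fold fitting errors are recorded without aborting the other folds.
#'
#' @param data metric tibble covering all animals (needs \code{animal_id},
#'   \code{timestamp} and the metric channels).
#' @param validation tibble: \code{animal_id}, \code{earliest},
#'   \code{latest} (Date) plausible birth interval per animal.
#' @param window,threshold,tz decision-rule settings, see [detect_lambing()].
#' @param ... passed on to [fit_hmm()] (e.g. \code{n_restarts}, \code{seed}).
#' @return object of class \code{lamb_loocv}: per-fold tibble and the
#'   aggregate success rate.
#' @export
loocv <- function(data, validation, window = 48, threshold = 0.5, tz = "UTC",
                  ...) {
  stopifnot(all(c("animal_id", "earliest", "latest") %in% names(validation)))
  if (any(validation$earliest > validation$latest))
    stop("validation windows must satisfy earliest <= latest")
  sets <- split_animals(data)
  ids <- names(sets)
  if (length(sets) < 3) stop("LOOCV needs at least 3 animals")

  full_model <- label_states(fit_hmm(data, ...))
  full_calls <- detect_lambing(viterbi(full_model, data), window = window,
                               threshold = threshold, tz = tz)

  folds <- purrr::map(ids, function(id) {
    res <- tryCatch({
      train <- dplyr::bind_rows(sets[setdiff(ids, id)])
      m <- label_states(fit_hmm(train, ...))
      call <- detect_lambing(viterbi(m, sets[[id]]), window = window,
                             threshold = threshold, tz = tz)
      call
    }, error = function(e) {
      tibble::tibble(animal_id = id, detected = FALSE,
                     lambing_datetime = as.POSIXct(NA, tz = "UTC"),
                     lambing_date = as.Date(NA),
                     window_proportion = NA_real_, window_span = window,
                     fold_error = conditionMessage(e))
    })
    res
  })
  folds <- dplyr::bind_rows(folds)
  if (!"fold_error" %in% names(folds)) folds$fold_error <- NA_character_

  v <- validation[match(folds$animal_id, validation$animal_id), ]
  folds$in_validation_window <- folds$detected & !is.na(v$earliest) &
    folds$lambing_date >= v$earliest & folds$lambing_date <= v$latest
  folds$in_validation_window[is.na(folds$in_validation_window)] <- FALSE

  fc <- full_calls[match(folds$animal_id, full_calls$animal_id), ]
  dt_h <- abs(as.numeric(difftime(folds$lambing_datetime, fc$lambing_datetime,
                                  units = "hours")))
  folds$agrees_with_full <- folds$detected & fc$detected & !is.na(dt_h) & dt_h <= 6
  folds$success <- folds$detected & folds$in_validation_window

  structure(list(
    folds = folds,
    success_rate = mean(folds$success),
    full_calls = full_calls,
    full_model = full_model
  ), class = "lamb_loocv")
}

#' @method print lamb_loocv
#' @export
print.lamb_loocv <- function(x, ...) {
  cat("Leave-one-out cross-validation over", nrow(x$folds), "animals\n")
  cat(sprintf("  success rate: %.3f (%d/%d)\n", x$success_rate,
              sum(x$folds$success), nrow(x$folds)))
  cat("  agree with full-data call (±6 h):", sum(x$folds$agrees_with_full), "\n")
  invisible(x)
}

#' @describeIn loocv per-fold results.
#' @param x a \code{lamb_loocv} object.
#' @param ... unused.
#' @export
tidy.lamb_loocv <- function(x, ...) x$folds

#' @describeIn loocv one-row summary.
#' @export
glance.lamb_loocv <- function(x, ...) {
  tibble::tibble(n_animals = nrow(x$folds),
                 n_success = sum(x$folds$success),
                 success_rate = x$success_rate,
                 n_agree_full = sum(x$folds$agrees_with_full))
}

#' Apply a fitted model out of sample
#'
#' Decodes and applies the decision rule to animals not used in training
#' (e.g. non-parturient or unknown-status ewes). When ground truth event
#' times are supplied (simulations), per-animal absolute timing errors and
#' false-positive indicators are added.
#'
#' @param model fitted, labelled [fit_hmm()] model.
#' @param data metric tibble for the evaluation animals; an empty tibble (or
#'   one with zero rows) yields an empty report.
#' @param truth optional tibble \code{animal_id}, \code{event_time}
#'   (POSIXct or NA for no event).
#' @param window,threshold,tz see [detect_lambing()].
#' @return tibble: per animal \code{detected}, \code{lambing_datetime},
#'   \code{window_proportion}; with truth also \code{true_event_time},
#'   \code{abs_error_h}, \code{false_positive}.
#' @export
evaluate_out_of_sample <- function(model, data, truth = NULL, window = 48,
                                   threshold = 0.5, tz = "UTC") {
  if (is.null(data) || nrow(data) == 0) {
    return(tibble::tibble(animal_id = character(0), detected = logical(0),
                          lambing_datetime = as.POSIXct(character(0), tz = "UTC"),
                          window_proportion = numeric(0)))
  }
  calls <- detect_lambing(viterbi(model, data), window = window,
                          threshold = threshold, tz = tz)
  if (!is.null(truth)) {
    tr <- truth[match(calls$animal_id, truth$animal_id), ]
    calls$true_event_time <- tr$event_time
    calls$abs_error_h <- abs(as.numeric(difftime(
      calls$lambing_datetime, tr$event_time, units = "hours")))
    calls$false_positive <- calls$detected & is.na(tr$event_time)
  }
  calls
}
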