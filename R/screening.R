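#' Per-fix travel speeds and turning-angle cosine
#'
#' For each fix computes the incoming speed (from the previous fix, km/h),
#' outgoing speed (to the next fix, km/h) and the cosine of the turning
#' angle, i.e. the normalized dot product of the displacement vectors
#' arriving at and leaving the fix. Quantities lacking a neighbour are NA;
#' the cosine is NA when either adjacent step has zero length.
#'
#' @param traj single-animal trajectory tibble (animal_id, timestamp, x, y).
#' @return The input with columns \code{incoming_speed}, \code{outgoing_speed}
#'   and \code{turn_cosine} appended.
#' @export
fix_kinematics <- function(traj) {
  assert_trajectory(traj)
  if (length(unique(traj$animal_id)) > 1)
    return(dplyr::bind_rows(lapply(split_animals(traj), fix_kinematics)))
  n <- nrow(traj)
  dt <- diff(as.numeric(traj$timestamp)) / 3600
  if (any(dt <= 0)) stop("zero or negative elapsed time between fixes")
  dx <- diff(traj$x); dy <- diff(traj$y)
  step <- sqrt(dx^2 + dy^2)
  speed <- step / 1000 / dt                       # km/h per interval
  incoming <- c(NA_real_, speed)
  outgoing <- c(speed, NA_real_)
  cosv <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    num <- dx[i - 1] * dx[i] + dy[i - 1] * dy[i]
    den <- step[i - 1] * step[i]
    cosv[i] <- ifelse(den > 0, num / den, NA_real_)
  }
  dplyr::mutate(traj, incoming_speed = incoming, outgoing_speed = outgoing,
                turn_cosine = cosv)
}

is_2d_class <- function(fc) {
  if (is.numeric(fc)) return(fc < 4)           # satellite counts
  toupper(trimws(as.character(fc))) == "2D"
}

#' Screen erroneous GPS fixes
#'
#' Applies three removal rules in order: (1) drop fixes with a 2D fix class
#' (fewer than 4 satellites); (2) drop fixes whose incoming speed exceeds
#' \code{max_speed}; (3) drop spike fixes whose incoming and outgoing speeds
#' both exceed \code{spike_speed} while the turning-angle cosine is below
#' \code{cos_threshold} (an out-and-back artefact). Because removing a fix
#' changes its neighbours' speeds, rules 2-3 are recomputed on the surviving
#' sequence and repeated until a pass removes nothing. Track endpoints are
#' never removed by rules 2-3.
#'
#' @param traj trajectory tibble; multiple animals are screened per animal.
#' @param max_speed rule-2 incoming-speed ceiling, km/h.
#' @param spike_speed rule-3 speed threshold, km/h.
#' @param cos_threshold rule-3 turning-cosine threshold.
#' @return list with \code{trajectory} (surviving fixes) and \code{report}
#'   (class \code{screening_report}: n_input, per-rule removal counts,
#'   removed row indices of the input, fraction removed).
#' @export
screen_fixes <- function(traj, max_speed = 5, spike_speed = 2,
                         cos_threshold = -0.97) {
  assert_trajectory(traj, min_fixes = 3L)
  parts <- split_animals(traj)
  if (length(parts) > 1) {
    offs <- cumsum(c(0, head(vapply(parts, nrow, 0L), -1)))
    res <- purrr::map2(parts, offs, function(a, off) {
      r <- screen_fixes(a, max_speed, spike_speed, cos_threshold)
      r$report$removed_indices <- r$report$removed_indices + off
      r
    })
    rep_all <- structure(list(
      n_input = nrow(traj),
      n_removed_by_rule = Reduce(`+`, purrr::map(res, ~ .x$report$n_removed_by_rule)),
      removed_indices = sort(unlist(purrr::map(res, ~ .x$report$removed_indices),
                                    use.names = FALSE)),
      fraction_removed = NA_real_,
      per_animal = purrr::map(res, "report")
    ), class = "screening_report")
    rep_all$fraction_removed <- length(rep_all$removed_indices) / nrow(traj)
    return(list(trajectory = dplyr::bind_rows(purrr::map(res, "trajectory")),
                report = rep_all))
  }

  n_input <- nrow(traj)
  orig_idx <- seq_len(n_input)
  counts <- c(rule_2d = 0L, rule_speed = 0L, rule_spike = 0L)
  removed <- integer(0)

  is2d <- is_2d_class(traj$fix_class %||% rep("3D", n_input))
  if (any(is2d)) {
    counts["rule_2d"] <- sum(is2d)
    removed <- c(removed, orig_idx[is2d])
    traj <- traj[!is2d, , drop = FALSE]
    orig_idx <- orig_idx[!is2d]
  }

  repeat {
    n <- nrow(traj)
    if (n < 3) stop("fewer than 3 fixes survive screening")
    k <- fix_kinematics(traj)
    interior <- seq_len(n) > 1 & seq_len(n) < n
    r2 <- which(interior & !is.na(k$incoming_speed) & k$incoming_speed > max_speed)
    if (length(r2) > 0) {
      counts["rule_speed"] <- counts["rule_speed"] + length(r2)
      removed <- c(removed, orig_idx[r2])
      traj <- traj[-r2, , drop = FALSE]
      orig_idx <- orig_idx[-r2]
      next
    }
    r3 <- which(interior &
                  !is.na(k$incoming_speed) & k$incoming_speed > spike_speed &
                  !is.na(k$outgoing_speed) & k$outgoing_speed > spike_speed &
                  !is.na(k$turn_cosine) & k$turn_cosine < cos_threshold)
    if (length(r3) > 0) {
      counts["rule_spike"] <- counts["rule_spike"] + length(r3)
      removed <- c(removed, orig_idx[r3])
      traj <- traj[-r3, , drop = FALSE]
      orig_idx <- orig_idx[-r3]
      next
    }
    break
  }
  if (nrow(traj) < 3) stop("fewer than 3 fixes survive screening")
  report <- structure(list(
    n_input = n_input,
    n_removed_by_rule = counts,
    removed_indices = sort(removed),
    fraction_removed = length(removed) / n_input
  ), class = "screening_report")
  list(trajectory = traj, report = report)
}

#' @method print screening_report
#' @export
print.screening_report <- function(x, ...) {
  cat("GPS screening report\n")
  cat("  fixes in:       ", x$n_input, "\n")
  cat("  removed (2D):   ", x$n_removed_by_rule[["rule_2d"]], "\n")
  cat("  removed (speed):", x$n_removed_by_rule[["rule_speed"]], "\n")
  cat("  removed (spike):", x$n_removed_by_rule[["rule_spike"]], "\n")
  cat(sprintf("  fraction removed: %.4f%%\n", 100 * x$fraction_removed))
  invisible(x)
}

#' @export
tidy.screening_report <- function(x, ...) {
  tibble::tibble(
    rule = c("2d_class", "incoming_speed", "spike"),
    n_removed = as.integer(x$n_removed_by_rule)
  )
}
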