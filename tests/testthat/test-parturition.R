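label_seq <- function(labels, dt_h = 2, id = "E01") {
  tibble::tibble(
    animal_id = id,
    timestamp = as.POSIXct("2022-06-01", tz = "UTC") + 3600 * dt_h *
      (seq_along(labels) - 1),
    state_label = labels)
}

test_that("the decision rule handles saturated, empty and bout sequences", {
  n <- 30 * 12   # 30 days of 2-h fixes
  all_nm <- label_seq(rep("non-movement", n))
  call <- detect_lambing(all_nm)
  expect_true(call$detected)
  expect_equal(call$lambing_datetime, all_nm$timestamp[1])
  expect_equal(call$window_proportion, 1.0)

  none <- label_seq(rep(c("low-movement", "high-movement"), n / 2))
  expect_false(detect_lambing(none)$detected)

  # single contiguous 30-h bout (15 fixes): best 48-h window = 15/24 = 0.625
  labs <- rep("high-movement", n)
  labs[101:115] <- "non-movement"
  seq30 <- label_seq(labs)
  call <- detect_lambing(seq30)
  expect_true(call$detected)
  expect_equal(call$window_proportion, 15 / 24)
  # brute-force window scan confirms the selected start
  tt <- as.numeric(seq30$timestamp)
  starts <- which(tt + 48 * 3600 <= tt[n] + 1e-6)
  props <- vapply(starts, function(i) {
    inw <- tt >= tt[i] & tt < tt[i] + 48 * 3600
    mean(labs[inw] == "non-movement")
  }, numeric(1))
  expect_equal(call$lambing_datetime, seq30$timestamp[starts[which.max(props)]])
})

test_that("a best window at or below the threshold yields no call", {
  n <- 30 * 12
  labs <- rep("high-movement", n)
  labs[101:109] <- "non-movement"      # 18-h bout: best window 9/24 = 0.375
  expect_false(detect_lambing(label_seq(labs))$detected)
  # exactly at the threshold is not enough (strict inequality)
  labs[101:112] <- "non-movement"      # 12/24 = 0.5
  call <- detect_lambing(label_seq(labs))
  expect_equal(call$window_proportion, 0.5)
  expect_false(call$detected)
})

test_that("detection is monotone in the threshold and anchored to real fixes", {
  set.seed(81)
  for (r in 1:20) {
    labs <- sample(c("non-movement", "low-movement", "high-movement"),
                   200, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    s <- label_seq(labs)
    lo <- detect_lambing(s, threshold = 0.3)
    hi <- detect_lambing(s, threshold = 0.6)
    expect_true(lo$detected >= hi$detected)
    if (lo$detected)
      expect_true(lo$lambing_datetime %in% s$timestamp)
  }
})

test_that("the rule ignores the identity of the two movement states", {
  labs <- rep("low-movement", 360)
  labs[50:73] <- "non-movement"
  a <- detect_lambing(label_seq(labs))
  swapped <- ifelse(labs == "low-movement", "high-movement", labs)
  b <- detect_lambing(label_seq(swapped))
  expect_equal(a$detected, b$detected)
  expect_equal(a$lambing_datetime, b$lambing_datetime)
  expect_equal(a$window_proportion, b$window_proportion)
})

test_that("LOOCV has the right fold structure and scores validation windows", {
  fx <- herd_fixture()
  ids <- fx$part_ids[1:4]
  met <- fx$metrics[fx$metrics$animal_id %in% ids, ]
  ev <- fx$herd$events[match(ids, fx$herd$events$animal_id), ]
  validation <- tibble::tibble(
    animal_id = ids,
    earliest = as.Date(ev$event_time) - 3,
    latest = as.Date(ev$event_time) + 3)
  # push one validation window far from the true event: that fold must fail
  validation$earliest[2] <- as.Date("2022-05-01")
  validation$latest[2] <- as.Date("2022-05-05")
  cv <- loocv(met, validation, n_restarts = 2, seed = 82)
  expect_equal(nrow(cv$folds), length(ids))
  expect_setequal(cv$folds$animal_id, ids)
  expect_false(cv$folds$success[cv$folds$animal_id == ids[2]])
  expect_equal(cv$success_rate, mean(cv$folds$success))
  expect_equal(glance(cv)$n_animals, 4L)
})

test_that("out-of-sample evaluation reports empty inputs and truth comparisons", {
  fx <- herd_fixture()
  empty <- evaluate_out_of_sample(fx$model, fx$metrics[0, ])
  expect_equal(nrow(empty), 0)

  np <- fx$metrics[fx$metrics$animal_id %in% fx$nonpart_ids[1:3], ]
  truth <- tibble::tibble(animal_id = fx$nonpart_ids[1:3],
                          event_time = as.POSIXct(NA, tz = "UTC"))
  rep <- evaluate_out_of_sample(fx$model, np, truth = truth)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$false_positive, rep$detected)
})
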