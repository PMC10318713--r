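test_that("decay transform: closed forms, monotonicity, domain", {
  expect_equal(decay_transform(0), 1.0)
  expect_equal(decay_transform(500, range = 500), exp(-3))
  expect_lt(decay_transform(5000), 1e-12)
  d <- sort(runif(200, 0, 3000))
  expect_true(all(diff(decay_transform(d)) < 0))
  expect_error(decay_transform(-1), "non-negative")
})

test_that("landscape simulation is deterministic with coherent distance layers", {
  a <- simulate_landscape(extent = c(0, 5000, 0, 4000), resolution = 100,
                          seed = 91)
  b <- simulate_landscape(extent = c(0, 5000, 0, 4000), resolution = 100,
                          seed = 91)
  expect_identical(a$layers, b$layers)
  expect_error(simulate_landscape(extent = c(0, 500, 0, 500)), "1 km")

  # distance layer is ~0 on the feature itself (within one cell)
  verts <- a$features$road
  inside <- verts[, 1] > 0 & verts[, 1] < 5000 & verts[, 2] > 0 & verts[, 2] < 4000
  pts <- tibble::tibble(x = verts[inside, 1], y = verts[inside, 2])
  got <- extract_covariates(a, pts, "dist_road")$dist_road
  expect_true(all(got <= a$resolution))

  # brute-force check at 100 sampled cells: min distance over a 1 m
  # discretization of every road segment
  dense <- do.call(rbind, lapply(seq_len(nrow(verts) - 1), function(k) {
    p1 <- verts[k, ]; p2 <- verts[k + 1, ]
    s <- seq(0, 1, length.out = max(2, ceiling(sqrt(sum((p2 - p1)^2)))))
    cbind(p1[1] + s * (p2[1] - p1[1]), p1[2] + s * (p2[2] - p1[2]))
  }))
  set.seed(92)
  ix <- sample(a$nx, 100, replace = TRUE)
  iy <- sample(a$ny, 100, replace = TRUE)
  cx <- a$extent[1] + (ix - 0.5) * a$resolution
  cy <- a$extent[3] + (iy - 0.5) * a$resolution
  brute <- vapply(seq_len(100), function(q)
    min(sqrt((dense[, 1] - cx[q])^2 + (dense[, 2] - cy[q])^2)), numeric(1))
  expect_true(all(abs(a$layers$dist_road[cbind(iy, ix)] - brute) <=
                    a$resolution / 2))
})

test_that("covariate extraction matches a point-in-cell lookup and flags outsiders", {
  stk <- simulate_landscape(seed = 93)
  set.seed(94)
  pts <- tibble::tibble(x = runif(100, 0, 10000), y = runif(100, 0, 10000))
  got <- extract_covariates(stk, pts, "elevation")$elevation
  want <- vapply(seq_len(100), function(i) {
    jx <- floor(pts$x[i] / 100) + 1
    iy <- floor(pts$y[i] / 100) + 1
    stk$layers$elevation[iy, jx]
  }, numeric(1))
  expect_identical(got, want)
  expect_error(
    extract_covariates(stk, tibble::tibble(x = -5, y = 50)),
    "outside the raster extent")
})

test_that("selection-weighted sampling recovers uniformity and direction", {
  stk <- simulate_landscape(seed = 95)
  # all betas zero: used-point covariate mean ~ domain mean
  p0 <- simulate_selected_points(stk, c(elevation = 0), 5000, seed = 96)
  v0 <- extract_covariates(stk, p0, "elevation")$elevation
  expect_lt(abs(mean(v0) - mean(stk$layers$elevation)) /
              sd(stk$layers$elevation), 0.1)
  # strong positive beta shifts the mean up
  p2 <- simulate_selected_points(stk, c(elevation = 2), 2000, seed = 97)
  v2 <- extract_covariates(stk, p2, "elevation")$elevation
  expect_gt(mean(v2), mean(stk$layers$elevation) + 0.5 * sd(stk$layers$elevation))
  # determinism
  p2b <- simulate_selected_points(stk, c(elevation = 2), 2000, seed = 97)
  expect_identical(p2, p2b)
})

test_that("LSD tables split pre/post windows and standardize covariates", {
  stk <- simulate_landscape(extent = c(-20000, 20000, -20000, 20000),
                            resolution = 200, seed = 98)
  cfg <- sim_config(seed = 99,
                    event_time = as.POSIXct("2022-06-15", tz = "UTC"))
  sim <- simulate_ewe(cfg, animal_id = "P01")
  cfg2 <- sim_config(seed = 100,
                     event_time = as.POSIXct("2022-06-10", tz = "UTC"))
  sim2 <- simulate_ewe(cfg2, animal_id = "P02")
  traj <- dplyr::bind_rows(sim$trajectory, sim2$trajectory)
  calls <- tibble::tibble(
    animal_id = c("P01", "P02"), detected = TRUE,
    lambing_datetime = as.POSIXct(c("2022-06-15", "2022-06-10"), tz = "UTC"))
  tbl <- build_lsd_table(traj, calls, stk)
  # 15 d x 12 fixes/day on each side per animal
  expect_equal(sum(tbl$response == 0), 2 * 180)
  expect_equal(sum(tbl$response == 1), 2 * 180)
  covs <- setdiff(names(tbl), c("response", "animal_id", "timestamp", "x", "y"))
  for (cc in covs) {
    expect_lt(abs(mean(tbl[[cc]])), 1e-10)
    expect_lt(abs(sd(tbl[[cc]]) - 1), 1e-10)
  }
  # a call at the very start of the track leaves no prepartum rows
  calls3 <- tibble::tibble(animal_id = "P01", detected = TRUE,
                           lambing_datetime = sim$trajectory$timestamp[1])
  tbl3 <- build_lsd_table(sim$trajectory, calls3, stk)
  expect_true("P01" %in% attr(tbl3, "unbalanced_animals"))
  expect_equal(sum(tbl3$response == 0), 0)
})

test_that("RSF tables honour the availability ratio and the pooled MCP", {
  stk <- simulate_landscape(seed = 103)
  set.seed(104)
  used <- tibble::tibble(
    animal_id = rep(c("A", "B", "C"), each = 40),
    timestamp = as.POSIXct("2022-06-01", tz = "UTC") + 7200 * (1:120),
    x = runif(120, 2000, 8000), y = runif(120, 2000, 8000))
  tbl <- build_rsf_table(used, stk, ratio = 10, seed = 105,
                         standardize = FALSE)
  expect_equal(sum(tbl$response == 0), 1200)
  expect_equal(sum(tbl$response == 1), 120)
  # per-animal allocation of available points
  expect_true(all(table(tbl$animal_id[tbl$response == 0]) == 400))

  # all available points fall inside the pooled MCP polygon
  hr <- attr(tbl, "home_range")
  av <- tbl[tbl$response == 0, ]
  expect_true(all(sp::point.in.polygon(av$x, av$y, hr$x, hr$y) > 0))
  # seeded determinism
  tbl2 <- build_rsf_table(used, stk, ratio = 10, seed = 105,
                          standardize = FALSE)
  expect_equal(tbl, tbl2, ignore_attr = TRUE)

  # with a large ratio, the available-point mean of a covariate approaches
  # the polygon-integrated mean
  tbl_big <- build_rsf_table(used, stk, ratio = 30, seed = 106,
                             standardize = FALSE)
  avail <- tbl_big[tbl_big$response == 0, ]
  cc <- lambwatch:::cell_centers(stk)
  grid <- expand.grid(y = cc$y, x = cc$x)
  inside <- sp::point.in.polygon(grid$x, grid$y, hr$x, hr$y) > 0
  pool_mean <- mean(stk$layers$elevation[inside])
  expect_lt(abs(mean(avail$elevation) - pool_mean), 0.1)
})

test_that("the mixed logistic fitter is symmetric, handles zero variance, flags separation", {
  tbl <- make_glmm_table(8, 60, c(c1 = 1, c2 = -0.5), sigma = 0.4, seed = 107)
  f1 <- fit_random_intercept_logistic(tbl)
  tbl_flip <- dplyr::mutate(tbl, response = 1L - response)
  f2 <- fit_random_intercept_logistic(tbl_flip)
  expect_equal(tidy(f1)$estimate, -tidy(f2)$estimate, tolerance = 1e-3)

  # zero simulated animal variance: matches plain logistic regression
  tbl0 <- make_glmm_table(10, 80, c(c1 = 0.8, c2 = -0.8), sigma = 0, seed = 108)
  f0 <- fit_random_intercept_logistic(tbl0)
  g0 <- stats::glm(response ~ c1 + c2, data = tbl0, family = binomial())
  expect_lt(f0$sigma_animal, 0.05)
  expect_equal(tidy(f0)$estimate, unname(coef(g0)), tolerance = 1e-3)

  # complete separation on one covariate is reported by name
  sep <- make_glmm_table(6, 40, c(c1 = 0.5), sigma = 0.3, seed = 109)
  sep$c_sep <- ifelse(sep$response == 1, 1, -1) * runif(nrow(sep), 0.5, 1)
  expect_error(suppressWarnings(fit_random_intercept_logistic(sep)), "c_sep")
})

test_that("selection comparison is reflexive, order-invariant and roster-checked", {
  tbl <- make_glmm_table(8, 50, c(c1 = 1, c2 = -1), sigma = 0.3, seed = 110)
  f <- fit_random_intercept_logistic(tbl)
  self <- compare_selection(f, f)
  expect_true(all(self$difference == 0))
  expect_true(all(self$ci_overlap))

  tbl_re <- tbl[, c("response", "animal_id", "c2", "c1")]
  f_re <- fit_random_intercept_logistic(tbl_re)
  cmp1 <- compare_selection(f, f_re)
  expect_equal(cmp1$term, sort(cmp1$term))
  expect_equal(cmp1$estimate_a, cmp1$estimate_b, tolerance = 1e-4)

  tbl_other <- dplyr::rename(tbl, c3 = c2)
  f_other <- fit_random_intercept_logistic(tbl_other)
  expect_error(compare_selection(f, f_other), "roster")
})
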