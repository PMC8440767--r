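test_that("the generator is deterministic under a fixed seed", {
  sc <- scenario(n_rows = 40, n_cols = 40, cadence = "monthly",
                 period = c("2000-01-01", "2004-12-31"),
                 n_grove_clusters = 2, groves_per_cluster = 2, seed = 9)
  a <- quiet_scene(sc); b <- quiet_scene(sc)
  expect_identical(a$stack$values, b$stack$values)
  expect_identical(a$groves$polygons, b$groves$polygons)
  expect_identical(a$mask$agricultural, b$mask$agricultural)
  expect_identical(a$truth, b$truth)

  sc2 <- scenario(n_rows = 40, n_cols = 40, cadence = "monthly",
                  period = c("2000-01-01", "2004-12-31"),
                  n_grove_clusters = 2, groves_per_cluster = 2, seed = 10)
  expect_false(identical(quiet_scene(sc2)$stack$values, a$stack$values))
})

test_that("a single grove with fixed area is a ~53 m rectangle of 0.285 ha", {
  sc <- scenario(n_grove_clusters = 1, groves_per_cluster = 1,
                 grove_area_sdlog = 0, seed = 21)
  gs <- generate_groves(sc)
  expect_length(gs, 1)
  expect_equal(gs$area_ha, 0.285, tolerance = 1e-9)
  side <- sqrt(rowSums((gs$polygons[[1]][[1]][2, , drop = FALSE] -
                          gs$polygons[[1]][[1]][1, , drop = FALSE])^2))
  expect_gt(side, 53.4 / 1.3); expect_lt(side, 53.4 * 1.3)
  expect_length(generate_groves(scenario(n_grove_clusters = 0))$polygons, 0)
})

test_that("generated grove areas are log-normal around the 0.285 ha median", {
  sc <- scenario(n_grove_clusters = 10, groves_per_cluster = 20, seed = 22)
  gs <- generate_groves(sc)
  med <- median(gs$area_ha)
  expect_gt(med, 0.285 * 0.8); expect_lt(med, 0.285 / 0.8)
  # clustered placement: mean nearest-neighbour distance far below a
  # uniform scattering of the same intensity
  ctr <- t(vapply(gs$polygons, function(p) colMeans(p[[1]]), numeric(2)))
  nn <- vapply(seq_len(nrow(ctr)), function(i) {
    d <- sqrt((ctr[i, 1] - ctr[-i, 1])^2 + (ctr[i, 2] - ctr[-i, 2])^2)
    min(d)
  }, numeric(1))
  expect_lt(mean(nn), 0.5 * 0.5 / sqrt(nrow(ctr) / (6000 * 6000)))
})

test_that("planted slope follows the truncated exponential decay exactly", {
  sc <- scenario(n_rows = 80, n_cols = 80, cadence = "monthly",
                 period = c("2000-01-01", "2001-12-31"),
                 n_grove_clusters = 1, groves_per_cluster = 1,
                 decay_length_m = 150, spill_range_m = 360, seed = 23)
  scene <- quiet_scene(sc)
  tr <- scene$truth
  fin <- is.finite(tr$dist_m)
  expect_equal(tr$planted_slope[fin],
               sc$grove_effect_size * exp(-tr$dist_m[fin] / 150),
               tolerance = 1e-12)
  # at ~300 m the planted slope has decayed to ~e^-2 of the at-grove slope
  at_grove <- tr$planted_slope[which(tr$dist_m == 0)[1]]
  near300 <- which.min(abs(tr$dist_m - 300))
  expect_lt(abs(tr$dist_m[near300] - 300), 25)
  expect_equal(tr$planted_slope[near300] / at_grove,
               exp(-tr$dist_m[near300] / 150), tolerance = 1e-12)
  expect_equal(exp(-300 / 150), 0.1353, tolerance = 1e-3)
  expect_true(all(tr$planted_slope[!fin] == 0))
  expect_true(all(tr$dist_m[tr$grove] == 0))
  # beyond the planted spill range the effect is exactly zero
  expect_true(all(is.infinite(tr$dist_m[tr$dist_m > 360])))
})

test_that("a null scene yields constant smoothed series and tau in {0, NA}", {
  sc <- scenario(n_rows = 20, n_cols = 20, cadence = "monthly",
                 period = c("2000-01-01", "2004-12-31"),
                 n_grove_clusters = 1, groves_per_cluster = 1,
                 grove_effect_size = 0, background_slope_mean = 0,
                 background_slope_sd = 0, noise_sd = 0, missing_rate = 0,
                 stripe_width = 0, seed = 24)
  scene <- quiet_scene(sc)
  sm <- preprocess_stack(scene$stack, period = c("2000-01-01", "2004-12-31"))
  expect_lt(diff(range(sm$values)), 1e-12)
  tm <- trend_map(sm, min_points = 24)
  expect_true(all(is.na(tm$tau) | tm$tau == 0))
})

test_that("scan-line stripes appear only after the failure date", {
  sc <- scenario(n_rows = 30, n_cols = 30, cadence = "monthly",
                 period = c("2002-01-01", "2004-12-31"),
                 n_grove_clusters = 1, groves_per_cluster = 1,
                 missing_rate = 0, stripe_start = "2003-06-01", seed = 25)
  scene <- quiet_scene(sc)
  st <- scene$stack
  pre <- st$dates < as.Date("2003-06-01")
  expect_false(anyNA(st$values[, pre]))
  post <- which(!pre)
  frac_missing <- colMeans(is.na(st$values[, post]))
  expect_true(all(frac_missing > 0.05 & frac_missing < 0.3))
  # missingness is organised in whole columns of the scene
  k <- post[1]
  miss_cells <- which(is.na(st$values[, k]))
  cols <- unique((miss_cells - 1L) %/% 30L + 1L)
  expect_identical(sort(miss_cells),
                   sort(as.integer(outer(1:30, (cols - 1L) * 30L, `+`))))
})

test_that("masks respect the non-agricultural fraction and stay clear of groves", {
  sc0 <- scenario(n_rows = 40, n_cols = 40, non_agri_fraction = 0, seed = 26)
  m0 <- generate_masks(sc0, generate_groves(sc0))
  expect_true(all(m0$agricultural))

  sc1 <- scenario(n_rows = 40, n_cols = 40, n_grove_clusters = 1,
                  groves_per_cluster = 2, cluster_radius_m = 60,
                  non_agri_fraction = 0.15, seed = 27)
  g1 <- generate_groves(sc1)
  m1 <- generate_masks(sc1, g1)
  expect_lt(abs(mean(!m1$agricultural) - 0.15), 0.02)
  gpx <- grove_pixels(g1, m1$grid)
  expect_false(any(gpx & !m1$agricultural))
})

test_that("grove pixels green faster than the wider landscape (end-to-end)", {
  ok <- logical(20)
  for (i in seq_along(ok)) {
    fit <- run_scene_fit(desk_scenario(seed = 400 + i))
    ok[i] <- fit$ttests$grove_vs_other$t > 0 &&
      fit$greening$grove$strict > fit$greening$other_agri$strict
  }
  expect_true(all(ok))
})

test_that("a larger planted effect never yields fewer significant rings", {
  count_sig <- function(effect, seed) {
    sc <- scenario(n_rows = 120, n_cols = 120, cadence = "monthly",
                   n_grove_clusters = 3, groves_per_cluster = 5,
                   grove_effect_size = effect, seed = seed)
    fit <- run_scene_fit(sc)
    sum(fit$tests$significant[1:12], na.rm = TRUE)
  }
  for (seed in c(81, 82)) {
    n_sig <- vapply(c(0.02, 0.05, 0.08, 0.12, 0.15), count_sig, numeric(1),
                    seed = seed)
    expect_true(all(diff(n_sig) >= 0))
  }
})

test_that("ring-profile deltas decay monotonically with distance on average", {
  deltas <- matrix(NA_real_, 10, 17)
  for (i in 1:10) {
    fit <- run_scene_fit(desk_scenario(seed = 500 + i))
    deltas[i, ] <- fit$tests$delta
  }
  avg <- colMeans(deltas)
  upto <- 12  # planted spill range 360 m
  expect_true(all(diff(avg[1:upto]) < 0))
  expect_lt(max(abs(avg[13:17])), 0.05)
})
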