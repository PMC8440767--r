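test_that("Welch t-test matches the textbook formula and handles degeneracy", {
  set.seed(301)
  a <- rnorm(30, 0.1, 0.2); b <- rnorm(30, 0.0, 0.05)
  got <- class_ttest(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)

  same <- class_ttest(rep(0.3, 5), rep(0.3, 4))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  sep <- class_ttest(rep(0, 4), rep(1, 4))
  expect_equal(sep$p, 0); expect_true(is.infinite(sep$t) && sep$t < 0)
  expect_error(class_ttest(1, c(1, 2)), "at least two")
})

test_that("ring profile reports mean, SE and n per distance class", {
  sc <- fake_scene(list(grove = c(0.5, 0.7), ring_1 = c(0.1, 0.3),
                        ring_2 = rep(0.4, 4), ring_3 = numeric(0)), K = 3)
  expect_warning(prof <- ring_profile(sc$trend, sc$classes), "ring_3")
  expect_equal(prof$distance_m, c(0, 30, 60))
  expect_equal(prof$mean_tau, c(0.6, 0.2, 0.4))
  expect_equal(prof$se[2], 0.1)      # sd(0.1,0.3)/sqrt(2)
  expect_equal(prof$se[3], 0)        # constant ring
  expect_equal(prof$n, c(2L, 2L, 4L))
})

test_that("asymptote is the mean of the three outermost ring means", {
  prof <- data.frame(distance_m = c(450, 480, 510),
                     mean_tau = c(0.10, 0.12, 0.11),
                     se = c(0.01, 0.01, 0.01), n = c(10, 10, 10))
  expect_equal(estimate_asymptote(prof)$asymptote, 0.11)
  prof$mean_tau <- c(0.2, 0.2, 0.2)
  expect_equal(estimate_asymptote(prof)$asymptote, 0.2)
  prof$mean_tau <- c(0, 0, 0.3)
  expect_equal(estimate_asymptote(prof)$asymptote, 0.1)
  expect_error(estimate_asymptote(prof[1:2, ]), "510")
})

test_that("regression coefficients equal ring mean minus asymptote (closed form = lm)", {
  set.seed(302)
  taus <- c(list(grove = rnorm(40, 0.5, 0.1)),
            setNames(lapply(1:17, function(k)
              rnorm(sample(20:60, 1), 0.3 * exp(-k / 5), 0.1)),
              paste0("ring_", 1:17)))
  sc <- fake_scene(taus)
  prof <- ring_profile(sc$trend, sc$classes)
  asym <- estimate_asymptote(prof)
  tests <- asymptote_regression(sc$trend, sc$classes, asym)
  means <- vapply(1:17, function(k) mean(taus[[paste0("ring_", k)]]),
                  numeric(1))
  expect_equal(tests$delta, means - asym$asymptote, tolerance = 1e-10)
  expect_equal(unname(coef(structure(list(tests = tests),
                                     class = "spillover_fit"))),
               means - asym$asymptote, tolerance = 1e-10)

  # explicit no-intercept least squares on ring indicators agrees
  y <- unlist(taus[-1]) - asym$asymptote
  ringfac <- factor(rep(paste0("ring_", 1:17), lengths(taus[-1])),
                    levels = paste0("ring_", 1:17))
  fit <- lm(y ~ ringfac + 0)
  expect_equal(unname(coef(fit)), tests$delta, tolerance = 1e-10)
})

test_that("fixed-asymptote ring tests are exactly one-sample t-tests", {
  set.seed(303)
  for (rep in 1:100) {
    K <- 6
    taus <- setNames(lapply(1:K, function(k)
      rnorm(sample(3:40, 1), rnorm(1, 0.2, 0.1), runif(1, 0.02, 0.2))),
      paste0("ring_", 1:K))
    sc <- fake_scene(c(list(grove = rnorm(10, 0.5, 0.1)), taus))
    a0 <- runif(1, 0, 0.3)
    tests <- asymptote_regression(sc$trend, sc$classes, a0,
                                  se_method = "fixed")
    for (k in 1:K) {
      tt <- t.test(taus[[k]], mu = a0)
      expect_equal(tests$statistic[k], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(tests$p_value[k], tt$p.value, tolerance = 1e-12)
      expect_identical(tests$significant[k], tt$p.value < 0.05)
    }
  }
})

test_that("propagated-asymptote tests match a direct two-component computation", {
  set.seed(304)
  for (rep in 1:30) {
    K <- 17
    taus <- setNames(lapply(1:K, function(k)
      rnorm(sample(5:50, 1), 0.3 * exp(-k / 4) + 0.05, 0.1)),
      paste0("ring_", 1:K))
    sc <- fake_scene(c(list(grove = rnorm(10, 0.5, 0.1)), taus))
    prof <- ring_profile(sc$trend, sc$classes)
    asym <- estimate_asymptote(prof)
    tests <- asymptote_regression(sc$trend, sc$classes, asym)
    for (k in sample(1:K, 5)) {
      x <- taus[[k]]
      se <- sqrt(var(x) / length(x) + asym$se^2)
      stat <- (mean(x) - asym$asymptote) / se
      p <- 2 * pt(-abs(stat), length(x) - 1)
      expect_equal(tests$statistic[k], stat, tolerance = 1e-12)
      expect_equal(tests$p_value[k], p, tolerance = 1e-12)
    }
  }
})

test_that("a strongly offset ring is significant; identical-to-asymptote rings are not", {
  set.seed(305)
  taus <- setNames(lapply(1:17, function(k) rep(0.2, 50)), paste0("ring_", 1:17))
  sc <- fake_scene(c(list(grove = rep(0.5, 10)), taus))
  tests <- asymptote_regression(sc$trend, sc$classes, 0.2, se_method = "fixed")
  expect_true(all(tests$delta == 0))
  expect_false(any(tests$significant))

  taus$ring_2 <- rnorm(500, 0.4, 0.001)
  sc2 <- fake_scene(c(list(grove = rep(0.5, 10)), taus))
  tests2 <- asymptote_regression(sc2$trend, sc2$classes, 0.2,
                                 se_method = "fixed")
  expect_true(tests2$significant[2])

  # a ring with a single pixel is flagged untestable
  taus$ring_5 <- 0.3
  sc3 <- fake_scene(c(list(grove = rep(0.5, 10)), taus))
  tests3 <- asymptote_regression(sc3$trend, sc3$classes, 0.2)
  expect_false(tests3$testable[5])
  expect_true(is.na(tests3$significant[5]))
})

test_that("spill-over distance follows the first-nonsignificant-ring rule", {
  mk <- function(sig) data.frame(distance_m = seq_len(length(sig)) * 30,
                                 testable = TRUE, significant = sig)
  # significant through 360 m, background from 390 m
  d <- spillover_distance(mk(c(rep(TRUE, 12), FALSE, rep(c(FALSE, TRUE), 2))))
  expect_equal(d$spill_distance_m, 360)
  expect_equal(d$background_distance_m, 390)
  expect_false(d$censored)

  d0 <- spillover_distance(mk(c(FALSE, rep(TRUE, 16))))
  expect_equal(d0$spill_distance_m, 0)
  expect_equal(d0$background_distance_m, 30)

  dc <- spillover_distance(mk(rep(TRUE, 17)))
  expect_equal(dc$spill_distance_m, 510)
  expect_equal(dc$background_distance_m, 540)
  expect_true(dc$censored)

  # an isolated far significance does not extend the spill-over
  di <- spillover_distance(mk(c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 13))))
  expect_equal(di$spill_distance_m, 60)
})

test_that("influence summary reproduces the area roll-up arithmetic", {
  # the reported landscape accounting: groves + immediate ring + extended
  areas <- c(grove = 27198, ring_1 = 27750,
             setNames(rep(234720 / 11, 11), paste0("ring_", 2:12)),
             setNames(rep(999, 5), paste0("ring_", 13:17)))
  s <- influence_summary(areas, spill_distance_m = 360)
  expect_equal(s$grove_ha, 27198)
  expect_equal(s$immediate_ha, 27750)
  expect_equal(s$extended_ha, 234720)
  expect_equal(s$total_ha, 289668)

  s0 <- influence_summary(areas, spill_distance_m = 0)
  expect_equal(s0$total_ha, 27198)

  # one isolated grove pixel with spill 30 m: 0.09 + 8 x 0.09 ha
  g <- grid_spec(7, 7)
  grove <- logical(49); grove[cell_index(g, 4L, 4L)] <- TRUE
  mask <- study_mask(g, rep(TRUE, 49), rep(TRUE, 49))
  pc <- classify_pixels(grove, NULL, mask, K = 2)
  s1 <- influence_summary(pc, spill_distance_m = 30)
  expect_equal(s1$total_ha, 0.81)
})

test_that("spillover_fit assembles profile, tests, distance and areas coherently", {
  set.seed(306)
  taus <- c(list(grove = rnorm(60, 0.55, 0.05),
                 other_agri = rnorm(400, 0.05, 0.1)),
            setNames(lapply(1:17, function(k)
              rnorm(120, 0.1 + 0.4 * max(0, 1 - k / 10), 0.05)),
              paste0("ring_", 1:17)))
  sc <- fake_scene(taus)
  fit <- spillover_fit(sc$trend, sc$classes)
  expect_s3_class(fit, "spillover_fit")
  expect_equal(fit$influence$total_ha,
               fit$influence$grove_ha + fit$influence$immediate_ha +
                 fit$influence$extended_ha)
  expect_equal(fit$spill$background_distance_m,
               fit$spill$spill_distance_m + 30)
  expect_true(fit$ttests$grove_vs_other$p < 1e-10)
  expect_gt(fit$greening$grove$strict, 0.99)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("spill-over distance", out)))
  expect_true(any(grepl("Per-ring tests", out)))
})
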