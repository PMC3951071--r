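fit_known <- function(a, b = 0) {
  d <- c(2, 6, 12)
  fit_lq(d, lq_means(d, a, b))
}

test_that("isoeffective-dose inversion matches closed forms", {
  f1 <- fit_known(0.1)
  expect_equal(invert_lq(f1, 0.5), -log(0.5) / 0.1, tolerance = 1e-6)
  expect_equal(invert_lq(f1, 1), 0)
  expect_equal(invert_lq(f1, 1.3), 0) # no effect observed -> 0 Gy

  f2 <- fit_known(0.05, 0.01)
  # positive root of 0.01 D^2 + 0.05 D - 0.75 = 0
  expect_equal(invert_lq(f2, exp(-0.75)), 6.513878, tolerance = 1e-5)
})

test_that("inversion round-trips through the curve and is monotone", {
  f <- fit_known(0.07, 0.002)
  for (y in c(0.999, 0.9, 0.5, 0.2, 0.05)) {
    expect_equal(evaluate_lq(f, invert_lq(f, y)), y, tolerance = 1e-10)
  }
  ys <- seq(0.05, 0.99, by = 0.01)
  expect_true(all(diff(invert_lq(f, ys)) < 0)) # strictly decreasing in y
})

test_that("a flat curve cannot be inverted for a real effect", {
  d <- c(2, 6, 12)
  flat <- fit_lq(d, c(1, 1, 1))
  expect_error(invert_lq(flat, 0.5), "cannot produce effect")
  expect_error(invert_lq(fit_known(0.1), -0.2), "positive")
})

test_that("per-animal RBE is isoeffective dose over test dose", {
  ref <- fit_known(0.0693)
  rec <- tibble::tibble(animal_id = "t1", dose_gy = 5, timepoint = "d1",
                        cell_type = "WBC", fraction = 0.5)
  pt <- rbe_per_animal(ref, rec)
  expect_equal(pt$dose_isoeffective, 10.0029, tolerance = 1e-4)
  expect_equal(pt$rbe, pt$dose_isoeffective / 5)
  expect_equal(pt$timepoint_reference, "d1")
})

test_that("test day 4 pairs with reference day 7 by default", {
  ref <- fit_known(0.05)
  rec <- tibble::tibble(animal_id = "t1", dose_gy = 5, timepoint = "d4",
                        cell_type = "WBC", fraction = 0.8)
  pt <- rbe_per_animal(ref, rec)
  expect_equal(pt$timepoint_reference, "d7")
  expect_error(
    rbe_per_animal(ref, dplyr::mutate(rec, timepoint = "pre")),
    "pairing")
})

test_that("scaling the test-arm slope scales every RBE point", {
  a_ref <- 0.04
  ref <- fit_known(a_ref)
  for (k in c(1, 2.5, 3)) {
    doses <- rep(c(5, 7.7, 10), each = 3)
    rec <- tibble::tibble(animal_id = paste0("t", seq_along(doses)),
                          dose_gy = doses, timepoint = "d1",
                          cell_type = "WBC",
                          fraction = exp(-k * a_ref * doses))
    pt <- rbe_per_animal(ref, rec)
    expect_equal(pt$rbe, rep(k, length(doses)), tolerance = 1e-8)
  }
})

test_that("failed inversions are flagged without aborting the batch", {
  d <- c(2, 6, 12)
  flat <- fit_lq(d, c(1, 1, 1))
  rec <- tibble::tibble(animal_id = c("t1", "t2"), dose_gy = 5,
                        timepoint = "d1", cell_type = "WBC",
                        fraction = c(1.2, 0.5))
  pt <- rbe_per_animal(flat, rec)
  expect_equal(pt$ok, c(TRUE, FALSE))
  expect_equal(pt$rbe[1], 0) # fraction above 1: no effect
  expect_match(pt$note[2], "cannot produce effect")
})

test_that("quadratic trend interpolates exact data and saturates 3 doses", {
  d <- rep(c(2, 6, 12), each = 2)
  pts <- tibble::tibble(dose_test = d, rbe = 3 - 0.1 * d)
  tr <- fit_rbe_trend(pts)
  expect_equal(c(tr$c0, tr$c1, tr$c2), c(3, -0.1, 0), tolerance = 1e-10)
  expect_equal(tr$residual_variance, 0, tolerance = 1e-20)

  # 3 distinct doses x 3 replicates: fitted value = per-dose replicate mean
  set.seed(7)
  pts2 <- tibble::tibble(dose_test = rep(c(5, 7.7, 10), each = 3),
                         rbe = 2.5 + rnorm(9, 0, 0.3))
  tr2 <- fit_rbe_trend(pts2)
  tab <- fitted_rbe_with_ci(tr2, c(5, 7.7, 10))
  means <- tapply(pts2$rbe, pts2$dose_test, mean)
  expect_equal(tab$rbe_fitted, as.numeric(means), tolerance = 1e-8)
  expect_true(all(tab$ci_low <= tab$rbe_fitted & tab$rbe_fitted <= tab$ci_high))
})

test_that("trend recovers a flat RBE without spurious curvature", {
  set.seed(21)
  sims <- replicate(200, {
    pts <- tibble::tibble(dose_test = rep(c(5, 7.7, 10), each = 3),
                          rbe = 2.5 + rnorm(9, 0, 0.3))
    tr <- fit_rbe_trend(pts)
    c(tr$c0, tr$c1, tr$c2)
  })
  expect_equal(mean(sims[1, ]), 2.5, tolerance = 0.15)
  expect_lt(abs(mean(sims[2, ])), 0.05)
  expect_lt(abs(mean(sims[3, ])), 0.005)
})

test_that("confidence machinery degrades gracefully", {
  # zero residual variance collapses the interval onto the fit
  pts <- tibble::tibble(dose_test = rep(c(2, 6, 12), 2), rbe = 2)
  tab <- fitted_rbe_with_ci(fit_rbe_trend(pts), c(2, 6, 12))
  expect_equal(tab$ci_low, tab$rbe_fitted, tolerance = 1e-8)
  expect_equal(tab$ci_high, tab$rbe_fitted, tolerance = 1e-8)

  # symmetric non-saturated design: interval narrowest at the design centre
  # (with only 3 distinct doses the quadratic saturates and widths tie)
  set.seed(5)
  pts2 <- tibble::tibble(dose_test = rep(c(4, 6, 8, 10, 12), each = 3),
                         rbe = rnorm(15, 2, 0.2))
  tab2 <- fitted_rbe_with_ci(fit_rbe_trend(pts2), c(4, 8, 12))
  widths <- tab2$ci_high - tab2$ci_low
  expect_lt(widths[2], widths[1])
  expect_lt(widths[2], widths[3])

  # saturated design (df = 0): CIs disabled, not fabricated
  pts3 <- tibble::tibble(dose_test = c(2, 6, 12), rbe = c(2, 2.2, 1.9))
  tr3 <- fit_rbe_trend(pts3)
  expect_false(tr3$ci_enabled)
  expect_true(all(is.na(fitted_rbe_with_ci(tr3, 6)$ci_low)))
})

test_that("average RBE is the mean +/- SEM of the selected endpoints", {
  rows <- tibble::tibble(rbe_fitted = c(2, 3, 4))
  avg <- average_rbe(rows)
  expect_equal(avg$mean, 3)
  expect_equal(avg$sem, 1 / sqrt(3), tolerance = 1e-10) # 0.577
  expect_equal(average_rbe(tibble::tibble(rbe_fitted = c(2, 2)))$sem, 0)
  expect_error(average_rbe(tibble::tibble(rbe_fitted = 2)), "at least 2")
})
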