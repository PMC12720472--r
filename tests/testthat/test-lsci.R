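test_that("spatial contrast handles constant and fully developed speckle", {
  # constant frames have zero variance: masked, not propagated
  fr <- array(1, c(2, 12, 12))
  sc <- spatial_contrast(fr)
  expect_true(all(sc$contrast == 0))
  expect_true(all(is.na(sc$perfusion)))
  # unit-mean exponential intensities (fully developed static speckle): K ~ 1
  set.seed(0)
  fr2 <- array(rexp(2 * 512 * 512), c(2, 512, 512))
  k <- mean(spatial_contrast(fr2)$contrast)
  expect_equal(k, 1.0, tolerance = 0.05)
  expect_error(spatial_contrast(array(1, c(2, 3, 3)), window = 5), "smaller")
})

test_that("delta-CBF traces are baseline-relative ROI averages", {
  # constant perfusion: identically zero
  P <- array(2, c(30, 10, 10))
  t_min <- seq(-5, 24, by = 1)
  roi <- data.frame(y0 = 2, x0 = 2, y1 = 9, x1 = 9)
  tr <- delta_cbf_trace(P, t_min, roi)
  expect_true(all(abs(tr$dcbf_pct) < 1e-9))
  # step to 1.5x at onset: 0 before, +50% after
  P2 <- P; P2[t_min >= 0, , ] <- 3
  tr2 <- delta_cbf_trace(P2, t_min, roi)
  expect_equal(tr2$dcbf_pct[t_min < 0], rep(0, sum(t_min < 0)))
  expect_equal(tr2$dcbf_pct[t_min >= 0], rep(50, sum(t_min >= 0)))
  # two ROIs stepping +30% and +50% pool to +40%
  P3 <- array(2, c(30, 10, 10))
  P3[t_min >= 0, 1:5, ] <- 2.6
  P3[t_min >= 0, 6:10, ] <- 3.0
  rois <- data.frame(y0 = c(1, 6), x0 = 1, y1 = c(5, 10), x1 = 10)
  tr3 <- delta_cbf_trace(P3, t_min, rois)
  expect_equal(mean(tr3$dcbf_pct[t_min > 0]), 40, tolerance = 1e-9)
  expect_error(delta_cbf_trace(P, t_min, roi[0, ]), "at least one ROI")
  expect_error(delta_cbf_trace(P, t_min, data.frame(y0 = 2, x0 = 2, y1 = 99,
                                                    x1 = 9)), "outside")
  expect_error(delta_cbf_trace(P, t_min, roi, baseline_window_min = c(-1, 2)),
               "pre-onset")
})

test_that("traces are invariant to global intensity rescaling of raw frames", {
  prof <- data.frame(t_min = seq(-5, 5, by = 1 / 60),
                     dcbf_pct = ifelse(seq(-5, 5, by = 1 / 60) >= 0, 30, 0))
  st <- simulate_lsci_stack(prof, frame_shape = c(32L, 32L), seed = 3)
  roi <- data.frame(y0 = 4, x0 = 4, y1 = 29, x1 = 29)
  tr1 <- delta_cbf_trace(spatial_contrast(st)$perfusion, st$t_min, roi)
  st$frames <- st$frames * 7.3
  tr2 <- delta_cbf_trace(spatial_contrast(st)$perfusion, st$t_min, roi)
  expect_equal(tr1$dcbf_pct, tr2$dcbf_pct, tolerance = 1e-9)
})

test_that("CVR metrics quantify peak, plateau time and integrated response", {
  t_min <- seq(-5, 20, by = 1 / 60)
  # ideal logistic rise to +60% with midpoint 4 min
  tr <- data.frame(t_min = t_min,
                   dcbf_pct = 60 / (1 + exp(-1.5 * (t_min - 4))))
  m <- cvr_metrics(tr, "dilation")
  expect_equal(m$dcbf_p_pct, 60, tolerance = 1)
  expect_equal(m$t_p_min, 4 + log(19) / 1.5, tolerance = 0.5)
  expect_false(m$t_p_flag)
  expect_gt(m$ir_au, 0)
  # zero trace: zero peak and integral, undefined plateau time
  z <- data.frame(t_min = t_min, dcbf_pct = 0)
  mz <- cvr_metrics(z, "dilation")
  expect_equal(mz$dcbf_p_pct, 0)
  expect_equal(mz$ir_au, 0)
  expect_true(mz$t_p_flag)
  # constriction: -25% step has negative peak and negative integral
  s <- data.frame(t_min = t_min, dcbf_pct = ifelse(t_min >= 0, -25, 0))
  ms <- cvr_metrics(s, "constriction")
  expect_equal(ms$dcbf_p_pct, -25, tolerance = 0.5)
  expect_lt(ms$ir_au, 0)
  expect_error(cvr_metrics(data.frame(t_min = -5:-1, dcbf_pct = 0), "dilation"),
               "post-onset")
})

test_that("plateau time is monotone in the response midpoint", {
  t_min <- seq(-5, 25, by = 1 / 60)
  tps <- vapply(c(3, 5, 7, 9), function(mid) {
    tr <- data.frame(t_min = t_min,
                     dcbf_pct = 50 / (1 + exp(-1.2 * (t_min - mid))))
    cvr_metrics(tr, "dilation")$t_p_min
  }, numeric(1))
  expect_true(all(diff(tps) > 0))
})

test_that("correlation masks isolate stimulus-locked pixels", {
  set.seed(1)
  t_min <- seq(-14, 15, by = 1)
  P <- array(rnorm(30 * 8 * 8), c(30, 8, 8))
  P[t_min >= 1, 1:4, ] <- P[t_min >= 1, 1:4, ] + 5   # clean step response
  msk <- correlation_mask(P, t_min, c(-14, 0), c(1, 15))
  expect_true(all(msk[1:4, ]))
  # white-noise pixels mostly stay out of the mask
  expect_lt(mean(msk[5:8, ]), 0.2)
  # constant stacks produce an empty mask
  expect_true(!any(correlation_mask(array(1, c(30, 8, 8)), t_min,
                                    c(-14, 0), c(1, 15))))
  expect_error(correlation_mask(P, t_min, c(-14, -13.5), c(1, 15)),
               "at least 3 frames")
})
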