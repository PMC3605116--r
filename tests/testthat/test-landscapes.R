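test_that("single-peak landscape is piecewise linear with the peak at h = 0.5", {
  ls <- landscape_single_peak(0.8, 1.2)
  expect_equal(landscape_delta(ls, 0.5), 1.2)
  expect_equal(landscape_delta(ls, 0), 0.8)
  expect_equal(landscape_delta(ls, 1), 0.8)
  expect_equal(landscape_delta(ls, 0.25), 1.0)
  # symmetric about the peak over the whole grid
  d <- landscape_delta(ls)
  expect_equal(d, rev(d))
  expect_equal(which.max(d), 51L)  # bin centre 0.5
  # evaluation is piecewise constant per bin
  expect_equal(landscape_delta(ls, 0.204), landscape_delta(ls, 0.20))
  expect_error(landscape_single_peak(-0.1, 1.2), "growth bounds")
  expect_error(landscape_single_peak(1.2, 0.8), "growth bounds")
  expect_error(landscape_delta(ls, 1.3), "0, 1")
})

test_that("dynamic two-peak landscape is the pointwise max of scheduled peaks", {
  sched <- data.frame(time = c(1e5, 2e5, 3e5), height = c(0.9, 1.1, 1.3))
  ls <- landscape_two_peak(0.8, 1.2, sched, centre2 = 0.8)
  base <- landscape_single_peak(0.8, 1.2)
  # before the first schedule entry: identical to the static single peak
  expect_equal(landscape_delta(ls, t = 0), landscape_delta(base))
  expect_equal(landscape_delta(ls, t = 1e5 - 1), landscape_delta(base))
  # once the second peak exceeds the first, the global max moves to it
  d_late <- landscape_delta(ls, t = 3e5)
  expect_equal(max(d_late), 1.3)
  expect_equal(which.max(d_late), 81L)  # bin centre 0.8
  # pointwise max oracle over the full grid at an intermediate epoch
  grid <- genotype_grid()
  peak2 <- approx(c(0, 0.8, 1), c(0.8, 1.1, 0.8), xout = grid)$y
  expect_equal(landscape_delta(ls, t = 2.5e5),
               pmax(landscape_delta(base), peak2))
  expect_error(
    landscape_two_peak(0.8, 1.2,
                       data.frame(time = c(2, 1), height = c(1, 1.1))),
    "non-decreasing")
  expect_error(
    landscape_two_peak(0.8, 1.2,
                       data.frame(time = c(1, 2), height = c(1.1, 1.0))),
    "non-decreasing")
})

test_that("two_peak_schedule ramps to just above the first peak", {
  sch <- two_peak_schedule(1e6, steps = 10, delta_min = 0.8, delta_max = 1.2)
  expect_equal(nrow(sch), 10L)
  expect_false(is.unsorted(sch$time, strictly = TRUE))
  expect_equal(sch$height[1], 0.8)
  expect_equal(sch$height[10], 1.2 + 0.1 * 0.4)
  expect_lt(max(sch$time), 1e6)
})

test_that("multi-peak landscape follows the block anchor construction", {
  # n = 1: anchors (0, dmin), (1/3, dmax), (2/3, dmin), (1, dmax)
  ls1 <- landscape_multi_peak(1, 0.8, 1.2)
  oracle1 <- approx(c(0, 1/3, 2/3, 1), c(0.8, 1.2, 0.8, 1.2),
                    xout = genotype_grid())$y
  expect_equal(landscape_delta(ls1), oracle1)

  # n = 4: all 13 anchors from the block formula, evaluated by hand
  n <- 4; b_w <- 1 / n; b_h <- (1.2 - 0.8) / n
  x <- 0; y <- 0.8
  for (k in 1:n) {
    x <- c(x, (k - 1) * b_w + c(b_w / 3, 2 * b_w / 3, b_w))
    y <- c(y, 0.8 + (k - 1) * b_h + c(b_h, 0, b_h))
  }
  expect_length(x, 13L)
  ls4 <- landscape_multi_peak(4, 0.8, 1.2)
  expect_equal(landscape_delta(ls4), approx(x, y, xout = genotype_grid())$y)
  expect_equal(range(landscape_delta(ls4)), c(0.8, 1.2))

  # continuity at block boundaries: the boundary value starts the next block
  expect_equal(approx(x, y, xout = b_w)$y, 0.8 + b_h)

  # exactly n interior local maxima plus a maximum at h = 1
  d <- landscape_delta(ls4)
  interior <- sum(d[2:100] > d[1:99] & d[2:100] > d[3:101])
  expect_equal(interior, n)
  expect_gt(d[101], d[100])

  expect_error(landscape_multi_peak(0), "integer")
  expect_error(landscape_multi_peak(2.5), "integer")
})

test_that("rugged-slope landscape is slope plus seeded noise, smoothed", {
  grid <- genotype_grid()
  base <- 0.8 + 0.4 * grid

  # zero amplitude gives the exact linear slope for any span
  for (sp in c(1, 5, 9))
    expect_equal(landscape_delta(landscape_rugged_slope(sp, seed = 1,
                                                        amplitude = 0)),
                 base)

  # span = 1: raw slope + noise, bit-reproducible across calls
  a <- landscape_rugged_slope(1, seed = 42)
  b <- landscape_rugged_slope(1, seed = 42)
  expect_identical(landscape_delta(a), landscape_delta(b))
  noise <- landscape_delta(a) - base
  expect_true(all(abs(noise) <= 0.1))  # peak-to-peak amplitude 0.2
  expect_gt(sd(noise), 0)

  # hand-computed moving average oracle for span = 5 (edge windows shrink
  # symmetrically so the window stays centred)
  set.seed(42)
  raw <- base + runif(101, -0.1, 0.1)
  sm <- vapply(1:101, function(i) {
    w <- min(2, i - 1, 101 - i)
    mean(raw[(i - w):(i + w)])
  }, numeric(1))
  expect_equal(landscape_delta(landscape_rugged_slope(5, seed = 42)), sm)

  # construction does not disturb the caller's RNG stream
  set.seed(7); u1 <- runif(1)
  set.seed(7); invisible(landscape_rugged_slope(3, seed = 99)); u2 <- runif(1)
  expect_identical(u1, u2)

  expect_error(landscape_rugged_slope(4, seed = 1), "odd")
  expect_error(landscape_rugged_slope(5, seed = 1, amplitude = -1),
               "non-negative")
})

test_that("rugged-slope smoothing is variance-reducing in span", {
  grid <- genotype_grid()
  base <- 0.8 + 0.4 * grid
  spans <- c(1, 3, 5, 7, 9)
  v <- sapply(1:20, function(sd) {
    sapply(spans, function(sp) {
      var(landscape_delta(landscape_rugged_slope(sp, seed = sd)) - base)
    })
  })
  mean_v <- rowMeans(v)
  expect_true(all(diff(mean_v) < 0))
})

test_that("genotype-phenotype mapping is the identity plus landscape lookup", {
  ls <- landscape_single_peak()
  expect_equal(genotype_phenotype(0.2, "host", ls),
               list(h_hat = 0.2, delta = 0.96))
  expect_equal(genotype_phenotype(0.5, "host", ls)$delta, 1.2)
  expect_equal(genotype_phenotype(0.2, "phage"), list(v_hat = 0.2))
  expect_error(genotype_phenotype(1.2, "host", ls), "0, 1")
  expect_error(genotype_phenotype(-0.1, "phage"), "0, 1")
})

test_that("landscapes export as two-column tables", {
  df <- as.data.frame(landscape_single_peak())
  expect_named(df, c("h", "delta"))
  expect_equal(nrow(df), 101L)
  expect_equal(df$delta[df$h == 0.5], 1.2)
})
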