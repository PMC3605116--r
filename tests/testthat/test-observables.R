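test_that("fitness fields agree with the dynamics at occupied bins", {
  p <- bench_params()
  ls <- landscape_single_peak()
  st <- toy_state()
  ff <- fitness_field(st, p, ls)
  d <- state_derivatives(st, p, ls)
  for (i in which(st$N > 0))
    expect_equal(ff$host_net[i] * st$N[i], d$dN[i], tolerance = 1e-12)
  for (j in which(st$V > 0))
    expect_equal(ff$phage_net[j] * st$V[j], d$dV[j], tolerance = 1e-12)
  # growth/lysis decomposition reassembles the net rate
  expect_equal(ff$host_net, -p$omega + ff$host_growth - ff$host_lysis)
})

test_that("fitness field zeros and washout limits are analytic", {
  p <- bench_params()
  ls <- landscape_single_peak()
  # no phage: a genotype at R = Rbar(delta_x) has zero net host rate
  st <- community_state(rbar(1.2, p), hosts = data.frame(h = 0.2, N = 1e3))
  ff <- fitness_field(st, p, ls)
  expect_equal(ff$host_net[51], 0, tolerance = 1e-12)  # h = 0.5, delta 1.2
  # phage genotype far from all hosts: pure washout
  st2 <- community_state(2, hosts = data.frame(h = 0.05, N = 1e4))
  ff2 <- fitness_field(st2, p, ls)
  expect_equal(ff2$phage_net[101], -p$omega, tolerance = 1e-6)
})

test_that("growth-lysis correlation matches the brute-force Pearson formula", {
  p <- bench_params()
  ls <- landscape_single_peak()
  st <- community_state(2,
    hosts = data.frame(h = c(0.30, 0.40, 0.50, 0.60, 0.70),
                       N = c(2, 3, 5, 3, 2) * 1e4),
    phages = data.frame(v = c(0.40, 0.55), V = c(2e5, 4e5)))
  out <- growth_lysis_correlation(st, p, ls)
  # independent computation from first principles
  idx <- which(st$N > 0.01 * sum(st$N))
  delta <- landscape_delta(ls)
  g <- delta[idx] * p$gamma * st$R / (st$R + p$K)
  th <- outer(genotype_grid()[idx], c(0.40, 0.55),
              function(h, v) p$phi * exp(-p$s * (h - v)^2))
  l <- as.vector(th %*% c(2e5, 4e5))
  r_hand <- sum((g - mean(g)) * (l - mean(l))) /
    sqrt(sum((g - mean(g))^2) * sum((l - mean(l))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$n, 5L)
  tstat <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(out$p, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-10)
})

test_that("correlation is undefined below three strains or at zero variance", {
  p <- bench_params()
  ls <- landscape_single_peak()
  st2 <- community_state(2, hosts = data.frame(h = c(0.3, 0.5),
                                               N = c(1e4, 1e4)))
  expect_error(growth_lysis_correlation(st2, p, ls), "fewer than 3")
  # no phage at all: every lysis rate is zero -> zero variance
  st3 <- community_state(2, hosts = data.frame(h = c(0.3, 0.4, 0.5),
                                               N = rep(1e4, 3)))
  expect_error(growth_lysis_correlation(st3, p, ls), "zero variance")
})

test_that("genotype range uses the community-fraction threshold", {
  st <- community_state(2, hosts = data.frame(h = c(0.40, 0.50, 0.60),
                                              N = c(1e4, 2e4, 1e4)))
  expect_equal(genotype_range(st), 0.2)
  one <- community_state(2, hosts = data.frame(h = 0.37, N = 5e3))
  expect_equal(genotype_range(one), 0)
  # a strain just below 1% of total is excluded
  tot <- 1e6
  st2 <- community_state(2, hosts = data.frame(
    h = c(0.40, 0.60, 0.90), N = c(0.6 * tot, 0.395 * tot, 0.005 * tot)))
  expect_equal(genotype_range(st2), 0.2)
  expect_error(genotype_range(community_state(2)), "empty")
})

test_that("strain richness counts maximal runs of adjacent occupied bins", {
  expect_equal(strain_richness(community_state(2), "host"), 0L)
  st1 <- community_state(2, hosts = data.frame(h = c(0.20, 0.21, 0.22),
                                               N = rep(10, 3)))
  expect_equal(strain_richness(st1, "host"), 1L)
  st2 <- community_state(2, hosts = data.frame(
    h = c(0.20, 0.21, 0.35, 0.50, 0.51), N = rep(10, 5)))
  expect_equal(strain_richness(st2, "host"), 3L)
  # brute-force run-length oracle on random occupancy patterns
  set.seed(12)
  for (k in 1:10) {
    occ <- sort(sample(0:100, sample(1:30, 1)))
    st <- community_state(2, hosts = data.frame(h = occ / 100, N = 10))
    runs <- sum(diff(c(-10, occ)) > 1)
    expect_equal(strain_richness(st, "host"), runs)
  }
  stp <- community_state(2, phages = data.frame(v = c(0.1, 0.3), V = c(5, 5)))
  expect_equal(strain_richness(stp, "phage"), 2L)
  expect_equal(strain_richness(stp, "host"), 0L)
})

test_that("maximum community growth rate scans the landscape over extant strains", {
  p <- bench_params()
  ls <- landscape_single_peak()
  st <- community_state(2, hosts = data.frame(h = 0.5, N = 1e4))
  mg <- max_growth_rate(st, ls, p)
  expect_equal(mg$delta, 1.2)
  expect_equal(mg$rate, 1.2 * p$gamma)
  # exhaustive scan oracle on a rugged landscape
  lsr <- landscape_rugged_slope(3, seed = 8)
  h <- c(0.12, 0.47, 0.81)
  str <- community_state(2, hosts = data.frame(h = h, N = c(10, 20, 30)))
  expect_equal(max_growth_rate(str, lsr, p)$delta,
               max(landscape_delta(lsr)[genotype_bin(h) + 1]))
  # adding a faster strain cannot decrease the maximum
  st2 <- community_state(2, hosts = data.frame(h = c(0.3, 0.5),
                                               N = c(1e4, 1e4)))
  expect_gte(max_growth_rate(st2, ls, p)$delta,
             max_growth_rate(community_state(2,
               hosts = data.frame(h = 0.3, N = 1e4)), ls, p)$delta)
  expect_error(max_growth_rate(community_state(2), ls, p), "empty")
})

test_that("sample windows partition early, middle, and late samples", {
  p <- bench_params(T_total = 1e5, M_B = 0, M_V = 0)
  tr <- simulate_chemostat(p, landscape_single_peak(), seed = 1,
                           output_stride = 25)
  w <- sample_windows(tr, fraction = 0.05)
  ns <- length(tr$times)
  expect_equal(w$late[length(w$late)], ns)
  expect_equal(w$early[1], 1L)
  expect_true(max(w$early) < min(w$middle))
  expect_true(max(w$middle) < min(w$late))
})
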