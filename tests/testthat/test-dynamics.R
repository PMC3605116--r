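test_that("derivatives vanish at the washout equilibrium and analytic fixed points", {
  p <- bench_params()
  ls <- landscape_single_peak()
  # empty chemostat at supply concentration: nothing changes
  st <- community_state(p$R0)
  d <- state_derivatives(st, p, ls)
  expect_equal(d$dR, 0)
  expect_equal(d$dN, numeric(101))
  expect_equal(d$dV, numeric(101))

  # single host without phage at R = Rbar(delta): dN/dt = 0
  st2 <- community_state(rbar(1.2, p), hosts = data.frame(h = 0.5, N = 1e5))
  d2 <- state_derivatives(st2, p, ls)
  expect_equal(d2$dN[51], 0, tolerance = 1e-12)

  # matched phage with N = omega/(beta theta): dV/dt = 0
  st3 <- community_state(2, hosts = data.frame(h = 0.5, N = nhat(p)),
                         phages = data.frame(v = 0.5, V = 1e6))
  d3 <- state_derivatives(st3, p, ls)
  expect_equal(d3$dV[51], 0, tolerance = 1e-10)

  expect_error(state_derivatives(st, p, ls, theta = matrix(0, 2, 2)),
               "dimensions")
})

test_that("resource uptake equals epsilon times gross host growth, strain by strain", {
  p <- bench_params()
  ls <- landscape_single_peak()
  set.seed(3)
  for (k in 1:5) {
    st <- toy_state(R = runif(1, 0.5, 3),
                    hosts = data.frame(h = round(runif(3), 2),
                                       N = runif(3, 1e3, 1e5)))
    d <- state_derivatives(st, p, ls)
    gross <- p$gamma * st$R * st$N * landscape_delta(ls) / (st$R + p$K)
    uptake_from_dR <- -(d$dR + p$omega * (st$R - p$R0))
    expect_equal(uptake_from_dR, p$eps * sum(gross), tolerance = 1e-12)
    # and the same Monod term appears in dN: dN + omega N + lysis N = gross
    lysis <- as.vector(
      phagecoevo:::dense_theta(p, "gaussian") %*% st$V)
    expect_equal(d$dN + p$omega * st$N + st$N * lysis, gross,
                 tolerance = 1e-12)
  }
})

test_that("RK4 reproduces the closed-form resource relaxation", {
  p <- bench_params()
  ls <- landscape_single_peak()
  st <- community_state(0)  # empty chemostat, R(0) = 0
  for (k in 1:100) st <- rk4_step(st, p, ls)
  expect_equal(st$R, p$R0 * (1 - exp(-p$omega * 1000)), tolerance = 1e-7)
  expect_equal(st$t, 1000)
  # fixed point: zero derivatives leave the state unchanged
  fx <- community_state(p$R0)
  fx2 <- rk4_step(fx, p, ls)
  expect_equal(fx2$R, p$R0)
  expect_equal(fx2$N, fx$N)
})

test_that("one RK4 step matches a fine-step Euler oracle on predator-prey dynamics", {
  p <- bench_params()
  ls <- landscape_single_peak()
  st <- community_state(2, hosts = data.frame(h = 0.5, N = 5e4),
                        phages = data.frame(v = 0.5, V = 1e6))
  after <- rk4_step(st, p, ls, dt = 10)
  # Euler micro-steps as an independent integrator
  R <- st$R; N <- st$N; V <- st$V
  th <- phagecoevo:::dense_theta(p, "gaussian")
  delta <- landscape_delta(ls)
  h <- 10 / 1000
  for (k in 1:1000) {
    up <- p$gamma * R * N * delta / (R + p$K)
    dR <- -p$omega * (R - p$R0) - p$eps * sum(up)
    dN <- -p$omega * N + up - N * as.vector(th %*% V)
    dV <- -p$omega * V + p$beta * V * as.vector(crossprod(th, N))
    R <- R + h * dR; N <- N + h * dN; V <- V + h * dV
  }
  expect_equal(after$R, R, tolerance = 1e-6)
  expect_equal(after$N[51], N[51], tolerance = 1e-5)
  expect_equal(after$V[51], V[51], tolerance = 1e-5)
})

test_that("extinction cull removes populations strictly below one per ml", {
  st <- community_state(2, hosts = data.frame(h = c(0.1, 0.2, 0.3),
                                              N = c(2e3, 0.5, 1.7)),
                        phages = data.frame(v = c(0.1, 0.2),
                                            V = c(0.999, 1.0)))
  out <- cull_extinct(st)
  expect_equal(host_community(out)$N, c(2e3, 1.7))
  expect_equal(phage_community(out)$V, 1.0)  # boundary retained
})

test_that("simulation converges to the analytic equilibria with mutation off", {
  p <- bench_params(M_B = 0, M_V = 0, T_total = 3e5,
                    h_init = 0.5, v_init = 0.5)
  ls <- landscape_single_peak()
  # phage-free: (R, N) -> (Rbar, Nbar) within 0.1%
  tr0 <- simulate_chemostat(update_params(p, V_init = 0), ls, seed = 1)
  fin0 <- state_at(tr0, -1)
  expect_equal(fin0$R, rbar(1.2, p), tolerance = 1e-3)
  expect_equal(sum(fin0$N), nbar(1.2, p), tolerance = 1e-3)
  # with matched phage: N -> Nhat within 1%
  tr1 <- simulate_chemostat(p, ls, seed = 1)
  fin1 <- state_at(tr1, -1)
  expect_equal(sum(fin1$N), nhat(p), tolerance = 1e-2)
  expect_lt(sum(fin1$N), sum(fin0$N))  # phage limit hosts below capacity
  expect_equal(sum(fin1$V), vhat(1.2, p, fin1$R), tolerance = 1e-2)
})

test_that("trajectories are bit-identical under a repeated seed", {
  p <- bench_params(T_total = 5e4)
  ls <- landscape_single_peak()
  a <- simulate_chemostat(p, ls, seed = 11)
  b <- simulate_chemostat(p, ls, seed = 11)
  expect_identical(a$N, b$N)
  expect_identical(a$V, b$V)
  expect_identical(a$R, b$R)
  c <- simulate_chemostat(p, ls, seed = 12)
  expect_false(identical(a$N, c$N))
})

test_that("compiled and reference engines agree step for step", {
  p <- bench_params(T_total = 2e4, M_B = 1e-4, M_V = 1e-4)
  ls <- landscape_single_peak()
  tc <- simulate_chemostat(p, ls, seed = 7, engine = "cpp")
  tr <- simulate_chemostat(p, ls, seed = 7, engine = "r")
  expect_equal(tc$R, tr$R, tolerance = 1e-9)
  expect_equal(tc$N, tr$N, tolerance = 1e-9)
  expect_equal(tc$V, tr$V, tolerance = 1e-9)
  expect_identical(tc$range_edge, tr$range_edge)
  # same strains alive at the end: identical RNG event streams
  expect_identical(which(state_at(tc, -1)$N > 0),
                   which(state_at(tr, -1)$N > 0))
})

test_that("halving the timestep leaves the phage-free benchmark unchanged to 0.1%", {
  p10 <- bench_params(M_B = 0, M_V = 0, V_init = 0, T_total = 2e5, dt = 10)
  p5 <- update_params(p10, dt = 5)
  ls <- landscape_single_peak()
  a <- simulate_chemostat(p10, ls, seed = 1)
  b <- simulate_chemostat(p5, ls, seed = 1)
  fa <- state_at(a, -1); fb <- state_at(b, -1)
  expect_equal(fa$R, fb$R, tolerance = 1e-3)
  expect_equal(sum(fa$N), sum(fb$N), tolerance = 1e-3)
})

test_that("densities and resource stay non-negative through a mutating run", {
  p <- bench_params(T_total = 2e5, M_B = 1e-4, M_V = 1e-4)
  tr <- simulate_chemostat(p, landscape_single_peak(), seed = 3,
                           output_stride = 50)
  expect_true(all(tr$N >= 0))
  expect_true(all(tr$V >= 0))
  expect_true(all(tr$R >= 0))
})

test_that("custom initial communities and tidy export work", {
  p <- bench_params(M_B = 0, M_V = 0, T_total = 1e4)
  ls <- landscape_single_peak()
  init <- list(hosts = data.frame(h = c(0.3, 0.6), N = c(1e4, 2e4)),
               phages = data.frame(v = 0.3, V = 1e5))
  tr <- simulate_chemostat(p, ls, seed = 1, init = init)
  st0 <- state_at(tr, 1)
  expect_equal(host_community(st0)$N, c(1e4, 2e4))
  expect_equal(phage_community(st0)$v, 0.3)
  df <- as.data.frame(tr)
  expect_named(df, c("time", "variable", "genotype_bin", "value"))
  expect_true(all(c("R", "N", "V") %in% df$variable))
  expect_equal(nrow(df[df$variable == "R", ]), length(tr$times))
})

test_that("numerical blow-up raises an informative failure", {
  p <- bench_params(M_B = 0, M_V = 0, V_init = 0, dt = 1e305, T_total = 3e305)
  expect_error(simulate_chemostat(p, landscape_single_peak(), seed = 1),
               "numerical failure")
})
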