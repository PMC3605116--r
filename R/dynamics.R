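#' Ecological derivatives of the multi-strain chemostat
#'
#' Evaluates the right-hand side of the chemostat equations for the
#' current community:
#' \deqn{dR/dt = -\omega(R - R_0) - \sum_i \epsilon \gamma R N_i \delta_i / (R + K)}
#' \deqn{dN_i/dt = -\omega N_i + \gamma R N_i \delta_i / (R + K) - \sum_j \theta_{ij} N_i V_j}
#' \deqn{dV_j/dt = -\omega V_j + \sum_i \beta \theta_{ij} N_i V_j}
#' Resource is supplied at \code{R0} and diluted at \code{omega}; hosts
#' grow by Monod uptake scaled by their landscape factor \eqn{\delta_i}
#' and are lost to washout and lysis; phage are produced with burst size
#' \eqn{\beta} on every host they can adsorb to and are lost to washout.
#'
#' @param state A \code{community_state}.
#' @param params A \code{chemostat_params}.
#' @param landscape A \code{growth_landscape}.
#' @param scheme Infection scheme, \code{"gaussian"} or \code{"strict"}.
#' @param theta Optional precomputed dense adsorption matrix over the
#'   full genotype grid (bins x bins); built from the by-distance kernel
#'   when omitted.
#' @return A list with elements \code{dR}, \code{dN}, \code{dV} (the
#'   latter two dense over the grid).
#' @examples
#' p <- chemostat_params()
#' st <- community_state(p$R0, hosts = data.frame(h = 0.2, N = 1e5))
#' state_derivatives(st, p, landscape_single_peak())$dR
#' @export
state_derivatives <- function(state, params, landscape,
                              scheme = c("gaussian", "strict"),
                              theta = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(theta)) theta <- dense_theta(params, scheme)
  nb <- length(state$N)
  if (!all(dim(theta) == c(nb, nb)))
    stop("theta matrix dimensions do not match the genotype grid",
         call. = FALSE)
  delta <- landscape_delta(landscape, t = state$t)
  rhs_dense(state$R, state$N, state$V, delta, theta, params)
}

# Dense RHS shared by state_derivatives and the R reference engine.
rhs_dense <- function(R, N, V, delta, theta, params) {
  monod <- params$gamma * R / (R + params$K)
  uptake <- monod * N * delta              # gross growth, cells/(ml min)
  lysis <- as.vector(theta %*% V)          # per-capita lysis rate on hosts
  prod <- as.vector(crossprod(theta, N))   # per-capita production on phage
  list(dR = -params$omega * (R - params$R0) - params$eps * sum(uptake),
       dN = -params$omega * N + uptake - N * lysis,
       dV = -params$omega * V + params$beta * V * prod)
}

# Full-grid adsorption matrix from the by-distance kernel.
dense_theta <- function(params, scheme = c("gaussian", "strict")) {
  scheme <- match.arg(scheme)
  nb <- n_bins(params$rho)
  look <- theta_by_distance(params, scheme, nb)
  idx <- seq_len(nb)
  matrix(look[abs(outer(idx, idx, "-")) + 1L], nb, nb)
}

#' One classical Runge-Kutta step of the ecological dynamics
#'
#' Advances resource and all strain densities by one timestep with the
#' classical 4th-order Runge-Kutta update. The strain roster is fixed
#' within the step; mutation and extinction culling are applied between
#' steps by the simulation driver.
#'
#' @inheritParams state_derivatives
#' @param dt Timestep (min); defaults to \code{params$dt}.
#' @return The updated \code{community_state}, with \code{t} advanced.
#' @examples
#' p <- chemostat_params()
#' st <- community_state(p$R0, hosts = data.frame(h = 0.2, N = 1e5))
#' rk4_step(st, p, landscape_single_peak())$R
#' @export
rk4_step <- function(state, params, landscape,
                     scheme = c("gaussian", "strict"),
                     dt = params$dt, theta = NULL) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop_invalid("dt must be positive")
  if (is.null(theta)) theta <- dense_theta(params, scheme)
  delta <- landscape_delta(landscape, t = state$t)
  f <- function(R, N, V) rhs_dense(R, N, V, delta, theta, params)
  k1 <- f(state$R, state$N, state$V)
  k2 <- f(state$R + dt / 2 * k1$dR, state$N + dt / 2 * k1$dN,
          state$V + dt / 2 * k1$dV)
  k3 <- f(state$R + dt / 2 * k2$dR, state$N + dt / 2 * k2$dN,
          state$V + dt / 2 * k2$dV)
  k4 <- f(state$R + dt * k3$dR, state$N + dt * k3$dN, state$V + dt * k3$dV)
  out <- state
  out$R <- state$R + dt / 6 * (k1$dR + 2 * k2$dR + 2 * k3$dR + k4$dR)
  out$N <- state$N + dt / 6 * (k1$dN + 2 * k2$dN + 2 * k3$dN + k4$dN)
  out$V <- state$V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
  out$t <- state$t + dt
  if (!is.finite(out$R))
    stop("numerical failure: non-finite resource concentration R",
         call. = FALSE)
  for (nm in c("N", "V")) {
    bad <- which(!is.finite(out[[nm]]))
    if (length(bad))
      stop(sprintf("numerical failure: non-finite %s density at bin %d",
                   if (nm == "N") "host" else "phage", bad[1] - 1L),
           call. = FALSE)
  }
  out
}

#' Remove extinct strains
#'
#' The ODE densities are continuous, so a failing strain's density decays
#' asymptotically without ever reaching zero. Any host population below
#' 1 cell/ml, or phage population below 1 virion/ml, is assumed lost and
#' removed (strict inequality: a density of exactly 1 is retained).
#'
#' @param state A \code{community_state}.
#' @param threshold Extinction threshold (per ml).
#' @return The culled \code{community_state}.
#' @examples
#' st <- community_state(2, hosts = data.frame(h = c(0.2, 0.5),
#'                                             N = c(2e3, 0.5)))
#' host_community(cull_extinct(st))
#' @export
cull_extinct <- function(state, threshold = 1) {
  state$N[state$N < threshold] <- 0
  state$V[state$V < threshold] <- 0
  state
}

#' Simulate the coevolving chemostat
#'
#' Integrates the eco-evolutionary model forward from a single founding
#' host strain (plus matched phage unless \code{V_init = 0}) or a
#' user-supplied initial community. Each timestep applies, in order: one
#' RK4 step of the ecological dynamics, stochastic mutation (Poisson
#' counts from the instantaneous production rates, normal effect sizes,
#' binned at resolution \code{rho}), and the extinction cull. The run is
#' deterministic given \code{seed}.
#'
#' Mutations that would leave the genotype range [0, 1] are skipped and
#' raise the trajectory's \code{range_edge} flag; ensemble drivers
#' discard flagged runs.
#'
#' @param params A \code{chemostat_params}; \code{params$T_total} and
#'   \code{params$dt} set the horizon unless \code{t_total} is given.
#' @param landscape A \code{growth_landscape}.
#' @param seed Integer seed for the run's RNG stream.
#' @param scheme Infection scheme, \code{"gaussian"} or \code{"strict"}.
#' @param t_total Run duration (min); defaults to \code{params$T_total}.
#' @param output_stride Record every this-many steps (default: about 400
#'   samples per run).
#' @param init Optional initial community: a list with data frames
#'   \code{hosts} (columns \code{h}, \code{N}) and/or \code{phages}
#'   (columns \code{v}, \code{V}), overriding the single-founder default.
#' @param engine \code{"cpp"} (compiled core) or \code{"r"} (pure-R
#'   reference implementation built from \code{rk4_step},
#'   \code{draw_mutations}, \code{apply_mutations}, and
#'   \code{cull_extinct}). Both consume R's RNG stream in the same order
#'   and produce bit-identical trajectories.
#' @return An object of class \code{chemostat_trajectory}: sampled times,
#'   resource series, host and phage density matrices (samples x bins),
#'   the \code{range_edge} flag, and run metadata.
#' @examples
#' p <- chemostat_params(T_total = 2e4)
#' tr <- simulate_chemostat(p, landscape_single_peak(), seed = 1)
#' summary(tr)
#' @export
simulate_chemostat <- function(params, landscape, seed = 1,
                               scheme = c("gaussian", "strict"),
                               t_total = params$T_total,
                               output_stride = NULL, init = NULL,
                               engine = c("cpp", "r")) {
  scheme <- match.arg(scheme)
  engine <- match.arg(engine)
  stopifnot(inherits(params, "chemostat_params"),
            inherits(landscape, "growth_landscape"))
  if (abs(landscape$rho - params$rho) > 1e-12)
    stop_invalid("landscape and params use different genotype resolutions")
  n_steps <- as.integer(round(t_total / params$dt))
  if (n_steps < 1L) stop_invalid("t_total must cover at least one timestep")
  if (is.null(output_stride))
    output_stride <- max(1L, n_steps %/% 400L)
  output_stride <- as.integer(output_stride)

  nb <- n_bins(params$rho)
  N0 <- numeric(nb); V0 <- numeric(nb)
  if (is.null(init)) {
    N0[genotype_bin(params$h_init, params$rho) + 1L] <- params$N_init
    if (params$V_init > 0)
      V0[genotype_bin(params$v_init, params$rho) + 1L] <- params$V_init
  } else {
    st <- community_state(params$R0, init$hosts, init$phages,
                          rho = params$rho)
    N0 <- st$N; V0 <- st$V
  }

  # Landscape epochs tabulated for the engine; epoch k applies from
  # epoch_times[k] (first = -Inf, encoded as a very negative start).
  ep_t <- landscape$epoch_times
  ep_t[!is.finite(ep_t)] <- -1e300
  theta_look <- theta_by_distance(params, scheme, nb)

  set.seed(seed)
  res <- if (engine == "cpp") {
    sim_engine_cpp(params$R0, N0, V0, landscape$delta, ep_t, theta_look,
                   unclass(params), n_steps, output_stride)
  } else {
    sim_engine_r(params$R0, N0, V0, landscape, theta_look, params,
                 n_steps, output_stride, scheme)
  }

  structure(list(times = res$times, R = res$R, N = res$N, V = res$V,
                 range_edge = res$range_edge, params = params,
                 landscape = landscape, scheme = scheme, seed = seed,
                 engine = engine, n_steps = n_steps,
                 output_stride = output_stride),
            class = "chemostat_trajectory")
}

# Pure-R reference engine: the literal composition of the module-surface
# operations, consuming the RNG in the same order as the compiled core.
sim_engine_r <- function(R0, N0, V0, landscape, theta_look, params,
                         n_steps, output_stride, scheme) {
  nb <- length(N0)
  theta <- dense_theta(params, scheme)
  state <- structure(list(t = 0, R = R0, N = N0, V = V0, rho = params$rho),
                     class = "community_state")
  n_samp <- n_steps %/% output_stride + 1L
  times <- numeric(n_samp); Rv <- numeric(n_samp)
  Nm <- matrix(0, n_samp, nb); Vm <- matrix(0, n_samp, nb)
  times[1] <- 0; Rv[1] <- state$R; Nm[1, ] <- state$N; Vm[1, ] <- state$V
  range_edge <- FALSE
  k <- 1L
  for (step in seq_len(n_steps)) {
    state <- rk4_step(state, params, landscape, scheme, theta = theta)
    rates <- expected_mutation_rates(state, params, landscape, scheme,
                                     theta = theta)
    ev <- draw_mutations(rates, params)
    if (attr(ev, "range_edge")) range_edge <- TRUE
    state <- apply_mutations(state, ev, params)
    state <- cull_extinct(state)
    if (step %% output_stride == 0L) {
      k <- k + 1L
      times[k] <- state$t; Rv[k] <- state$R
      Nm[k, ] <- state$N; Vm[k, ] <- state$V
    }
  }
  list(times = times[1:k], R = Rv[1:k], N = Nm[1:k, , drop = FALSE],
       V = Vm[1:k, , drop = FALSE], range_edge = range_edge)
}

#' Extract a community state from a trajectory
#'
#' @param trajectory A \code{chemostat_trajectory}.
#' @param i Sample index (1-based; negative counts from the end, so
#'   \code{i = -1} is the final state).
#' @return A \code{community_state}.
#' @examples
#' p <- chemostat_params(T_total = 1e4)
#' tr <- simulate_chemostat(p, landscape_single_peak(), seed = 1)
#' state_at(tr, -1)
#' @export
state_at <- function(trajectory, i = -1) {
  ns <- length(trajectory$times)
  if (i < 0) i <- ns + 1L + i
  if (i < 1 || i > ns) stop_invalid("sample index out of range")
  structure(list(t = trajectory$times[i], R = trajectory$R[i],
                 N = trajectory$N[i, ], V = trajectory$V[i, ],
                 rho = trajectory$params$rho),
            class = "community_state")
}

#' @export
print.chemostat_trajectory <- function(x, ...) {
  cat(sprintf("Chemostat coevolution trajectory (%s kernel, seed %d)\n",
              x$scheme, x$seed))
  cat(sprintf("  %d steps of dt = %g min (T = %g min), %d samples\n",
              x$n_steps, x$params$dt, x$n_steps * x$params$dt,
              length(x$times)))
  fin <- state_at(x, -1)
  cat(sprintf("  final: R = %.4g; %d host strains (%.4g cells/ml); %d phage strains (%.4g virions/ml)\n",
              fin$R, sum(fin$N > 0), sum(fin$N), sum(fin$V > 0), sum(fin$V)))
  if (x$range_edge)
    cat("  NOTE: genotype range edge reached by mutation (discard flag set)\n")
  invisible(x)
}

#' @export
summary.chemostat_trajectory <- function(object, ...) {
  fin <- state_at(object, -1)
  out <- list(
    t_final = fin$t, R_final = fin$R,
    total_N = sum(fin$N), total_V = sum(fin$V),
    host_bins = sum(fin$N > 0), phage_bins = sum(fin$V > 0),
    host_richness = strain_richness(fin, "host"),
    phage_richness = strain_richness(fin, "phage"),
    range_edge = object$range_edge)
  class(out) <- "summary.chemostat_trajectory"
  out
}

#' @export
print.summary.chemostat_trajectory <- function(x, ...) {
  cat(sprintf("Final state at t = %g min:\n", x$t_final))
  cat(sprintf("  R = %.4g ug/ml; total N = %.4g cells/ml; total V = %.4g virions/ml\n",
              x$R_final, x$total_N, x$total_V))
  cat(sprintf("  host strains: %d (occupied bins %d); phage strains: %d (occupied bins %d)\n",
              x$host_richness, x$host_bins, x$phage_richness, x$phage_bins))
  if (x$range_edge) cat("  range-edge flag set\n")
  invisible(x)
}

#' @export
#' @param row.names,optional Standard method arguments (unused).
#' @rdname simulate_chemostat
as.data.frame.chemostat_trajectory <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  grid <- genotype_grid(x$params$rho)
  ns <- length(x$times)
  res <- data.frame(time = x$times, variable = "R", genotype_bin = NA_real_,
                    value = x$R)
  long <- function(mat, var) {
    occ <- which(mat > 0, arr.ind = TRUE)
    if (nrow(occ) == 0L) return(NULL)
    data.frame(time = x$times[occ[, 1]], variable = var,
               genotype_bin = grid[occ[, 2]], value = mat[occ])
  }
  out <- rbind(res, long(x$N, "N"), long(x$V, "V"))
  out[order(out$time, out$variable, out$genotype_bin), , drop = FALSE]
}

#' @export
plot.chemostat_trajectory <- function(x, what = c("genotypes", "totals"),
                                      ...) {
  what <- match.arg(what)
  grid <- genotype_grid(x$params$rho)
  if (what == "totals") {
    totN <- rowSums(x$N); totV <- rowSums(x$V)
    graphics::matplot(x$times, cbind(totN, totV + 1), type = "l", log = "y",
                      lty = 1, col = c("blue", "red"),
                      xlab = "time (min)", ylab = "density (per ml)", ...)
    graphics::legend("bottomright", c("total bacteria", "total phage"),
                     col = c("blue", "red"), lty = 1, bty = "n")
  } else {
    z <- log10(x$N + 1)
    graphics::image(x$times, grid, z, xlab = "time (min)",
                    ylab = "genotype h",
                    main = "host density log10(N+1)", ...)
  }
  invisible(x)
}
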