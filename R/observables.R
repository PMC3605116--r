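#' Fitness fields over the genotype grid
#'
#' Computes, for every genotype on the grid, the hypothetical per-capita
#' net growth rate a strain of that genotype would experience in the
#' current environment: for hosts
#' \eqn{-\omega + \delta_x \gamma R/(R+K) - \sum_j \theta_{xj} V_j}
#' (washout + growth - lysis, from the host equation), and for phage
#' \eqn{-\omega + \beta \sum_i \theta_{xi} N_i} (washout + production,
#' from the phage equation). The growth and lysis components are
#' reported separately; gradients in these fields are the selection
#' pressures driving adaptation, and at steady state they flatten to
#' zero over the occupied bins.
#'
#' @inheritParams state_derivatives
#' @return A data frame with one row per grid genotype: \code{h},
#'   \code{host_growth}, \code{host_lysis}, \code{host_net},
#'   \code{phage_net} (all per-capita rates, 1/min).
#' @examples
#' p <- chemostat_params()
#' st <- community_state(2, hosts = data.frame(h = 0.2, N = 1e5),
#'                       phages = data.frame(v = 0.2, V = 1e6))
#' ff <- fitness_field(st, p, landscape_single_peak())
#' ff[ff$h == 0.2, ]
#' @export
fitness_field <- function(state, params, landscape,
                          scheme = c("gaussian", "strict"), theta = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(theta)) theta <- dense_theta(params, scheme)
  delta <- landscape_delta(landscape, t = state$t)
  growth <- delta * params$gamma * state$R / (state$R + params$K)
  lysis <- as.vector(theta %*% state$V)
  production <- params$beta * as.vector(crossprod(theta, state$N))
  data.frame(h = genotype_grid(state$rho),
             host_growth = growth,
             host_lysis = lysis,
             host_net = -params$omega + growth - lysis,
             phage_net = -params$omega + production)
}

#' Correlation between growth and lysis rates across host strains
#'
#' Across all host strains above a density threshold, computes the
#' Pearson correlation between per-capita growth rates
#' \eqn{\delta_i \gamma R/(R+K)} and per-capita lysis rates
#' \eqn{\sum_j \theta_{ij} V_j}. Under kill-the-winner dynamics the two
#' are strongly positively correlated: faster-growing strains support
#' more phage and suffer more lysis, and at steady state the balance is
#' exact. Significance uses the standard t-transform of r.
#'
#' @inheritParams state_derivatives
#' @param threshold Minimum strain density as a fraction of total host
#'   density (default 0.01, i.e. strains forming > 1\% of cells).
#' @return A list with \code{r}, \code{p} (two-sided), and \code{n}
#'   (number of qualifying strains).
#' @examples
#' p <- chemostat_params()
#' st <- community_state(2,
#'   hosts = data.frame(h = c(0.2, 0.3, 0.4), N = c(1, 2, 3) * 1e4),
#'   phages = data.frame(v = c(0.25, 0.35), V = c(1e5, 2e5)))
#' growth_lysis_correlation(st, p, landscape_single_peak())
#' @export
growth_lysis_correlation <- function(state, params, landscape,
                                     scheme = c("gaussian", "strict"),
                                     threshold = 0.01, theta = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(theta)) theta <- dense_theta(params, scheme)
  tot <- sum(state$N)
  idx <- which(state$N > threshold * tot & state$N > 0)
  if (length(idx) < 3L)
    stop("correlation undefined: fewer than 3 host strains above threshold",
         call. = FALSE)
  delta <- landscape_delta(landscape, t = state$t)
  growth <- delta[idx] * params$gamma * state$R / (state$R + params$K)
  lysis <- as.vector(theta %*% state$V)[idx]
  if (stats::sd(growth) == 0 || stats::sd(lysis) == 0)
    stop("correlation undefined: zero variance in growth or lysis rates",
         call. = FALSE)
  ct <- stats::cor.test(growth, lysis, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(idx))
}

#' Genotype range of the host community
#'
#' Total range of genotypes (\eqn{h_{max} - h_{min}}) among host strains
#' whose density exceeds \code{threshold} times total host density; the
#' standing-variation measure used in the parameter-sensitivity
#' ensembles.
#'
#' @param state A \code{community_state}.
#' @param threshold Minimum density fraction for a strain to qualify.
#' @return The genotype range (0 for a single qualifying strain).
#' @examples
#' st <- community_state(2, hosts = data.frame(h = c(0.4, 0.5, 0.6),
#'                                             N = c(1e4, 2e4, 1e4)))
#' genotype_range(st)   # 0.2
#' @export
genotype_range <- function(state, threshold = 0.01) {
  tot <- sum(state$N)
  idx <- which(state$N > threshold * tot & state$N > 0)
  if (length(idx) == 0L)
    stop("genotype range undefined for an empty host community",
         call. = FALSE)
  h <- bin_centre(idx - 1L, state$rho)
  max(h) - min(h)
}

#' Strain richness by genotype clustering
#'
#' Counts strains as maximal runs of occupied adjacent genotype bins: a
#' gap of one or more empty bins separates clusters. This operationalises
#' the branching pattern in which a "strain" is a cluster of neighbouring
#' genotypes rather than a single bin.
#'
#' @param state A \code{community_state}.
#' @param class \code{"host"} or \code{"phage"}.
#' @param min_density Occupancy threshold (per ml); bins at or below it
#'   are treated as empty.
#' @return Integer cluster count (0 for an empty community).
#' @examples
#' st <- community_state(2, hosts = data.frame(
#'   h = c(0.20, 0.21, 0.35, 0.50, 0.51), N = rep(10, 5)))
#' strain_richness(st, "host")   # 3
#' @export
strain_richness <- function(state, class = c("host", "phage"),
                            min_density = 0) {
  class <- match.arg(class)
  dens <- if (class == "host") state$N else state$V
  occ <- dens > min_density
  if (!any(occ)) return(0L)
  # A cluster starts at every occupied bin whose left neighbour is empty.
  sum(occ & !c(FALSE, occ[-length(occ)]))
}

#' Maximum growth rate in the host community
#'
#' The highest landscape growth factor \eqn{\delta} among extant host
#' strains, reported alongside the absolute rate \eqn{\delta\gamma}
#' (the adaptation measure for rugged-landscape ensembles).
#'
#' @param state A \code{community_state}.
#' @param landscape A \code{growth_landscape}.
#' @param params A \code{chemostat_params} (supplies \code{gamma}).
#' @param min_density Minimum density for a strain to count.
#' @return A list with \code{delta} and \code{rate} (\eqn{\delta\gamma},
#'   ug/min).
#' @examples
#' st <- community_state(2, hosts = data.frame(h = 0.5, N = 1e4))
#' max_growth_rate(st, landscape_single_peak(), chemostat_params())
#' @export
max_growth_rate <- function(state, landscape, params, min_density = 0) {
  idx <- which(state$N > min_density)
  if (length(idx) == 0L)
    stop("maximum growth rate undefined for an empty host community",
         call. = FALSE)
  delta <- landscape_delta(landscape, t = state$t)
  d <- max(delta[idx])
  list(delta = d, rate = d * params$gamma)
}

#' Sampled-window indices of a trajectory
#'
#' Splits a trajectory's samples into early, middle, and late windows
#' (each a fraction of the sampled timepoints) for windowed observables
#' such as the growth-lysis correlation.
#'
#' @param trajectory A \code{chemostat_trajectory}.
#' @param fraction Window width as a fraction of the samples.
#' @return A list of integer index vectors \code{early}, \code{middle},
#'   \code{late}.
#' @examples
#' p <- chemostat_params(T_total = 1e4)
#' tr <- simulate_chemostat(p, landscape_single_peak(), seed = 1)
#' sample_windows(tr)$late
#' @export
sample_windows <- function(trajectory, fraction = 0.05) {
  ns <- length(trajectory$times)
  w <- max(1L, as.integer(round(fraction * ns)))
  mid0 <- (ns - w) %/% 2L
  list(early = seq_len(w),
       middle = seq.int(mid0 + 1L, mid0 + w),
       late = seq.int(ns - w + 1L, ns))
}
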