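#' Expected mutant production rates
#'
#' Mutants arise in proportion to the instantaneous production of new
#' particles: for host strain \eqn{h_i} the expected mutant rate is
#' \eqn{M_B L \gamma R N_i \delta_i / (R + K)} per minute (gross cell
#' production times the per-cell mutation rate, scaled by chemostat
#' volume), and for phage strain \eqn{v_j} it is
#' \eqn{M_V L \sum_i \beta \theta_{ij} N_i V_j} (gross virion
#' production).
#'
#' @inheritParams state_derivatives
#' @return A list with data frames \code{host} and \code{phage}, each
#'   with columns \code{bin} (0-based, ascending) and \code{rate}
#'   (mutants per minute) for occupied bins.
#' @examples
#' p <- chemostat_params()
#' st <- community_state(2, hosts = data.frame(h = 0.5, N = 1e5))
#' expected_mutation_rates(st, p, landscape_single_peak())$host
#' @export
expected_mutation_rates <- function(state, params, landscape,
                                    scheme = c("gaussian", "strict"),
                                    theta = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(theta)) theta <- dense_theta(params, scheme)
  delta <- landscape_delta(landscape, t = state$t)
  monod <- params$gamma * state$R / (state$R + params$K)
  hidx <- which(state$N > 0)
  pidx <- which(state$V > 0)
  hrate <- params$M_B * params$L * monod * state$N[hidx] * delta[hidx]
  prod <- as.vector(crossprod(theta, state$N))
  prate <- params$M_V * params$L * params$beta * state$V[pidx] * prod[pidx]
  list(host = data.frame(bin = hidx - 1L, rate = hrate),
       phage = data.frame(bin = pidx - 1L, rate = prate))
}

#' Draw stochastic mutation events
#'
#' For each strain, the number of mutants in a timestep is Poisson with
#' mean \code{rate * dt}; each mutant's genotype is the parent's plus a
#' normal deviate (sd \code{sigma_B} for hosts, \code{sigma_V} for
#' phage), binned to the \code{rho}-grid. Because the effect sd equals
#' the bin width by default, most offsets round back to the parental bin;
#' such zero-effect mutations are dropped. Offsets that leave [0, 1] are
#' skipped and flagged. Draws are consumed strain-by-strain, hosts by
#' ascending bin then phage by ascending bin, so event lists are
#' reproducible from the RNG state.
#'
#' @param rates Output of \code{\link{expected_mutation_rates}}.
#' @param params A \code{chemostat_params}.
#' @param dt Timestep (min).
#' @return A data frame of mutation events (columns \code{class},
#'   \code{parent_bin}, \code{offspring_bin}, \code{count}; one row per
#'   mutant, in draw order) with attribute \code{range_edge}.
#' @examples
#' p <- chemostat_params(M_B = 1e-3)
#' st <- community_state(2, hosts = data.frame(h = 0.5, N = 1e6))
#' r <- expected_mutation_rates(st, p, landscape_single_peak())
#' set.seed(1)
#' draw_mutations(r, p)
#' @export
draw_mutations <- function(rates, params, dt = params$dt) {
  events <- list()
  range_edge <- FALSE
  nb <- n_bins(params$rho)
  draw_class <- function(tab, sigma, cls) {
    for (k in seq_len(nrow(tab))) {
      m <- stats::rpois(1L, tab$rate[k] * dt)
      if (m == 0L) next
      par_bin <- tab$bin[k]
      offs <- stats::rnorm(m, 0, sigma)
      off_bin <- genotype_bin(bin_centre(par_bin, params$rho) + offs,
                              params$rho)
      out <- off_bin < 0L | off_bin > nb - 1L
      if (any(out)) range_edge <<- TRUE
      keep <- !out & off_bin != par_bin
      if (any(keep))
        events[[length(events) + 1L]] <<- data.frame(
          class = cls, parent_bin = par_bin,
          offspring_bin = off_bin[keep], count = 1L)
    }
  }
  draw_class(rates$host, params$sigma_B, "host")
  draw_class(rates$phage, params$sigma_V, "phage")
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(class = character(0), parent_bin = integer(0),
                        offspring_bin = integer(0), count = integer(0))
  attr(ev, "range_edge") <- range_edge
  ev
}

#' Apply mutation events to a community state
#'
#' Each event moves \code{count / L} density units from the parent bin to
#' the offspring bin (mutants are a reclassification of newly produced
#' particles, not new biomass), creating the offspring population if
#' absent. The debit from the parent is floored at zero; up to that edge
#' case, mutation conserves total host and phage density. Events are
#' processed in list order.
#'
#' @param state A \code{community_state}.
#' @param events Event data frame from \code{\link{draw_mutations}}.
#' @param params A \code{chemostat_params} (supplies \code{L}).
#' @return The updated \code{community_state}.
#' @examples
#' p <- chemostat_params()
#' st <- community_state(2, hosts = data.frame(h = 0.5, N = 100))
#' ev <- data.frame(class = "host", parent_bin = 50L,
#'                  offspring_bin = 51L, count = 1L)
#' host_community(apply_mutations(st, ev, p))
#' @export
apply_mutations <- function(state, events, params) {
  if (nrow(events) == 0L) return(state)
  nb <- length(state$N)
  if (any(events$offspring_bin < 0L | events$offspring_bin > nb - 1L))
    stop_invalid("event offspring bin outside the genotype grid")
  for (k in seq_len(nrow(events))) {
    amt <- events$count[k] / params$L
    par <- events$parent_bin[k] + 1L
    off <- events$offspring_bin[k] + 1L
    if (events$class[k] == "host") {
      state$N[off] <- state$N[off] + amt
      state$N[par] <- state$N[par] - min(state$N[par], amt)
    } else {
      state$V[off] <- state$V[off] + amt
      state$V[par] <- state$V[par] - min(state$V[par], amt)
    }
  }
  state
}
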