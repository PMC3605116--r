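#' Closed-form steady states of the chemostat
#'
#' Equilibrium theory for the model, used both as predictions in their
#' own right and as analytic oracles for the simulator.
#'
#' For a single host strain without phage, setting \eqn{dN/dt = 0} gives
#' the limiting resource concentration
#' \deqn{\bar R = \omega K / (\gamma \delta - \omega)}
#' (the R* of resource-competition theory: the strain with the lowest
#' \eqn{\bar R} wins pure resource competition), and \eqn{dR/dt = 0} then
#' gives the resource-limited density \eqn{\bar N}. With a perfect-match
#' phage, \eqn{dV/dt = 0} pins the host at the phage-limited density
#' \deqn{\hat N = \omega / (\beta \phi),} independent of \eqn{\delta},
#' while the phage equilibrates at
#' \eqn{\hat V = -\omega/\phi + \gamma R \delta / (\phi (R + K))},
#' increasing with host growth rate.
#'
#' @param delta Growth scaling factor of the strain.
#' @param params A \code{chemostat_params}.
#' @return \code{rbar}: the limiting resource concentration (ug/ml).
#' @examples
#' p <- chemostat_params()
#' rbar(1.2, p)            # R* for the fastest strain, ~1.152
#' nbar(1.2, p)            # resource-limited carrying capacity
#' nhat(p)                 # phage-limited host density, ~4.47e4
#' @export
rbar <- function(delta, params) {
  g <- params$gamma * delta
  if (any(g <= params$omega))
    stop("no positive equilibrium: gamma * delta must exceed omega",
         call. = FALSE)
  params$omega * params$K / (g - params$omega)
}

#' @rdname rbar
#' @return \code{nbar}: the phage-free equilibrium host density
#'   (cells/ml).
#' @export
nbar <- function(delta, params) {
  rb <- rbar(delta, params)
  if (any(rb > params$R0))
    stop("strain cannot establish: limiting resource exceeds supply R0",
         call. = FALSE)
  params$omega * (params$R0 - rb) * (rb + params$K) /
    (params$eps * params$gamma * delta * rb)
}

#' @rdname rbar
#' @return \code{nhat}: the phage-limited host density
#'   \eqn{\omega/(\beta\phi)} (cells/ml), the same for every strain with
#'   an infectious phage.
#' @export
nhat <- function(params) {
  params$omega / (params$beta * params$phi)
}

#' @rdname rbar
#' @param R Resource concentration at which to evaluate the phage
#'   equilibrium.
#' @return \code{vhat}: the equilibrium phage density (virions/ml) on a
#'   perfect-match host at resource level \code{R}.
#' @export
vhat <- function(delta, params, R) {
  -params$omega / params$phi +
    params$gamma * R * delta / (params$phi * (R + params$K))
}

#' @rdname rbar
#' @return \code{phage_limited}: a list with the phage-limited host
#'   density \code{N_hat} and the matched-phage density \code{V_hat}
#'   evaluated at the single-strain coexistence resource level
#'   (\code{R} defaults to \code{rhat(1, delta, params)}).
#' @export
phage_limited <- function(params, delta, R = NULL) {
  if (is.null(R)) R <- rhat(1L, delta, params)
  list(N_hat = nhat(params), V_hat = vhat(delta, params, R), R = R)
}

#' Phage-limited equilibrium resource after sequential introductions
#'
#' Under strict lock-and-key infection, suppose strains
#' \eqn{h_1, ..., h_i} (ordered by decreasing growth factor) have each
#' established with an associated phage, so every one sits at the
#' phage-limited density \eqn{\hat N = \omega/(\beta\phi)}. Solving the
#' resource balance at equilibrium gives a quadratic in the resource
#' concentration whose positive root is
#' \deqn{\hat R_i = \frac{A + \sqrt{A^2 + 4 R_0 K}}{2}, \quad
#'       A = R_0 - K - \frac{\epsilon\gamma\sum_{j \le i}\delta_j}{\beta\phi}.}
#' \eqn{\hat R_i} decreases as more consumers are added.
#'
#' @param i Number of established strains (may be a vector).
#' @param delta_pool Growth factors \eqn{\delta_1 > \delta_2 > ...} of
#'   the candidate strains, strictly decreasing.
#' @param params A \code{chemostat_params}.
#' @return \eqn{\hat R_i} (ug/ml), same length as \code{i}.
#' @examples
#' p <- chemostat_params()
#' rhat(1:3, seq(1.2, 0.8, by = -0.04), p)
#' @export
rhat <- function(i, delta_pool, params) {
  check_pool(delta_pool)
  if (any(i < 1) || any(i > length(delta_pool)) || any(i != round(i)))
    stop_invalid("i must index into the strain pool")
  csum <- cumsum(delta_pool)[i]
  A <- params$R0 - params$K -
    params$eps * params$gamma * csum / (params$beta * params$phi)
  disc <- A^2 + 4 * params$R0 * params$K
  if (any(disc < 0))
    stop("internal error: negative discriminant in equilibrium quadratic",
         call. = FALSE)
  (A + sqrt(disc)) / 2
}

check_pool <- function(delta_pool) {
  if (length(delta_pool) < 1L)
    stop_invalid("the strain pool must be non-empty")
  if (any(!is.finite(delta_pool)) || any(delta_pool <= 0))
    stop_invalid("growth factors must be positive and finite")
  if (is.unsorted(rev(delta_pool), strictly = TRUE) &&
      length(delta_pool) > 1L)
    stop_invalid("delta_pool must be strictly decreasing")
  invisible(delta_pool)
}

#' Steady-state host diversity by sequential introduction
#'
#' Predicts the number of host strains coexisting at steady state under
#' strict lock-and-key infection, given a pool of candidate strains with
#' strictly decreasing growth factors. Strains enter in order of
#' decreasing growth rate, each acquiring a matched phage and settling at
#' the phage-limited density \eqn{\hat N}; strain \eqn{i} can establish
#' while the prevailing resource level \eqn{\hat R_{i-1}} exceeds its
#' limiting concentration \eqn{\bar R_i}. The cascade ends at the first
#' strain that is resource-limited rather than phage-limited, i.e. the
#' smallest \eqn{i} with \eqn{\bar R_i > \hat R_i}; that strain cannot
#' support phage and the predicted diversity is \eqn{x = i}. The
#' equilibrium reached is independent of the order of introduction.
#'
#' If no strain in the pool is resource-limited, all \eqn{H} strains
#' coexist phage-limited and the \code{all_phage_limited} flag is set.
#' If even the fastest strain cannot establish at supply \code{R0},
#' \eqn{x = 0}.
#'
#' @param delta_pool Strictly decreasing growth factors
#'   \eqn{\delta_1 > ... > \delta_H}.
#' @param params A \code{chemostat_params}.
#' @return An object of class \code{steady_state_diversity}: a list with
#'   \code{x} (predicted number of coexisting host strains),
#'   \code{all_phage_limited}, and the \code{rbar}/\code{rhat} sequences
#'   over the pool.
#' @examples
#' p <- chemostat_params()   # R0 = 2.2
#' steady_state_diversity(seq(1.2, 0.8, by = -0.04), p)$x   # 6
#' @export
steady_state_diversity <- function(delta_pool, params) {
  check_pool(delta_pool)
  H <- length(delta_pool)
  rb <- vapply(delta_pool, function(d) {
    if (params$gamma * d <= params$omega) Inf else rbar(d, params)
  }, numeric(1))
  rh <- rhat(seq_len(H), delta_pool, params)
  x <- NA_integer_
  all_pl <- FALSE
  if (rb[1] >= params$R0) {
    x <- 0L                       # nothing can establish
  } else {
    hit <- which(rb > rh)
    if (length(hit)) {
      x <- hit[1]
    } else {
      x <- H                      # every candidate is phage-limited
      all_pl <- TRUE
    }
  }
  structure(list(x = x, all_phage_limited = all_pl, H = H,
                 delta_pool = delta_pool, rbar = rb, rhat = rh,
                 params = params),
            class = "steady_state_diversity")
}

#' @export
print.steady_state_diversity <- function(x, ...) {
  cat(sprintf("Steady-state diversity prediction: x = %d of %d candidate strains\n",
              x$x, x$H))
  if (x$all_phage_limited)
    cat("  (all candidates phage-limited; the pool bounds the prediction)\n")
  else if (x$x > 0)
    cat(sprintf("  strain %d is the first resource-limited strain (Rbar = %.4g > Rhat = %.4g)\n",
                x$x, x$rbar[x$x], x$rhat[x$x]))
  invisible(x)
}

#' Steady-state diversity across resource supply levels
#'
#' Re-evaluates the sequential-introduction prediction for a series of
#' supply concentrations \code{R0}; diversity is non-decreasing in
#' resource supply.
#'
#' @param R0_values Supply concentrations to scan.
#' @param delta_pool Strictly decreasing growth factors.
#' @param params A \code{chemostat_params} (its \code{R0} is replaced).
#' @return Data frame with columns \code{R0}, \code{x},
#'   \code{all_phage_limited}.
#' @examples
#' diversity_scan(c(1.7, 2.2, 2.7), seq(1.2, 0.8, by = -0.04),
#'                chemostat_params())
#' @export
diversity_scan <- function(R0_values, delta_pool, params) {
  rows <- lapply(R0_values, function(r0) {
    ss <- steady_state_diversity(delta_pool, update_params(params, R0 = r0))
    data.frame(R0 = r0, x = ss$x, all_phage_limited = ss$all_phage_limited)
  })
  do.call(rbind, rows)
}

#' Equal growth rates preclude phage-supported coexistence
#'
#' Corollary of the sequential-introduction analysis: if all host strains
#' share one growth factor \eqn{\delta}, they share one limiting resource
#' concentration \eqn{\bar R}. The first established strain that cannot
#' support phage draws resource down to \eqn{\bar R}, at which every
#' phage-limited strain (held at \eqn{\hat N} with extra mortality from
#' lysis) has \eqn{dN/dt < 0}; those strains and eventually their phage
#' are lost. Stable host-phage coexistence under strict lock-and-key
#' therefore requires variation in host growth rates.
#'
#' @param params A \code{chemostat_params}.
#' @param delta The shared growth factor.
#' @param n_strains Number of equal-growth strains considered.
#' @return A list describing the prediction: at most the phage-free
#'   strains persist (\code{phage_supported_survivors = 0}), with the
#'   shared \code{rbar} and the phage-limited density \code{N_hat}.
#' @examples
#' equal_growth_collapse_check(chemostat_params(), 1.0, 3)
#' @export
equal_growth_collapse_check <- function(params, delta, n_strains) {
  stopifnot(n_strains >= 1)
  rb <- rbar(delta, params)
  list(delta = delta, n_strains = n_strains, rbar = rb,
       N_hat = nhat(params),
       phage_supported_survivors = 0L,
       prediction = "phage-supported coexistence collapses; only phage-free strains persist")
}
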