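#' Community state of the chemostat
#'
#' A snapshot of the system at one time point: resource concentration
#' \code{R} plus the densities of every host and phage strain, stored as
#' dense vectors over the genotype grid (zero density marks an
#' unoccupied bin). Strains are identified with grid bins; each host bin
#' carries the phenotypes \eqn{\hat h} (its bin centre) and \eqn{\delta}
#' (from the growth landscape), each phage bin carries \eqn{\hat v}.
#'
#' @param R Resource concentration (ug/ml), non-negative.
#' @param hosts Data frame with columns \code{h} (genotype) and \code{N}
#'   (density, cells/ml), or \code{NULL} for no hosts.
#' @param phages Data frame with columns \code{v} and \code{V}
#'   (virions/ml), or \code{NULL} for no phage.
#' @param rho Genotype bin resolution.
#' @param t Time stamp (min).
#' @return An object of class \code{community_state} with fields
#'   \code{t}, \code{R}, \code{N}, \code{V} (dense density vectors), and
#'   \code{rho}.
#' @examples
#' st <- community_state(R = 2.2,
#'                       hosts = data.frame(h = 0.2, N = 4.6e4),
#'                       phages = data.frame(v = 0.2, V = 8.1e5))
#' host_community(st)
#' @export
community_state <- function(R, hosts = NULL, phages = NULL,
                            rho = 0.01, t = 0) {
  if (!is.finite(R) || R < 0) stop_invalid("R must be finite and >= 0")
  nb <- n_bins(rho)
  N <- numeric(nb); V <- numeric(nb)
  fill <- function(vec, g, dens, what) {
    if (any(!is.finite(g)) || any(g < 0) || any(g > 1))
      stop_invalid(what, " genotypes must lie in [0, 1]")
    if (any(!is.finite(dens)) || any(dens < 0))
      stop_invalid(what, " densities must be finite and >= 0")
    idx <- genotype_bin(g, rho) + 1L
    for (k in seq_along(idx)) vec[idx[k]] <- vec[idx[k]] + dens[k]
    vec
  }
  if (!is.null(hosts) && nrow(hosts) > 0)
    N <- fill(N, hosts$h, hosts$N, "host")
  if (!is.null(phages) && nrow(phages) > 0)
    V <- fill(V, phages$v, phages$V, "phage")
  structure(list(t = t, R = R, N = N, V = V, rho = rho),
            class = "community_state")
}

#' @rdname community_state
#' @param state A \code{community_state}.
#' @return \code{host_community} / \code{phage_community} return a data
#'   frame of the occupied bins (columns \code{bin}, genotype, density).
#' @export
host_community <- function(state) {
  idx <- which(state$N > 0)
  data.frame(bin = idx - 1L, h = bin_centre(idx - 1L, state$rho),
             N = state$N[idx])
}

#' @rdname community_state
#' @export
phage_community <- function(state) {
  idx <- which(state$V > 0)
  data.frame(bin = idx - 1L, v = bin_centre(idx - 1L, state$rho),
             V = state$V[idx])
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("Community state at t = %g min\n", x$t))
  cat(sprintf("  R = %.4g ug/ml\n", x$R))
  cat(sprintf("  hosts: %d occupied bins, total %.4g cells/ml\n",
              sum(x$N > 0), sum(x$N)))
  cat(sprintf("  phage: %d occupied bins, total %.4g virions/ml\n",
              sum(x$V > 0), sum(x$V)))
  invisible(x)
}
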