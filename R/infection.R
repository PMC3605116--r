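#' Lock-and-key infection kernels
#'
#' Adsorption of phage to host depends on the genetic match between the
#' host resistance phenotype \eqn{\hat h} and the phage infection
#' phenotype \eqn{\hat v}. Two schemes are supported:
#' \describe{
#'   \item{gaussian (relaxed lock-and-key)}{\eqn{\theta = \phi
#'     e^{-s(\hat h - \hat v)^2}}: infection is maximal at a perfect match
#'     and decays with genetic distance at a rate set by the specificity
#'     \eqn{s}.}
#'   \item{strict lock-and-key}{\eqn{\theta = \phi} if host and phage
#'     occupy the same genotype bin, 0 otherwise. Equality is tested on
#'     bin indices, never on floating-point traits.}
#' }
#'
#' @param h_hat Host resistance phenotype(s) in [0, 1].
#' @param v_hat Phage infection phenotype(s) in [0, 1].
#' @param phi Maximum adsorption rate (ml/(min cell)).
#' @param s Specificity (> 0 required for the Gaussian kernel).
#' @return Adsorption coefficient(s) \eqn{\theta} in [0, \eqn{\phi}].
#' @examples
#' adsorption_gaussian(0.5, 0.5, phi = 0.104e-8, s = 100)  # = phi
#' adsorption_gaussian(0.5, 0.6, phi = 1, s = 100)         # exp(-1)
#' adsorption_strict(0.5, 0.51, phi = 1)                   # 0
#' @export
adsorption_gaussian <- function(h_hat, v_hat, phi, s) {
  if (!is.finite(phi) || phi <= 0)
    stop_invalid("phi must be a positive finite number")
  if (!is.finite(s) || s <= 0)
    stop_invalid("s must be a positive finite number")
  check_trait(h_hat); check_trait(v_hat)
  phi * exp(-s * (h_hat - v_hat)^2)
}

#' @rdname adsorption_gaussian
#' @param rho Genotype bin resolution used for the strict equality test.
#' @export
adsorption_strict <- function(h_hat, v_hat, phi, rho = 0.01) {
  if (!is.finite(phi) || phi <= 0)
    stop_invalid("phi must be a positive finite number")
  check_trait(h_hat); check_trait(v_hat)
  ifelse(genotype_bin(h_hat, rho) == genotype_bin(v_hat, rho), phi, 0)
}

check_trait <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_invalid("traits must lie in [0, 1]")
  invisible(x)
}

#' Pairwise adsorption matrix for a strain roster
#'
#' Builds the matrix \eqn{\theta_{ij}} of adsorption coefficients for
#' every host strain \eqn{i} (rows) against every phage strain \eqn{j}
#' (columns). An empty roster on either side yields a dimensioned empty
#' matrix, which makes all lysis/production sums vanish (the no-phage
#' control).
#'
#' @param host_traits Host resistance phenotypes (possibly empty).
#' @param phage_traits Phage infection phenotypes (possibly empty).
#' @param params A \code{chemostat_params} object supplying \code{phi},
#'   \code{s}, and \code{rho}.
#' @param scheme \code{"gaussian"} or \code{"strict"}.
#' @return A numeric matrix of dimension
#'   \code{length(host_traits)} x \code{length(phage_traits)}.
#' @examples
#' p <- chemostat_params()
#' adsorption_matrix(c(0.2, 0.5), 0.2, p)
#' @export
adsorption_matrix <- function(host_traits, phage_traits, params,
                              scheme = c("gaussian", "strict")) {
  scheme <- match.arg(scheme)
  nh <- length(host_traits); nv <- length(phage_traits)
  if (nh == 0L || nv == 0L)
    return(matrix(numeric(0), nrow = nh, ncol = nv))
  if (scheme == "gaussian") {
    outer(host_traits, phage_traits,
          function(h, v) adsorption_gaussian(h, v, params$phi, params$s))
  } else {
    outer(host_traits, phage_traits,
          function(h, v) adsorption_strict(h, v, params$phi, params$rho))
  }
}

# Kernel values by bin distance d = |i - j| on the rho-grid; theta depends
# on traits only through their distance, so the full matrix is a lookup.
theta_by_distance <- function(params, scheme = c("gaussian", "strict"),
                              n = n_bins(params$rho)) {
  scheme <- match.arg(scheme)
  d <- (seq_len(n) - 1L) * params$rho
  if (scheme == "gaussian") params$phi * exp(-params$s * d^2)
  else c(params$phi, rep(0, n - 1L))
}
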