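#' Model parameters for the chemostat coevolution model
#'
#' Constructs the full parameter set governing chemostat ecology, the
#' infection kernel, and the mutation process. Defaults are the benchmark
#' parameterisation used throughout: a 1 ml chemostat diluted at
#' \code{omega} per minute and supplied with resource at \code{R0}, hosts
#' growing by Monod uptake kinetics (\code{gamma}, \code{K}) scaled by a
#' genotype-dependent factor \eqn{\delta \in [\delta_{min}, \delta_{max}]},
#' and phage adsorbing at up to \code{phi} with Gaussian specificity
#' \code{s}. Mutation rates are per new cell (\code{M_B}) and per new
#' virion (\code{M_V}), with normally distributed effect sizes
#' (\code{sigma_B}, \code{sigma_V}) on the genotype line, which is binned
#' at resolution \code{rho}.
#'
#' @param omega Chemostat dilution rate (1/min).
#' @param R0 Resource supply concentration (ug/ml).
#' @param eps Resource conversion rate (ug/cell).
#' @param gamma Maximum resource uptake rate (ug/min).
#' @param K Half-saturation constant (ug/ml).
#' @param phi Maximum adsorption rate (ml/(min cell)).
#' @param beta Burst size (virions per lysis).
#' @param s Specificity of phage (dimensionless; larger = more specialist).
#' @param delta_min,delta_max Minimum and maximum growth scaling factors.
#' @param M_B,M_V Host / phage mutation rate (per cell, per virion).
#' @param sigma_B,sigma_V Std. dev. of host / phage mutation effect size.
#' @param dt Integration timestep (min).
#' @param T_total Simulation duration (min).
#' @param rho Genotype bin resolution.
#' @param L Chemostat volume (ml).
#' @param N_init Initial host density (cells/ml).
#' @param V_init Initial phage density (virions/ml); 0 gives a no-phage run.
#' @param h_init,v_init Initial host and phage genotypes in [0, 1].
#'
#' @return An object of class \code{chemostat_params}: a named list of
#'   validated parameters.
#' @examples
#' p <- chemostat_params()
#' p$R0
#' chemostat_params(R0 = 2.7, s = 400)
#' @export
chemostat_params <- function(omega = 0.0033,
                             R0 = 2.2,
                             eps = 2.6e-6,
                             gamma = 0.0123,
                             K = 4,
                             phi = 0.104e-8,
                             beta = 71,
                             s = 100,
                             delta_min = 0.8,
                             delta_max = 1.2,
                             M_B = 1e-6,
                             M_V = 1e-6,
                             sigma_B = 0.01,
                             sigma_V = 0.01,
                             dt = 10,
                             T_total = 20e6,
                             rho = 0.01,
                             L = 1,
                             N_init = 4.6e4,
                             V_init = 8.1e5,
                             h_init = 0.2,
                             v_init = 0.2) {
  p <- list(omega = omega, R0 = R0, eps = eps, gamma = gamma, K = K,
            phi = phi, beta = beta, s = s,
            delta_min = delta_min, delta_max = delta_max,
            M_B = M_B, M_V = M_V, sigma_B = sigma_B, sigma_V = sigma_V,
            dt = dt, T_total = T_total, rho = rho, L = L,
            N_init = N_init, V_init = V_init,
            h_init = h_init, v_init = v_init)
  validate_params(p)
  class(p) <- "chemostat_params"
  p
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  pos <- c("omega", "R0", "eps", "gamma", "K", "phi", "beta",
           "delta_min", "delta_max", "dt", "rho", "L", "N_init")
  for (nm in pos) {
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  }
  nonneg <- c("s", "M_B", "M_V", "sigma_B", "sigma_V", "T_total", "V_init")
  for (nm in nonneg) {
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$delta_max < p$delta_min)
    stop("delta_max must be >= delta_min", call. = FALSE)
  if (p$h_init < 0 || p$h_init > 1 || p$v_init < 0 || p$v_init > 1)
    stop("initial genotypes must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.chemostat_params <- function(x, ...) {
  cat("Chemostat coevolution parameters\n")
  cat(sprintf("  dilution omega = %g /min; supply R0 = %g ug/ml; volume L = %g ml\n",
              x$omega, x$R0, x$L))
  cat(sprintf("  uptake gamma = %g ug/min; K = %g ug/ml; conversion eps = %g ug/cell\n",
              x$gamma, x$K, x$eps))
  cat(sprintf("  adsorption phi = %g ml/(min cell); burst beta = %g; specificity s = %g\n",
              x$phi, x$beta, x$s))
  cat(sprintf("  growth scaling delta in [%g, %g]\n", x$delta_min, x$delta_max))
  cat(sprintf("  mutation M_B = %g /cell, M_V = %g /virion; sigma = (%g, %g); rho = %g\n",
              x$M_B, x$M_V, x$sigma_B, x$sigma_V, x$rho))
  cat(sprintf("  integration dt = %g min, T = %g min\n", x$dt, x$T_total))
  cat(sprintf("  init: N = %g at h = %g; V = %g at v = %g\n",
              x$N_init, x$h_init, x$V_init, x$v_init))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named fields replaced and the
#' result revalidated. Convenient for one-at-a-time sensitivity scans.
#'
#' @param params A \code{chemostat_params} object.
#' @param ... Named parameter replacements.
#' @return A new \code{chemostat_params} object.
#' @examples
#' update_params(chemostat_params(), R0 = 1.7, s = 1000)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "chemostat_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  bad <- setdiff(names(repl), names(params))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_params(p)
  class(p) <- "chemostat_params"
  p
}
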