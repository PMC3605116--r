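#' Growth-rate landscapes: genotype to growth scaling factor
#'
#' A growth landscape maps host genotype \eqn{h \in [0,1]} to the growth
#' scaling factor \eqn{\delta = f(h)}, pleiotropically linking the host's
#' resistance phenotype (\eqn{\hat h = h}, which sets infection risk) to
#' its growth rate. Four families are provided:
#' \describe{
#'   \item{\code{landscape_single_peak}}{piecewise linear, joining
#'     \eqn{(0, \delta_{min})} to \eqn{(0.5, \delta_{max})} to
#'     \eqn{(1, \delta_{min})}.}
#'   \item{\code{landscape_two_peak}}{time-dependent pointwise maximum of
#'     the static single peak and a second peak whose height follows a
#'     step schedule, modelling a changing environment.}
#'   \item{\code{landscape_multi_peak}}{\code{n} repeated up-down-up
#'     blocks forming a saw-toothed increasing gradient with \code{n}
#'     interior local maxima separated by fitness valleys.}
#'   \item{\code{landscape_rugged_slope}}{a linear slope from
#'     \eqn{(0, \delta_{min})} to \eqn{(1, \delta_{max})} plus uniform
#'     noise, smoothed by a centred moving average of width \code{span};
#'     smaller \code{span} gives a more rugged landscape.}
#' }
#' Landscapes are tabulated on the genotype grid at resolution \code{rho};
#' evaluation is piecewise constant per bin, since strains only ever
#' occupy bin centres.
#'
#' @param delta_min,delta_max Minimum and maximum growth scaling factors.
#' @param rho Genotype bin resolution.
#' @return An object of class \code{growth_landscape}.
#' @examples
#' ls1 <- landscape_single_peak()
#' landscape_delta(ls1, h = c(0, 0.25, 0.5))   # 0.8 1.0 1.2
#' ls4 <- landscape_multi_peak(n = 4)
#' lsr <- landscape_rugged_slope(span = 5, seed = 42)
#' @export
landscape_single_peak <- function(delta_min = 0.8, delta_max = 1.2,
                                  rho = 0.01) {
  check_delta_bounds(delta_min, delta_max)
  grid <- genotype_grid(rho)
  delta <- peak_profile(0.5, delta_max, delta_min, grid)
  new_landscape("single_peak", rbind(delta), -Inf, grid, rho,
                list(delta_min = delta_min, delta_max = delta_max))
}

#' @rdname landscape_single_peak
#' @param schedule Data frame with columns \code{time} and \code{height}:
#'   the second peak takes height \code{height[k]} from \code{time[k]}
#'   onwards (step schedule). Both columns must be non-decreasing. Before
#'   the first entry the landscape equals the static single peak. See
#'   \code{\link{two_peak_schedule}} for the default ramp.
#' @param centre2 Genotype position of the second peak.
#' @export
landscape_two_peak <- function(delta_min = 0.8, delta_max = 1.2,
                               schedule, centre2 = 0.8, rho = 0.01) {
  check_delta_bounds(delta_min, delta_max)
  if (!is.data.frame(schedule) ||
      !all(c("time", "height") %in% names(schedule)) ||
      nrow(schedule) < 1L)
    stop_invalid("schedule must be a data.frame with columns time, height")
  if (is.unsorted(schedule$time, strictly = FALSE) ||
      is.unsorted(schedule$height, strictly = FALSE))
    stop_invalid("schedule must be non-decreasing in both time and height")
  if (centre2 <= 0 || centre2 >= 1)
    stop_invalid("centre2 must lie strictly inside (0, 1)")
  grid <- genotype_grid(rho)
  peak1 <- peak_profile(0.5, delta_max, delta_min, grid)
  heights <- c(delta_min, schedule$height)  # pre-schedule epoch: no bump
  delta <- t(vapply(heights, function(hh) {
    pmax(peak1, peak_profile(centre2, hh, delta_min, grid))
  }, numeric(length(grid))))
  new_landscape("dynamic_two_peak", delta, c(-Inf, schedule$time), grid, rho,
                list(delta_min = delta_min, delta_max = delta_max,
                     centre2 = centre2, schedule = schedule))
}

#' @rdname landscape_single_peak
#' @param n Number of blocks (local peaks) for the multi-peak landscape.
#' @export
landscape_multi_peak <- function(n, delta_min = 0.8, delta_max = 1.2,
                                 rho = 0.01) {
  check_delta_bounds(delta_min, delta_max)
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop_invalid("n must be an integer >= 1")
  n <- as.integer(n)
  b_w <- 1 / n
  b_h <- (delta_max - delta_min) / n
  # Block k motif anchors: (0,0) -> (b_w/3, b_h) -> (2 b_w/3, 0) -> (b_w, b_h),
  # offset by the running height; last point of each block starts the next.
  x <- 0
  y <- delta_min
  for (k in seq_len(n)) {
    x <- c(x, (k - 1) * b_w + c(b_w / 3, 2 * b_w / 3, b_w))
    y <- c(y, delta_min + (k - 1) * b_h + c(b_h, 0, b_h))
  }
  grid <- genotype_grid(rho)
  delta <- stats::approx(x, y, xout = grid)$y
  new_landscape("multi_peak", rbind(delta), -Inf, grid, rho,
                list(delta_min = delta_min, delta_max = delta_max,
                     n = n, b_w = b_w, b_h = b_h,
                     anchors = data.frame(h = x, delta = y)))
}

#' @rdname landscape_single_peak
#' @param span Odd positive integer: width (in grid points) of the centred
#'   moving-average smoothing window; \code{span = 1} means no smoothing.
#'   Near the domain edges the window shrinks symmetrically, so the
#'   underlying linear slope is never distorted by smoothing.
#' @param seed RNG seed for the noise signal (landscape-local; the
#'   caller's RNG state is untouched).
#' @param amplitude Peak-to-peak amplitude of the uniform noise, i.e.
#'   noise is drawn i.i.d. from
#'   \eqn{U(-\mathrm{amplitude}/2, +\mathrm{amplitude}/2)}.
#' @export
landscape_rugged_slope <- function(span, seed, amplitude = 0.2,
                                   delta_min = 0.8, delta_max = 1.2,
                                   rho = 0.01) {
  check_delta_bounds(delta_min, delta_max)
  if (length(span) != 1L || !is.finite(span) || span < 1 ||
      span != round(span) || span %% 2 == 0)
    stop_invalid("span must be an odd positive integer")
  if (!is.finite(amplitude) || amplitude < 0)
    stop_invalid("amplitude must be non-negative")
  grid <- genotype_grid(rho)
  base <- delta_min + (delta_max - delta_min) * grid
  noise <- with_seed(seed, stats::runif(length(grid),
                                        -amplitude / 2, amplitude / 2))
  delta <- moving_average(base + noise, as.integer(span))
  new_landscape("rugged_slope", rbind(delta), -Inf, grid, rho,
                list(delta_min = delta_min, delta_max = delta_max,
                     span = as.integer(span), amplitude = amplitude,
                     seed = seed, base = base))
}

#' Default ramp schedule for the dynamic two-peak landscape
#'
#' Ramps the second peak's height in \code{steps} equal increments from
#' \code{delta_min} (no bump) up to
#' \eqn{\delta_{max} + 0.1(\delta_{max} - \delta_{min})}, so the second
#' peak overtakes the first part-way through the run. Step \code{k} takes
#' effect at time \code{k * t_end / (steps + 1)}, leaving the final height
#' in force for the last fraction of the run.
#'
#' @param t_end Run duration (min) the ramp spans.
#' @param steps Number of height increments.
#' @param delta_min,delta_max Growth scaling bounds of the landscape.
#' @return A data frame with columns \code{time}, \code{height}.
#' @examples
#' two_peak_schedule(2e6)
#' @export
two_peak_schedule <- function(t_end, steps = 10,
                              delta_min = 0.8, delta_max = 1.2) {
  stopifnot(t_end > 0, steps >= 1)
  data.frame(
    time = seq_len(steps) * t_end / (steps + 1),
    height = seq(delta_min, delta_max + 0.1 * (delta_max - delta_min),
                 length.out = steps)
  )
}

new_landscape <- function(kind, delta, epoch_times, grid, rho, meta) {
  structure(list(kind = kind, delta = delta, epoch_times = epoch_times,
                 grid = grid, rho = rho, meta = meta),
            class = "growth_landscape")
}

check_delta_bounds <- function(delta_min, delta_max) {
  if (!is.finite(delta_min) || !is.finite(delta_max) ||
      delta_min <= 0 || delta_max < delta_min)
    stop_invalid("require finite growth bounds with delta_max >= delta_min > 0")
}

# Triangular peak profile through (0, floor) -> (centre, height) -> (1, floor).
peak_profile <- function(centre, height, floor, grid) {
  stats::approx(c(0, centre, 1), c(floor, height, floor), xout = grid)$y
}

# Row of the tabulated landscape in force at time t.
epoch_index <- function(landscape, t) {
  max(which(landscape$epoch_times <= t))
}

#' Evaluate a growth landscape
#'
#' Returns the growth scaling factor \eqn{\delta} at genotype(s) \code{h}
#' (binned to the grid) at time \code{t}, or the full tabulated vector
#' over the grid when \code{h} is \code{NULL}. Only the dynamic two-peak
#' kind depends on \code{t}.
#'
#' @param landscape A \code{growth_landscape}.
#' @param h Genotype value(s) in [0, 1], or \code{NULL} for the full grid.
#' @param t Time (min) at which to evaluate.
#' @return Numeric vector of \eqn{\delta} values.
#' @examples
#' landscape_delta(landscape_single_peak(), h = 0.5)   # 1.2
#' @export
landscape_delta <- function(landscape, h = NULL, t = 0) {
  stopifnot(inherits(landscape, "growth_landscape"))
  row <- landscape$delta[epoch_index(landscape, t), ]
  if (is.null(h)) return(row)
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1))
    stop_invalid("genotype h must lie in [0, 1]")
  row[genotype_bin(h, landscape$rho) + 1L]
}

#' Genotype-to-phenotype mapping
#'
#' Host genotypes map to a resistance phenotype and a growth scaling
#' factor, \eqn{h \to \{\hat h, \delta\}} with \eqn{\hat h = h} and
#' \eqn{\delta} read from the growth landscape; phage genotypes map
#' directly to the infection phenotype, \eqn{v \to \hat v = v}.
#'
#' @param genotype Genotype value(s) in [0, 1].
#' @param class \code{"host"} or \code{"phage"}.
#' @param landscape Growth landscape (required for hosts).
#' @param t Time at which to evaluate the landscape.
#' @return For hosts, a list with elements \code{h_hat} and \code{delta};
#'   for phage, a list with element \code{v_hat}.
#' @examples
#' genotype_phenotype(0.5, "host", landscape_single_peak())
#' genotype_phenotype(0.2, "phage")
#' @export
genotype_phenotype <- function(genotype, class = c("host", "phage"),
                               landscape = NULL, t = 0) {
  class <- match.arg(class)
  if (any(!is.finite(genotype)) || any(genotype < 0) || any(genotype > 1))
    stop_invalid("genotype must lie in [0, 1]")
  if (class == "phage") return(list(v_hat = genotype))
  if (is.null(landscape))
    stop_invalid("host phenotype requires a growth landscape")
  list(h_hat = genotype, delta = landscape_delta(landscape, genotype, t))
}

#' @export
print.growth_landscape <- function(x, ...) {
  cat(sprintf("Growth landscape: %s on %d-point grid (rho = %g)\n",
              x$kind, length(x$grid), x$rho))
  cat(sprintf("  delta range tabulated: [%.4g, %.4g]\n",
              min(x$delta), max(x$delta)))
  if (x$kind == "dynamic_two_peak")
    cat(sprintf("  %d epochs; second peak at h = %g\n",
                nrow(x$delta), x$meta$centre2))
  if (x$kind == "multi_peak")
    cat(sprintf("  n = %d blocks (width %.3g, height %.3g)\n",
                x$meta$n, x$meta$b_w, x$meta$b_h))
  if (x$kind == "rugged_slope")
    cat(sprintf("  span = %d, noise amplitude %g, seed %s\n",
                x$meta$span, x$meta$amplitude, format(x$meta$seed)))
  invisible(x)
}

#' @export
#' @param row.names,optional Passed through (standard method signature).
#' @param t Time at which to tabulate a dynamic landscape.
#' @rdname landscape_single_peak
as.data.frame.growth_landscape <- function(x, row.names = NULL,
                                           optional = FALSE, t = 0, ...) {
  data.frame(h = x$grid, delta = landscape_delta(x, t = t))
}

#' @export
plot.growth_landscape <- function(x, t = 0, ...) {
  graphics::plot(x$grid, landscape_delta(x, t = t), type = "l",
                 xlab = "genotype h", ylab = expression(delta),
                 main = paste("Growth landscape:", x$kind), ...)
  invisible(x)
}
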