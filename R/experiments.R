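#' Experiment drivers: ensembles over seeds, landscapes, and parameters
#'
#' These functions reproduce the study designs built on the simulator:
#' a single-peak case study of coevolutionary diversification, paired
#' with/without-phage evolvability comparisons, a genotype-range
#' parameter scan, rugged-landscape adaptation ensembles, one-at-a-time
#' parameter sensitivity, and the mutation-rate asymmetry check. Every
#' driver is reproducible from a master seed (per-run seeds are derived
#' from it), and runs whose mutations reach the genotype range edge are
#' flagged and excluded from ensemble statistics.
#'
#' @name experiments
NULL

# Per-run seeds derived from one master seed (kept < 2^31).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

run_summary <- function(tr, landscape, params, threshold = 0.01) {
  fin <- state_at(tr, -1)
  mg <- if (any(fin$N > 0)) max_growth_rate(fin, landscape, params)
        else list(delta = NA_real_, rate = NA_real_)
  data.frame(
    R_final = fin$R, total_N = sum(fin$N), total_V = sum(fin$V),
    host_richness = strain_richness(fin, "host"),
    phage_richness = strain_richness(fin, "phage"),
    genotype_range = if (any(fin$N > 0)) genotype_range(fin, threshold)
                     else NA_real_,
    max_delta = mg$delta, max_rate = mg$rate,
    range_edge = tr$range_edge)
}

#' Coevolutionary diversification case study
#'
#' Runs the benchmark single-peak scenario (one founding host strain
#' with matched phage) across seeds, together with a no-phage control
#' (\code{V_init = 0}) per seed, and records final community summaries
#' and growth-lysis correlations in the late sample window.
#'
#' @param params A \code{chemostat_params}; set \code{T_total} to the
#'   desired (possibly reduced) horizon.
#' @param seeds Integer vector of run seeds.
#' @param control Also run the paired no-phage control for each seed.
#' @param window_fraction Width of the late correlation window as a
#'   fraction of samples.
#' @param threshold Density fraction for correlation/range qualification.
#' @return A list of class \code{case_study} with data frames
#'   \code{runs} and \code{control} (one row per seed) and
#'   \code{late_correlations} (per seed and window sample).
#' @examples
#' \donttest{
#' p <- chemostat_params(T_total = 2e5)
#' cs <- run_case_study(p, seeds = 1:2)
#' cs$runs
#' }
#' @export
run_case_study <- function(params = chemostat_params(T_total = 5e6),
                           seeds = 1:5, control = TRUE,
                           window_fraction = 0.05, threshold = 0.01) {
  landscape <- landscape_single_peak(params$delta_min, params$delta_max,
                                     params$rho)
  runs <- list(); ctrl <- list(); cors <- list()
  for (sd in seeds) {
    tr <- simulate_chemostat(params, landscape, seed = sd)
    runs[[length(runs) + 1L]] <- cbind(seed = sd,
                                       run_summary(tr, landscape, params,
                                                   threshold))
    late <- sample_windows(tr, window_fraction)$late
    for (i in late) {
      st <- state_at(tr, i)
      r <- tryCatch(growth_lysis_correlation(st, params, landscape,
                                             threshold = threshold),
                    error = function(e) NULL)
      if (!is.null(r))
        cors[[length(cors) + 1L]] <- data.frame(
          seed = sd, t = st$t, r = r$r, p = r$p, n = r$n)
    }
    if (control) {
      p0 <- update_params(params, V_init = 0)
      tr0 <- simulate_chemostat(p0, landscape, seed = sd)
      ctrl[[length(ctrl) + 1L]] <- cbind(seed = sd,
                                         run_summary(tr0, landscape, p0,
                                                     threshold))
    }
  }
  structure(list(
    runs = do.call(rbind, runs),
    control = if (control) do.call(rbind, ctrl) else NULL,
    late_correlations = if (length(cors)) do.call(rbind, cors)
                        else NULL,
    params = params), class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat("Coevolutionary diversification case study\n")
  cat(sprintf("  %d seeds, T = %g min\n", nrow(x$runs), x$params$T_total))
  cat(sprintf("  host richness: %s; phage richness: %s\n",
              paste(x$runs$host_richness, collapse = " "),
              paste(x$runs$phage_richness, collapse = " ")))
  if (!is.null(x$control))
    cat(sprintf("  no-phage control richness: %s\n",
                paste(x$control$host_richness, collapse = " ")))
  if (!is.null(x$late_correlations))
    cat(sprintf("  late-window growth-lysis r: min %.3f, median %.3f (%d windows)\n",
                min(x$late_correlations$r),
                stats::median(x$late_correlations$r),
                nrow(x$late_correlations)))
  invisible(x)
}

#' Paired evolvability comparison on one landscape
#'
#' For each seed, runs bacteria alone (\code{V_init = 0}) and bacteria
#' coevolving with phage on the same landscape with the same seed, so
#' the initial phage density is the only difference, and compares the
#' maximum growth factor reached by the final host community.
#'
#' @param landscape A \code{growth_landscape} (multi-peak, dynamic
#'   two-peak, or rugged-slope).
#' @param params A \code{chemostat_params}; following the paired design,
#'   typically with \code{M_V = 1e-5}.
#' @param seeds Integer vector of run seeds.
#' @return Data frame with one row per seed: final \code{max_delta}
#'   with phage (\code{max_delta_phage}) and alone
#'   (\code{max_delta_alone}), \code{improved} (strictly greater with
#'   phage), and discard flags.
#' @examples
#' \donttest{
#' p <- chemostat_params(T_total = 5e5, M_B = 1e-5, M_V = 1e-5)
#' run_paired_evolvability(landscape_multi_peak(4), p, seeds = 1:2)
#' }
#' @export
run_paired_evolvability <- function(landscape, params, seeds = 1:10) {
  rows <- lapply(seeds, function(sd) {
    tr1 <- simulate_chemostat(params, landscape, seed = sd)
    p0 <- update_params(params, V_init = 0)
    tr0 <- simulate_chemostat(p0, landscape, seed = sd)
    s1 <- run_summary(tr1, landscape, params)
    s0 <- run_summary(tr0, landscape, p0)
    data.frame(seed = sd,
               max_delta_phage = s1$max_delta,
               max_delta_alone = s0$max_delta,
               improved = s1$max_delta > s0$max_delta,
               range_edge = s1$range_edge | s0$range_edge)
  })
  do.call(rbind, rows)
}

#' Genotype-range sensitivity scan
#'
#' Ensemble scan of standing host genotype variation on the single-peak
#' landscape across resource supply \code{R0}, landscape floor
#' \code{delta_min}, and phage specificity \code{s}. Follows the scan
#' design: founders at the peak (\code{h_init = v_init = 0.5}) and
#' symmetric mutation rates \code{M_B = M_V = 1e-5}. Range-edge runs are
#' excluded from cell means.
#'
#' @param params Baseline \code{chemostat_params}; \code{T_total} sets
#'   the per-run horizon.
#' @param R0_values,delta_min_values,s_values Grid of manipulated values.
#' @param n_reps Replicates per cell.
#' @param master_seed Seed from which per-run seeds are derived.
#' @return Data frame with one row per grid cell: means, sds, and the
#'   number of retained replicates.
#' @examples
#' \donttest{
#' p <- chemostat_params(T_total = 5e5)
#' run_range_scan(p, R0_values = c(1.7, 2.7), delta_min_values = 0.8,
#'                s_values = c(100, 1000), n_reps = 2)
#' }
#' @export
run_range_scan <- function(params,
                           R0_values = c(1.7, 2.2, 2.7),
                           delta_min_values = c(0.8, 0.9, 1.0),
                           s_values = c(100, 300, 1000),
                           n_reps = 5, master_seed = 1) {
  grid <- expand.grid(R0 = R0_values, delta_min = delta_min_values,
                      s = s_values)
  seeds <- matrix(derive_seeds(master_seed, nrow(grid) * n_reps),
                  nrow(grid), n_reps)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    p <- update_params(params, R0 = grid$R0[g],
                       delta_min = grid$delta_min[g], s = grid$s[g],
                       h_init = 0.5, v_init = 0.5,
                       M_B = 1e-5, M_V = 1e-5)
    landscape <- landscape_single_peak(p$delta_min, p$delta_max, p$rho)
    res <- lapply(seeds[g, ], function(sd) {
      tr <- simulate_chemostat(p, landscape, seed = sd)
      run_summary(tr, landscape, p)
    })
    res <- do.call(rbind, res)
    keep <- !res$range_edge
    data.frame(R0 = grid$R0[g], delta_min = grid$delta_min[g],
               s = grid$s[g],
               mean_range = mean(res$genotype_range[keep]),
               sd_range = stats::sd(res$genotype_range[keep]),
               n_used = sum(keep), n_discarded = sum(!keep))
  })
  do.call(rbind, rows)
}

#' Rugged-slope adaptation ensemble
#'
#' For each smoothing window \code{span}, generates an ensemble of
#' rugged-slope landscapes; on each landscape runs bacteria alone and
#' coevolutionary runs across specificities \code{s}, all founded at
#' \code{h_init = v_init = 0.2}, and records the maximum growth factor
#' in the final community.
#'
#' @param params Baseline \code{chemostat_params} (\code{M_B = M_V =
#'   1e-5} per the ensemble design is applied on top).
#' @param spans Smoothing window widths (odd integers; 1 = most rugged).
#' @param s_values Specificities for the coevolutionary runs.
#' @param n_landscapes Landscapes per span.
#' @param master_seed Seed for landscape noise and run seeds.
#' @return Long data frame: one row per run, with \code{span},
#'   \code{landscape_id}, \code{s} (\code{NA} for the no-phage run),
#'   \code{max_delta}, the landscape's attainable \code{global_max},
#'   and the discard flag.
#' @examples
#' \donttest{
#' p <- chemostat_params(T_total = 5e5)
#' run_rugged_ensemble(p, spans = c(1, 7), s_values = 1000,
#'                     n_landscapes = 2)
#' }
#' @export
run_rugged_ensemble <- function(params, spans = c(1, 3, 5, 7),
                                s_values = c(100, 1000),
                                n_landscapes = 5, master_seed = 1) {
  base <- update_params(params, h_init = 0.2, v_init = 0.2,
                        M_B = 1e-5, M_V = 1e-5)
  ls_seeds <- derive_seeds(master_seed, length(spans) * n_landscapes)
  run_seeds <- derive_seeds(master_seed + 1L,
                            length(spans) * n_landscapes)
  rows <- list()
  k <- 0L
  for (sp in spans) {
    for (lk in seq_len(n_landscapes)) {
      k <- k + 1L
      landscape <- landscape_rugged_slope(sp, seed = ls_seeds[k],
                                          delta_min = base$delta_min,
                                          delta_max = base$delta_max,
                                          rho = base$rho)
      gm <- max(landscape_delta(landscape))
      p0 <- update_params(base, V_init = 0)
      tr0 <- simulate_chemostat(p0, landscape, seed = run_seeds[k])
      s0 <- run_summary(tr0, landscape, p0)
      rows[[length(rows) + 1L]] <- data.frame(
        span = sp, landscape_id = k, s = NA_real_,
        max_delta = s0$max_delta, global_max = gm,
        range_edge = s0$range_edge)
      for (sv in s_values) {
        ps <- update_params(base, s = sv)
        tr <- simulate_chemostat(ps, landscape, seed = run_seeds[k])
        s1 <- run_summary(tr, landscape, ps)
        rows[[length(rows) + 1L]] <- data.frame(
          span = sp, landscape_id = k, s = sv,
          max_delta = s1$max_delta, global_max = gm,
          range_edge = s1$range_edge)
      }
    }
  }
  do.call(rbind, rows)
}

#' One-at-a-time parameter sensitivity
#'
#' Runs ensembles with each of \code{R0}, \code{gamma}, \code{K},
#' \code{omega}, \code{eps}, \code{beta}, \code{phi} increased and
#' decreased by \code{factor}, and reports the ensemble-mean final state
#' (resource, total densities, host and phage richness) normalised to
#' the benchmark parameterisation.
#'
#' @param params Benchmark \code{chemostat_params}.
#' @param factor Multiplicative perturbation (default 1.5: x1.5 and
#'   /1.5).
#' @param n_reps Replicates per parameterisation.
#' @param master_seed Seed from which run seeds are derived.
#' @return Data frame: one row per (parameter, direction) plus the
#'   benchmark row, with normalised \code{R}, \code{total_N},
#'   \code{total_V}, \code{host_richness}, \code{phage_richness}.
#' @examples
#' \donttest{
#' p <- chemostat_params(T_total = 5e5)
#' run_parameter_sensitivity(p, n_reps = 2)
#' }
#' @export
run_parameter_sensitivity <- function(params, factor = 1.5, n_reps = 3,
                                      master_seed = 1) {
  pars <- c("R0", "gamma", "K", "omega", "eps", "beta", "phi")
  cases <- rbind(data.frame(parameter = "benchmark", direction = "none",
                            stringsAsFactors = FALSE),
                 expand.grid(parameter = pars,
                             direction = c("up", "down"),
                             stringsAsFactors = FALSE))
  seeds <- derive_seeds(master_seed, n_reps)
  landscape <- landscape_single_peak(params$delta_min, params$delta_max,
                                     params$rho)
  ens <- function(p) {
    res <- lapply(seeds, function(sd) {
      tr <- simulate_chemostat(p, landscape, seed = sd)
      run_summary(tr, landscape, p)
    })
    res <- do.call(rbind, res)
    keep <- !res$range_edge
    colMeans(res[keep, c("R_final", "total_N", "total_V",
                         "host_richness", "phage_richness")])
  }
  out <- lapply(seq_len(nrow(cases)), function(i) {
    p <- params
    if (cases$parameter[i] != "benchmark") {
      f <- if (cases$direction[i] == "up") factor else 1 / factor
      repl <- list(unclass(params)[[cases$parameter[i]]] * f)
      names(repl) <- cases$parameter[i]
      p <- do.call(update_params, c(list(params), repl))
    }
    m <- ens(p)
    data.frame(parameter = cases$parameter[i],
               direction = cases$direction[i],
               R = m[["R_final"]], total_N = m[["total_N"]],
               total_V = m[["total_V"]],
               host_richness = m[["host_richness"]],
               phage_richness = m[["phage_richness"]])
  })
  out <- do.call(rbind, out)
  bench <- out[out$parameter == "benchmark", ]
  for (cn in c("R", "total_N", "total_V", "host_richness",
               "phage_richness"))
    out[[paste0(cn, "_norm")]] <- out[[cn]] / bench[[cn]]
  out
}

#' Mutation-rate asymmetry check
#'
#' Compares coevolutionary persistence of phage when the phage mutation
#' rate is far below the host rate (\code{M_V = 1e-7} vs
#' \code{M_B = 1e-5}) against the symmetric case \code{M_V = M_B}: with
#' slow-mutating phage unable to track their evolving hosts, phage go
#' extinct in most runs.
#'
#' @param params Baseline \code{chemostat_params}.
#' @param n_seeds Seeds per arm.
#' @param M_B,M_V_low Host rate and the depressed phage rate.
#' @param master_seed Seed from which run seeds are derived.
#' @return Data frame with one row per (arm, seed):
#'   \code{phage_extinct} is \code{TRUE} when no phage remain at the end
#'   of the run.
#' @examples
#' \donttest{
#' p <- chemostat_params(T_total = 5e5)
#' run_mutation_asymmetry(p, n_seeds = 2)
#' }
#' @export
run_mutation_asymmetry <- function(params, n_seeds = 5, M_B = 1e-5,
                                   M_V_low = 1e-7, master_seed = 1) {
  seeds <- derive_seeds(master_seed, n_seeds)
  landscape <- landscape_single_peak(params$delta_min, params$delta_max,
                                     params$rho)
  arm <- function(name, p) {
    rows <- lapply(seeds, function(sd) {
      tr <- simulate_chemostat(p, landscape, seed = sd)
      fin <- state_at(tr, -1)
      data.frame(arm = name, seed = sd,
                 phage_extinct = sum(fin$V) == 0,
                 host_richness = strain_richness(fin, "host"),
                 range_edge = tr$range_edge)
    })
    do.call(rbind, rows)
  }
  rbind(arm("asymmetric", update_params(params, M_B = M_B, M_V = M_V_low)),
        arm("symmetric", update_params(params, M_B = M_B, M_V = M_B)))
}
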