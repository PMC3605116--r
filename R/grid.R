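#' Genotype grid and binning
#'
#' Genotypes live on the unit interval and are binned at resolution
#' \code{rho}: bin \eqn{k} has centre \eqn{k \rho}, so for the default
#' \code{rho = 0.01} there are 101 bins with centres 0, 0.01, ..., 1.
#' All strain bookkeeping, landscape tabulation, and strict-match
#' infection tests operate on bin indices, never on floating-point trait
#' comparisons.
#'
#' @param rho Bin resolution (default 0.01).
#' @return \code{genotype_grid} returns the vector of bin centres.
#' @examples
#' length(genotype_grid())      # 101
#' genotype_bin(0.204)          # 20: nearest bin centre is 0.20
#' bin_centre(20)
#' @export
genotype_grid <- function(rho = 0.01) {
  n <- n_bins(rho)
  (seq_len(n) - 1L) * rho
}

n_bins <- function(rho = 0.01) {
  n <- round(1 / rho) + 1L
  if (abs((n - 1L) * rho - 1) > 1e-9)
    stop("rho must divide [0, 1] into a whole number of bins", call. = FALSE)
  as.integer(n)
}

#' @rdname genotype_grid
#' @param h Genotype value(s); may lie outside [0, 1] (mutation edge
#'   handling checks the returned index against the grid).
#' @return \code{genotype_bin} returns 0-based bin indices
#'   (\code{round(h / rho)}).
#' @export
genotype_bin <- function(h, rho = 0.01) {
  as.integer(round(h / rho))
}

#' @rdname genotype_grid
#' @param bin 0-based bin index.
#' @return \code{bin_centre} returns the genotype at a bin centre.
#' @export
bin_centre <- function(bin, rho = 0.01) {
  bin * rho
}
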