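# Internal helpers.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Keeps landscape construction deterministic without
# disturbing the simulation's global RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Centred moving average; edge windows shrink symmetrically (half-width
# min(hw, i-1, n-i)) so the window always stays centred. A centred mean
# preserves any linear signal exactly, so smoothing never distorts the
# underlying slope — only the noise is averaged away.
moving_average <- function(y, span) {
  if (span %% 2 == 0 || span < 1)
    stop("span must be an odd positive integer", call. = FALSE)
  if (span == 1) return(y)
  n <- length(y)
  hw <- (span - 1L) / 2L
  vapply(seq_len(n), function(i) {
    w <- min(hw, i - 1L, n - i)
    mean(y[(i - w):(i + w)])
  }, numeric(1))
}

stop_invalid <- function(...) stop(..., call. = FALSE)
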