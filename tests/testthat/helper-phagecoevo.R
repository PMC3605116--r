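# Shared fixtures: benchmark parameters and small toy communities, built
# in code at test time.

bench_params <- function(...) chemostat_params(...)

# A toy occupied state with a few host and phage strains.
toy_state <- function(R = 2,
                      hosts = data.frame(h = c(0.2, 0.3, 0.5),
                                         N = c(1e4, 5e4, 2e4)),
                      phages = data.frame(v = c(0.2, 0.45),
                                          V = c(1e5, 3e5)),
                      t = 0) {
  community_state(R, hosts, phages, t = t)
}

# Literal transcription of the printed phage-free density formula
# (nested fraction), kept independent of the package's simplified form.
nbar_printed <- function(delta, p) {
  rb <- p$omega * p$K / (p$gamma * delta - p$omega)
  -p$omega * (rb - p$R0) * (rb + p$K) / (p$eps * p$gamma * delta * rb)
}

# Random valid parameter sets for equivalence spot checks.
random_params <- function() {
  chemostat_params(
    omega = runif(1, 1e-4, 1e-2),
    R0 = runif(1, 1, 5),
    eps = 10^runif(1, -7, -5),
    gamma = runif(1, 5e-3, 5e-2),
    K = runif(1, 1, 8),
    phi = 10^runif(1, -10, -8),
    beta = runif(1, 10, 200))
}
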