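# Shared fixtures. Everything is generated in code; the expensive study-scale
# sweep is computed once per session and reused by the acceptance tests.

.eidyn_cache <- new.env(parent = emptyenv())

with_seed <- withr::with_seed

# Full-scale single-coupling sweep at the study conditions: 78 regions,
# Vd2 in 6..8 by 0.5 at S = 1, 10 runs x 4096 samples, three band/delay
# conditions. Used by the acceptance suite.
study_sweep <- function() {
  if (is.null(.eidyn_cache$sweep)) {
    cfg <- study_config(s_grid = 1, base_seed = 101)
    .eidyn_cache$sweep <- run_study(cfg)
  }
  .eidyn_cache$sweep
}

# Small, fast sweep for the orchestration unit tests.
small_sweep <- function() {
  if (is.null(.eidyn_cache$small)) {
    .eidyn_cache$small <- run_study(small_config(),
                                    connectome = small_connectome())
  }
  .eidyn_cache$small
}

small_connectome <- function(n = 16, seed = 7) {
  synthetic_connectome(n_regions = n, edge_density = 0.3, seed = seed)
}

small_config <- function() {
  study_config(
    vd2_grid = c(6.5, 7, 7.5), s_grid = 1,
    runs_per_model = 2, samples_per_run = 512, burn_in = 300,
    conditions = tibble::tibble(
      condition = c("broadband_tau1", "alpha_tau1"),
      low = c(0.5, 6), high = c(70, 13), tau = c(1L, 1L)
    ),
    base_seed = 11
  )
}

# naive per-window ordinal symbolizer used as the independent oracle:
# order() with earlier-index tie-breaking, Lehmer-coded by explicit counting
oracle_symbolize <- function(x, n = 4, tau = 1) {
  L <- length(x) - (n - 1) * tau
  f <- rev(cumprod(c(1, seq_len(n - 1))))
  vapply(seq_len(L), function(t) {
    w <- x[t + (0:(n - 1)) * tau]
    sigma <- order(w) - 1L         # order() breaks ties by index
    code <- 0
    for (i in seq_len(n - 1)) {
      code <- code + sum(sigma[(i + 1):n] < sigma[i]) * f[i]
    }
    code
  }, numeric(1))
}

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}
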