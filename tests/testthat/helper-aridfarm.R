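# Shared fixtures: a small watershed and a compact farm configuration keep the
# unit tests fast; experiment-scale objects are built only where a test needs
# them.

small_watershed <- function(seed = 11) {
  make_synthetic_watershed(seed = seed, n_rows = 30, n_cols = 24)
}

small_config <- function(...) {
  sim_config(
    years = 3, n_farms = 4, grape_per_farm = 1, wheat_per_farm = 1,
    runoff_ratio = 10, reserve_sites = 4,
    n_rows = 30, n_cols = 24, ...
  )
}

# independent textbook SCS-CN oracle, written in US-customary units on purpose
# so it shares no code path with the implementation
scs_oracle_mm <- function(p_mm, cn, lambda = 0.2) {
  p_in <- p_mm / 25.4
  s_in <- 1000 / cn - 10
  ia_in <- lambda * s_in
  q_in <- if (p_in > ia_in) (p_in - ia_in)^2 / (p_in - ia_in + s_in) else 0
  q_in * 25.4
}
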