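# shared fixtures: small, fast configurations used across test files

default_flow <- function(...) flow_params(...)

# a sparse, quick configuration: few particles, coarse step, one cycle
tiny_config <- function(N = 40L, A_f = 1e-3, B_f = 4e-3, dt = 1e-4,
                        n_cycles = 1L, seed = 42L, ...) {
  flow <- flow_params(A_f = A_f, B_f = B_f)
  simulation_config(flow = flow, N = N, dt = dt, n_cycles = n_cycles,
                    seed = seed, ...)
}

# independent all-pairs aggregation detection in plain R (oracle)
brute_close_pairs <- function(pos, L, cutoff) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- pos[i, 1] - pos[j, 1]
      dx <- dx - L * round(dx / L)
      if (dx^2 + (pos[i, 2] - pos[j, 2])^2 < cutoff^2) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# independent brute-force pair-force accumulation in plain R (oracle)
brute_pair_forces <- function(mp, fp, pos) {
  n <- nrow(pos)
  f <- matrix(0, n, 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- pos[i, 1] - pos[j, 1]
      dx <- dx - fp$L * round(dx / fp$L)
      dy <- pos[i, 2] - pos[j, 2]
      d <- sqrt(dx^2 + dy^2)
      nij <- c(dx, dy) / d
      fij <- elastic_force(mp, d, nij) + aggregation_force(mp, d, nij)
      f[i, ] <- f[i, ] + fij
      f[j, ] <- f[j, ] - fij
    }
  }
  f
}
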