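# Shared fixtures: tiny configs and independent oracles used across tests.

tiny_config <- function(..., grid_dims = c(12L, 12L, 10L),
                        n_per_group = c(3L, 3L), seed = 11L) {
  simulation_config(grid_dims = grid_dims, seed = seed,
                    n_per_group = n_per_group, ...)
}

# Independent flood-fill oracle for connected-component counting: plain
# recursive stack-based fill over an explicit neighbour test, sharing no
# code with label_clusters().
flood_fill_components <- function(bin, connectivity) {
  dims <- dim(bin)
  seen <- array(FALSE, dims)
  comps <- list()
  conn_ok <- function(d) {
    s <- sum(d != 0L)
    if (connectivity == 6L) s == 1L
    else if (connectivity == 18L) s <= 2L && s >= 1L
    else s >= 1L
  }
  for (i0 in seq_len(dims[1L])) for (j0 in seq_len(dims[2L]))
    for (k0 in seq_len(dims[3L])) {
      if (!bin[i0, j0, k0] || seen[i0, j0, k0]) next
      stack <- list(c(i0, j0, k0))
      seen[i0, j0, k0] <- TRUE
      members <- integer(0)
      while (length(stack) > 0L) {
        v <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        members <- c(members,
                     v[1L] + dims[1L] * (v[2L] - 1L) +
                     dims[1L] * dims[2L] * (v[3L] - 1L))
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
          if (di == 0L && dj == 0L && dk == 0L) next
          if (!conn_ok(c(di, dj, dk))) next
          w <- v + c(di, dj, dk)
          if (any(w < 1L) || any(w > dims)) next
          if (bin[w[1L], w[2L], w[3L]] && !seen[w[1L], w[2L], w[3L]]) {
            seen[w[1L], w[2L], w[3L]] <- TRUE
            stack[[length(stack) + 1L]] <- w
          }
        }
      }
      comps[[length(comps) + 1L]] <- sort(members)
    }
  comps
}

# Brute-force single-sided amplitude spectrum via stats::fft, the oracle
# for the basis-product implementation.
fft_amplitude <- function(x, bins0) {
  (2 / length(x)) * Mod(stats::fft(x)[bins0 + 1L])
}
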