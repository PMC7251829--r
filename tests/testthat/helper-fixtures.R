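# Shared fixtures: one small configuration and matrix pair reused across
# test files.  Everything is generated in code under fixed seeds.

fx_config <- sim_config(seed = 1)
fx_matrices <- make_transition_matrices(fx_config)

fx_config_clean <- sim_config(seed = 2, noise_sd = 0)

# deterministic reference sequences
fx_genome <- random_genome(c(chrS = 6000), seed = 3)

# a profile tibble from vectors
prof_tbl <- function(position, value, read_id = "r1", chrom = "chrS") {
  tibble::tibble(read_id = read_id, chrom = chrom,
                 position = position, value = value)
}

# breakpoints tibble as segment_profile would emit
bp_tbl <- function(position, value) {
  tibble::tibble(position = position, value = value, index = seq_along(position))
}

# independent recursive Ramer-Douglas-Peucker oracle (vertical deviation)
rdp_oracle <- function(x, y, eps) {
  n <- length(x)
  if (n <= 2L) return(rep(TRUE, n))
  slope <- (y[n] - y[1]) / (x[n] - x[1])
  dev <- abs(y - (y[1] + (x - x[1]) * slope))
  dev[c(1L, n)] <- 0
  m <- which.max(dev)
  if (dev[m] <= eps) {
    keep <- rep(FALSE, n)
    keep[c(1L, n)] <- TRUE
    return(keep)
  }
  left <- rdp_oracle(x[1:m], y[1:m], eps)
  right <- rdp_oracle(x[m:n], y[m:n], eps)
  c(left, right[-1L])
}

# brute-force connected components of the gap < mied graph, per chromosome
cluster_oracle <- function(chrom, midpoint, mied) {
  out <- integer(length(midpoint))
  lab <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- midpoint[idx]
    adj <- abs(outer(p, p, "-")) < mied
    comp <- rep(0L, length(p))
    for (i in seq_along(p)) {
      if (comp[i] == 0L) {
        lab <- lab + 1L
        frontier <- i
        comp[i] <- lab
        while (length(frontier)) {
          nb <- which(adj[frontier[1], ] & comp == 0L)
          comp[nb] <- lab
          frontier <- c(frontier[-1], nb)
        }
      }
    }
    out[idx] <- comp
  }
  out
}
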