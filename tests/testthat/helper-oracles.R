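# Brute-force oracles for the order-statistic primitives, written directly
# from the definitions and independent of the implementation.
oracle_critical_count <- function(counts, p) {
  xs <- sort(counts)
  n <- length(xs)
  best <- NA
  for (i in seq_len(n)) { # largest index whose suffix proportion >= p
    if ((n - i + 1) / n >= p - 1e-12) best <- xs[i]
  }
  best
}

oracle_aggregate <- function(values, m) {
  xs <- sort(values)
  n <- length(xs)
  for (i in seq_len(n)) { # smallest order statistic covering proportion m
    if (i / n >= m - 1e-12) return(xs[i])
  }
}

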