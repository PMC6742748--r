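# Shared fixture builders: everything is generated in code at test time.

make_profile <- function(positions, counts, strand = "+", L = 2000,
                         label = "TAP_PLUS") {
  end_profile(L, strand, label, positions = positions, counts = counts)
}

make_genes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

# Build a tep_cluster directly from per-position counts on consecutive
# positions starting at `first`.
make_cluster <- function(counts, first = 1L, strand = "+") {
  pos <- which(counts > 0) + first - 1L
  cand <- data.frame(pos = pos, count = counts[counts > 0])
  cl <- cluster_teps(cand, strand, max_gap = length(counts) + 10L)
  stopifnot(length(cl) == 1L)
  cl[[1]]
}

# Independent brute-force oracle for the leave-one-out modified z-score:
# explicit recomputation of the moments by summation over the other cluster
# positions, with the same degenerate-case conventions.
oracle_zscore <- function(r, i) {
  n <- length(r)
  if (n == 1L) return(Inf)
  others <- r[-i]
  mu <- sum(others) / (n - 1)
  mu2 <- sum(others^2) / (n - 1)
  sigma <- sqrt(max(mu2 - mu^2, 0))
  if (sigma == 0) {
    if (r[i] > mu) Inf else 0
  } else {
    (r[i] - mu) / sigma
  }
}

# A quiet TAP(-) profile (all zero) for callers that need the pair.
zero_profile <- function(strand = "+", L = 2000, label = "TAP_MINUS") {
  end_profile(L, strand, label)
}

quiet_pair <- function(L = 2000, label = "TAP_MINUS") {
  list(plus = zero_profile("+", L, label), minus = zero_profile("-", L, label))
}
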