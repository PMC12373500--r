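# Shared fixtures and independent oracles. Everything is generated in
# code; no stored data files.

# minimal annotation: n_origins origins, 1 patient + n_pdx PDXs each
tiny_annotation <- function(n_origins = 4, n_pdx = 2, passage = 1L) {
  do.call(rbind, lapply(seq_len(n_origins), function(i) {
    origin <- sprintf("O%d", i)
    rbind(
      data.frame(sample_id = paste0(origin, "_P0"), origin = origin,
                 host = "human", passage = 0L, stringsAsFactors = FALSE),
      if (n_pdx > 0) data.frame(
        sample_id = sprintf("%s_P%d_R%d", origin, passage, seq_len(n_pdx)),
        origin = origin, host = "mouse", passage = passage,
        stringsAsFactors = FALSE)
    )
  }))
}

# brute-force Euclidean distance oracle (naive double loop)
oracle_distances <- function(std, pdx_ids, patient_ids, mets = rownames(std)) {
  D <- matrix(NA_real_, length(pdx_ids), length(patient_ids),
              dimnames = list(pdx_ids, patient_ids))
  for (i in pdx_ids) for (j in patient_ids) {
    D[i, j] <- sqrt(sum((std[mets, i] - std[mets, j])^2))
  }
  D
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper_tail <- function(hits, K, N, n) {
  i <- seq(hits, min(n, K))
  if (!length(i) || hits > min(n, K)) return(if (hits <= 0) 1 else 0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exhaustive isotope enumeration: mass-shift distribution of a fragment
# with j labelled tracer carbons, by expanding every atom's isotope state
oracle_shift_distribution <- function(counts, j, abundances, n_max) {
  atoms <- list()
  for (el in names(counts)) {
    n_at <- counts[[el]]
    if (el == "C") n_at <- n_at - j  # labelled carbons are fixed 13C
    if (n_at > 0) {
      atoms <- c(atoms, rep(list(abundances[[el]]), n_at))
    }
  }
  dist <- numeric(n_max + 1L)
  if (!length(atoms)) {
    if (j <= n_max) dist[j + 1L] <- 1
    return(dist)
  }
  grid <- do.call(expand.grid, lapply(atoms, function(a) seq_along(a) - 1L))
  prob <- do.call(expand.grid, lapply(atoms, identity))
  p <- apply(as.matrix(prob), 1L, prod)
  shift <- rowSums(as.matrix(grid)) + j
  for (r in seq_along(p)) {
    if (shift[r] <= n_max) dist[shift[r] + 1L] <- dist[shift[r] + 1L] + p[r]
  }
  dist
}

expect_all_close <- function(x, y, tol = 1e-9) {
  expect_lt(max(abs(x - y)), tol)
}
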