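# Independent brute-force implementations used as oracles. These use
# explicit loops and stats::sd directly, deliberately avoiding the
# covariance-identity route the package takes.

oracle_pv_matrix <- function(rq) {
  G <- nrow(rq)
  V <- matrix(0, G, G, dimnames = list(rownames(rq), rownames(rq)))
  for (j in seq_len(G)) for (k in seq_len(G)) if (j != k) {
    ratios <- numeric(ncol(rq))
    for (s in seq_len(ncol(rq))) ratios[s] <- log2(rq[j, s] / rq[k, s])
    V[j, k] <- sd(ratios)
  }
  V
}

oracle_m <- function(rq) {
  V <- oracle_pv_matrix(rq)
  m <- numeric(nrow(rq))
  for (j in seq_len(nrow(rq))) m[j] <- mean(V[j, -j])
  names(m) <- rownames(rq)
  m
}

oracle_cv <- function(rq) {
  out <- numeric(nrow(rq))
  for (j in seq_len(nrow(rq))) out[j] <- sd(rq[j, ]) / mean(rq[j, ])
  names(out) <- rownames(rq)
  out
}

oracle_nf <- function(rq, genes) {
  nf <- numeric(ncol(rq))
  for (s in seq_len(ncol(rq)))
    nf[s] <- prod(rq[genes, s])^(1 / length(genes))
  names(nf) <- colnames(rq)
  nf
}

oracle_v_series <- function(rq, order) {
  G <- length(order)
  v <- numeric(G - 2L)
  for (n in 2:(G - 1L)) {
    nf_n <- oracle_nf(rq, order[1:n])
    nf_n1 <- oracle_nf(rq, order[1:(n + 1L)])
    v[n - 1L] <- sd(log2(nf_n / nf_n1))
  }
  v
}

# random positive gene-by-sample matrix (log-normal on base-2 scale)
rand_rq <- function(genes, samples) {
  m <- matrix(2^rnorm(genes * samples, 0, 1), genes, samples,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("s", seq_len(samples))))
  m
}

# micro-fixture used across modules: constant-ratio pair plus one
# divergent gene
micro_rq <- function() rbind(A = c(1, 2), B = c(1, 2), C = c(1, 8))
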