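# Independent brute-force reference implementations used as oracles.
# These deliberately recompute everything with explicit loops and the
# textbook formulas, sharing no code with the package internals.

naive_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

naive_M <- function(q) {
  n <- nrow(q)
  m <- numeric(n)
  for (j in seq_len(n)) {
    vs <- numeric(0)
    for (k in seq_len(n)) {
      if (k == j) next
      vs <- c(vs, naive_sd(log2(q[j, ] / q[k, ])))
    }
    m[j] <- mean(vs)
  }
  names(m) <- rownames(q)
  m
}

naive_nf <- function(q, genes) {
  out <- numeric(ncol(q))
  for (s in seq_len(ncol(q))) {
    prod_q <- 1
    for (g in genes) prod_q <- prod_q * q[g, s]
    out[s] <- prod_q^(1 / length(genes))
  }
  names(out) <- colnames(q)
  out
}

naive_v_series <- function(q, best_first) {
  n_genes <- length(best_first)
  v <- numeric(n_genes - 2)
  for (n in 2:(n_genes - 1)) {
    nf_n <- naive_nf(q, best_first[1:n])
    nf_n1 <- naive_nf(q, best_first[1:(n + 1)])
    v[n - 1] <- naive_sd(log2(nf_n / nf_n1))
  }
  v
}

# Explicit group-mean sums of squares for the balanced fully nested
# three-level design, computed record by record.
naive_nested_ss <- function(d) {
  grand <- mean(d$log2_value)
  ss_gene <- 0; ss_cond <- 0; ss_rep <- 0
  for (g in unique(d$gene)) {
    dg <- d[d$gene == g, ]
    gm <- mean(dg$log2_value)
    ss_gene <- ss_gene + nrow(dg) * (gm - grand)^2
    for (cc in unique(dg$condition)) {
      dc <- dg[dg$condition == cc, ]
      cm <- mean(dc$log2_value)
      ss_cond <- ss_cond + nrow(dc) * (cm - gm)^2
      ss_rep <- ss_rep + sum((dc$log2_value - cm)^2)
    }
  }
  c(gene = ss_gene, condition = ss_cond, replicate = ss_rep)
}

random_positive_matrix <- function(n_genes, n_samples) {
  q <- matrix(2^rnorm(n_genes * n_samples, 0, 1), n_genes, n_samples)
  rownames(q) <- sprintf("g%02d", seq_len(n_genes))
  colnames(q) <- sprintf("s%02d", seq_len(n_samples))
  q
}
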