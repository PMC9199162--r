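# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the implementation they check.

# rank ratio by direct pairwise counting
oracle_rank_ratio <- function(v) {
  g <- length(v)
  out <- numeric(g)
  for (i in seq_len(g)) {
    below <- 0; tied <- 0
    for (j in seq_len(g)) {
      if (j == i) next
      if (v[j] < v[i]) below <- below + 1
      if (v[j] == v[i]) tied <- tied + 1
    }
    out[i] <- (below + 0.5 * tied) / (g - 1)
  }
  out
}

# full consensus table by double loop over (cell type, gene)
oracle_consensus <- function(counts, lognorm, labels, symbols) {
  res <- list()
  for (ct in unique(labels)) {
    cells <- which(labels == ct)
    g <- ncol(counts)
    freq <- numeric(g); expr <- numeric(g)
    for (j in seq_len(g)) {
      freq[j] <- sum(counts[cells, j] > 0) / length(cells)
      expr[j] <- mean(lognorm[cells, j])
    }
    fr <- oracle_rank_ratio(freq)
    er <- oracle_rank_ratio(expr)
    res[[ct]] <- data.frame(cell_type = ct, gene = symbols,
                            consensus = fr + er, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# smallest n per group whose normal-approximation power reaches the target
oracle_sample_size <- function(power, alpha, d, n_max = 10000) {
  z_a <- qnorm(1 - alpha / 2)
  for (n in 2:n_max) {
    achieved <- pnorm(d * sqrt(n / 2) - z_a)
    if (achieved >= power) return(n)
  }
  NA_integer_
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small annotated + normalized dataset used by several suites
small_sim <- function(seed = 3L, n_cells = 600, n_genes = 300) {
  p <- sim_params(n_cells = n_cells, n_genes = n_genes,
                  n_null_markers = 10, seed = seed)
  sim <- simulate_dataset(p)
  ds <- apply_truth_clusters(sim$dataset, sim$truth)
  list(dataset = normalize_log(ds), truth = sim$truth)
}
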