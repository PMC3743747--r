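# Independent brute-force oracles for the stability statistics.
# Deliberately naive (explicit loops, no shared code with the package)
# so that agreement is meaningful.

oracle_pairwise_variation <- function(qmat, j, k) {
  n <- ncol(qmat)
  x <- numeric(n)
  for (s in seq_len(n)) x[s] <- log2(qmat[j, s] / qmat[k, s])
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

oracle_m_value <- function(qmat, j, within = rownames(qmat)) {
  acc <- 0
  cnt <- 0
  for (k in within) {
    if (k == j) next
    acc <- acc + oracle_pairwise_variation(qmat, j, k)
    cnt <- cnt + 1
  }
  acc / cnt
}

# same contract as rank_stepwise: exclude max-M assay (ties: later in
# input order), final pair ordered by full-set M descending, ties by id
# (larger id first).
oracle_rank_stepwise <- function(qmat) {
  assays <- rownames(qmat)
  m_full <- sapply(assays, function(a) oracle_m_value(qmat, a, assays))
  current <- assays
  ranking <- character(0)
  while (length(current) > 2) {
    ms <- sapply(current, function(a) oracle_m_value(qmat, a, current))
    worst <- current[ms >= max(ms) - 1e-12]
    pick <- worst[length(worst)]
    ranking <- c(ranking, pick)
    current <- current[current != pick]
  }
  pair <- rev(current[order(m_full[current], current)])
  c(ranking, pair)
}

oracle_geomean <- function(v) prod(v)^(1 / length(v))

oracle_v_values <- function(qmat, ranking) {
  stable <- rev(ranking)
  k <- length(stable)
  nf <- function(n) {
    sapply(seq_len(ncol(qmat)),
           function(s) oracle_geomean(qmat[stable[1:n], s]))
  }
  v <- numeric(0)
  for (n in 2:(k - 1)) {
    x <- log2(nf(n) / nf(n + 1))
    mu <- mean(x)
    v <- c(v, sqrt(sum((x - mu)^2) / (length(x) - 1)))
  }
  stats::setNames(v, as.character(2:(k - 1)))
}

# fixtures built in code ------------------------------------------------------

rand_quantity_matrix <- function(n_assays, n_samples, seed) {
  set.seed(seed)
  q <- 2^matrix(stats::rnorm(n_assays * n_samples, 0, 1), n_assays, n_samples)
  dimnames(q) <- list(sprintf("g%02d", seq_len(n_assays)),
                      sprintf("s%02d", seq_len(n_samples)))
  quantity_matrix(q)
}

rand_instance <- function(n_assays, n_lists, seed) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n_assays)]
  lapply(seq_len(n_lists), function(i) {
    ranked_list(paste0("e", i), sample(ids), sort(stats::runif(n_assays)))
  })
}
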