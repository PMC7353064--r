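# Independent oracles used to validate the package's implementations.
# These deliberately use naive, brute-force strategies.

# Reflexive transitive closure by breadth-first search over is_a parents.
oracle_bfs_ancestors <- function(parents, term) {
  seen <- character()
  queue <- term
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, parents[[v]])
  }
  sort(seen)
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, m / seq(i, m) * ranked[seq(i, m)]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# P(X >= k) by exhaustive enumeration of all C(N, n) draws from an urn of
# N balls with K marked. Returns the tail for every k in 0..min(K, n).
oracle_hyper_tail_all <- function(K, n, N) {
  ks <- 0:min(K, n)
  if (n == 0L || N == 0L) {
    return(stats::setNames(as.numeric(ks == 0), ks))
  }
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # balls 1..K are the marked ones
  vapply(ks, function(k) mean(hits >= k), numeric(1)) |>
    stats::setNames(ks)
}

# Random DAG on n nodes; edges only point to lower indices, so it is
# acyclic by construction.
random_parents <- function(n, p_edge = 0.25) {
  ids <- sprintf("T%03d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    if (i == 1L) {
      parents[[i]] <- character()
      next
    }
    cand <- ids[seq_len(i - 1L)]
    parents[[i]] <- cand[stats::runif(length(cand)) < p_edge]
  }
  parents
}

random_dag <- function(n, p_edge = 0.25) {
  parents <- random_parents(n, p_edge)
  go_dag(tibble::tibble(id = names(parents), name = names(parents),
                        namespace = "cellular_component"),
         parents)
}
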