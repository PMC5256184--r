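# Slow, definitional implementations used as independent oracles for the
# graph metrics, plus small graph generators. Everything here is written
# from the textbook definitions (loops, BFS level counting) and shares no
# code with the package implementations.

random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1L, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

oracle_degree <- function(adj) {
  n <- nrow(adj)
  k <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) k[i] <- k[i] + adj[i, j]
  k
}

# BFS from one source: distances and number of distinct shortest paths.
bfs_counts <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  nsp <- numeric(n)
  dist[s] <- 0
  nsp[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1L)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) nsp[w] <- nsp[w] + nsp[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, nsp = nsp)
}

# Betweenness by direct evaluation of sum over ordered pairs (h, j) of
# sigma_hj(i) / sigma_hj, with sigma_hj(i) = nsp(h,i) * nsp(i,j) when i is
# on a shortest h-j path.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs <- lapply(seq_len(n), function(s) bfs_counts(adj, s))
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (h in seq_len(n)) {
      for (j in seq_len(n)) {
        if (h == j || h == i || j == i) next
        dhj <- bfs[[h]]$dist[j]
        if (is.infinite(dhj)) next
        if (bfs[[h]]$dist[i] + bfs[[i]]$dist[j] == dhj) {
          b[i] <- b[i] + bfs[[h]]$nsp[i] * bfs[[i]]$nsp[j] / bfs[[h]]$nsp[j]
        }
      }
    }
  }
  b
}

oracle_within_module_degree <- function(adj, mem) {
  n <- nrow(adj)
  z <- numeric(n)
  for (i in seq_len(n)) {
    peers <- which(mem == mem[i])
    k_in <- sapply(peers, function(v) sum(adj[v, peers]))
    mu <- mean(k_in)
    sig <- sqrt(sum((k_in - mu)^2) / length(k_in))
    ki <- sum(adj[i, peers])
    z[i] <- if (sig > 0) (ki - mu) / sig else 0
  }
  z
}

oracle_participation <- function(adj, mem) {
  n <- nrow(adj)
  p <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(adj[i, ])
    if (ki == 0) next
    acc <- 0
    for (m in unique(mem)) acc <- acc + (sum(adj[i, mem == m]) / ki)^2
    p[i] <- 1 - acc
  }
  p
}

# Newman modularity by the independent route (igraph's evaluator).
oracle_modularity <- function(adj, mem) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  igraph::modularity(g, mem)
}

# Planted-partition (stochastic block) binary graph.
planted_partition_graph <- function(n_per_block, n_blocks, p_in, p_out) {
  mem <- rep(seq_len(n_blocks), each = n_per_block)
  n <- length(mem)
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (mem[i] == mem[j]) p_in else p_out
      a[i, j] <- a[j, i] <- rbinom(1L, 1L, p)
    }
  }
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  list(adj = a, membership = mem)
}

# Two k-cliques joined by a single bridge edge between node 1 and node k+1.
two_clique_graph <- function(k = 5L) {
  n <- 2L * k
  a <- matrix(0L, n, n)
  a[seq_len(k), seq_len(k)] <- 1L
  a[(k + 1):n, (k + 1):n] <- 1L
  diag(a) <- 0L
  a[1L, k + 1L] <- a[k + 1L, 1L] <- 1L
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}
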