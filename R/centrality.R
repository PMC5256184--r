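# Nodal centrality metrics on binary undirected graphs, plus modularity
# partitioning. Degree, within-module degree, participation coefficient and
# the modularity value are computed directly from their definitions here;
# shortest-path counting (betweenness) and the Louvain heuristic go through
# igraph.

# Internal: validate a binary symmetric zero-diagonal adjacency matrix.
check_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) tn_stop("adjacency must be square")
  if (any(adj != 0 & adj != 1)) tn_stop("adjacency must be binary")
  if (any(diag(adj) != 0)) tn_stop("adjacency must have zero diagonal")
  if (any(adj != t(adj))) tn_stop("adjacency must be symmetric")
  adj
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Degree centrality
#'
#' Number of edges incident to each node of a binary undirected graph.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @return Named integer vector of node degrees.
#' @export
node_degree <- function(adj) {
  adj <- check_adjacency(adj)
  k <- rowSums(adj)
  storage.mode(k) <- "integer"
  k
}

#' Betweenness centrality
#'
#' Summed proportion of all-pairs shortest paths that pass through each
#' node. Ordered source/target pairs (h, j) with h != j != i are counted, so
#' each unordered pair contributes twice; unreachable pairs contribute
#' nothing. Optionally normalized by (N - 1)(N - 2), the number of ordered
#' pairs.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @param normalized Divide by (N - 1)(N - 2).
#' @return Named numeric vector.
#' @export
node_betweenness <- function(adj, normalized = FALSE) {
  adj <- check_adjacency(adj)
  b <- 2 * igraph::betweenness(as_igraph(adj), directed = FALSE)
  if (normalized) {
    n <- nrow(adj)
    if (n > 2) b <- b / ((n - 1) * (n - 2))
  }
  names(b) <- rownames(adj)
  b
}

#' Newman modularity of a given partition
#'
#' Direct evaluation of the binary undirected modularity
#' Q = (1 / 2m) * sum_ij (a_ij - k_i k_j / 2m) * delta(c_i, c_j).
#' Defined as 0 for an edgeless graph.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @param membership Integer module assignment per node.
#' @return Scalar Q in `[-1, 1]`.
#' @export
modularity_q <- function(adj, membership) {
  adj <- check_adjacency(adj)
  if (length(membership) != nrow(adj)) tn_stop("membership length mismatch")
  m2 <- sum(adj)  # 2m
  if (m2 == 0) return(0)
  k <- rowSums(adj)
  same <- outer(membership, membership, "==")
  sum((adj - outer(k, k) / m2) * same) / m2
}

#' Modularity-maximizing partition with random restarts
#'
#' Runs Louvain community detection `n_restarts` times, each restart on a
#' randomly permuted node ordering, and returns the partition with maximal
#' Newman modularity Q. Reproducible given `seed`; with the same seed, a
#' larger `n_restarts` extends the same restart stream, so the returned Q is
#' non-decreasing in `n_restarts`.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @param n_restarts Number of randomized restarts (default 100).
#' @param seed RNG seed for the restart stream.
#' @return A list of class `module_partition` with `membership` (named,
#'   modules labeled 1..M), `q`, `n_restarts_used`, `seed`.
#' @export
best_partition <- function(adj, n_restarts = 100L, seed = 1L) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  labels <- rownames(adj)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n_restarts < 1L) tn_stop("best_partition: n_restarts must be >= 1")
  if (sum(adj) == 0) {
    warning("best_partition: graph has no edges; single-module partition, Q = 0",
            call. = FALSE)
    return(structure(list(membership = setNames(rep(1L, n), labels), q = 0,
                          n_restarts_used = 0L, seed = as.integer(seed)),
                     class = "module_partition"))
  }
  best_q <- -Inf
  best_mem <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    perm <- sample.int(n)
    g <- as_igraph(adj[perm, perm, drop = FALSE])
    mem_perm <- as.integer(igraph::membership(igraph::cluster_louvain(g)))
    mem <- integer(n)
    mem[perm] <- mem_perm
    q <- modularity_q(adj, mem)
    if (q > best_q) {
      best_q <- q
      best_mem <- mem
    }
  }
  # relabel modules 1..M in order of first appearance
  best_mem <- match(best_mem, unique(best_mem))
  structure(list(membership = setNames(as.integer(best_mem), labels),
                 q = best_q, n_restarts_used = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d nodes in %d modules, Q = %.4f (%d restarts)\n",
              length(x$membership), length(unique(x$membership)), x$q,
              x$n_restarts_used))
  invisible(x)
}

as_membership_vector <- function(partition, n) {
  mem <- if (inherits(partition, "module_partition")) partition$membership else partition
  if (length(mem) != n) tn_stop("partition does not cover all nodes")
  as.integer(mem)
}

#' Within-module degree (z-score)
#'
#' For each node, the z-score of its intra-module degree against the
#' intra-module degree distribution of its own module (population standard
#' deviation). Defined as 0 when the module's degree spread is zero (this
#' covers singleton modules).
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @param partition A [best_partition()] result or membership vector.
#' @return Named numeric vector Z.
#' @export
within_module_degree <- function(adj, partition) {
  adj <- check_adjacency(adj)
  mem <- as_membership_vector(partition, nrow(adj))
  z <- numeric(nrow(adj))
  for (m in unique(mem)) {
    idx <- which(mem == m)
    k_in <- rowSums(adj[idx, idx, drop = FALSE])
    s <- sqrt(mean((k_in - mean(k_in))^2))
    z[idx] <- if (s > 0) (k_in - mean(k_in)) / s else 0
  }
  names(z) <- rownames(adj)
  z
}

#' Participation coefficient
#'
#' P_i = 1 - sum_m (K_im / K_i)^2, where K_im is the number of node i's
#' edges into module m and K_i its total degree. P is 0 for a node whose
#' edges all stay inside its own module and approaches 1 when they spread
#' uniformly over all modules. Defined as 0 for isolated nodes.
#'
#' @param adj Binary symmetric adjacency matrix with zero diagonal.
#' @param partition A [best_partition()] result or membership vector.
#' @return Named numeric vector P in `[0, 1]`.
#' @export
participation_coefficient <- function(adj, partition) {
  adj <- check_adjacency(adj)
  mem <- as_membership_vector(partition, nrow(adj))
  k <- rowSums(adj)
  p <- numeric(nrow(adj))
  mods <- unique(mem)
  k_im <- sapply(mods, function(m) rowSums(adj[, mem == m, drop = FALSE]))
  if (is.null(dim(k_im))) k_im <- matrix(k_im, nrow = nrow(adj))
  nz <- k > 0
  p[nz] <- 1 - rowSums((k_im[nz, , drop = FALSE] / k[nz])^2)
  names(p) <- rownames(adj)
  p
}

#' Full centrality profile of one subject
#'
#' For every density in the subject's adjacency stack: find the
#' modularity-maximizing partition, then compute degree, betweenness,
#' within-module degree and participation coefficient on that density's
#' graph against that density's partition. Density-averaged values per node
#' and metric are appended.
#'
#' @param stack An [threshold_by_density()] adjacency stack.
#' @param n_restarts Louvain restarts per density (default 100).
#' @param seed Seed for the restart streams (one derived stream per
#'   density).
#' @param normalized_betweenness Passed to [node_betweenness()].
#' @return A list of class `centrality_profile` with fields `subject_id`,
#'   `densities`, `q` (modularity per density), `metrics` (list of N x D
#'   matrices named degree, betweenness, within_module_degree,
#'   participation) and `averaged` (data.frame node x metric).
#' @export
profile_subject <- function(stack, n_restarts = 100L, seed = 1L,
                            normalized_betweenness = FALSE) {
  stopifnot(inherits(stack, "adjacency_stack"))
  n <- length(stack$node_labels)
  d_n <- length(stack$densities)
  metrics <- c("degree", "betweenness", "within_module_degree", "participation")
  out <- lapply(metrics, function(m)
    matrix(NA_real_, n, d_n,
           dimnames = list(stack$node_labels, names(stack$adj))))
  names(out) <- metrics
  q <- setNames(numeric(d_n), names(stack$adj))
  for (di in seq_len(d_n)) {
    adj <- stack$adj[[di]]
    part <- best_partition(adj, n_restarts,
                           seed = derive_seed(seed, names(stack$adj)[di]))
    q[di] <- part$q
    out$degree[, di] <- node_degree(adj)
    out$betweenness[, di] <- node_betweenness(adj, normalized_betweenness)
    out$within_module_degree[, di] <- within_module_degree(adj, part)
    out$participation[, di] <- participation_coefficient(adj, part)
  }
  averaged <- data.frame(node = stack$node_labels,
                         lapply(out, rowMeans),
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(subject_id = stack$subject_id, densities = stack$densities,
                 q = q, metrics = out, averaged = averaged),
            class = "centrality_profile")
}

#' @export
as.data.frame.centrality_profile <- function(x, ...) {
  long <- do.call(rbind, lapply(names(x$metrics), function(m) {
    mat <- x$metrics[[m]]
    data.frame(subject_id = x$subject_id,
               node = rep(rownames(mat), times = ncol(mat)),
               density = rep(x$densities, each = nrow(mat)),
               metric = m, value = as.vector(mat),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' Group-average network modules and intermodular links
#'
#' Averages connectivity matrices over subjects, thresholds the mean matrix
#' at one density (default 0.30), finds the modularity-maximizing partition,
#' and, for each query node, lists its neighbors annotated as same-module or
#' other-module. This is the group-level modular summary used to read off
#' which intermodular connections a hub has gained.
#'
#' @param matrices List of [correlation_matrix()] results with identical
#'   node labels.
#' @param density Single density at which to threshold the mean matrix.
#' @param query_nodes Character vector of node labels to summarize.
#' @param n_restarts,seed Passed to [best_partition()].
#' @return A list of class `group_network` with `partition`, `mean_r`,
#'   `adjacency`, and `query` (named list of data.frames with columns
#'   `neighbor`, `module`, `intermodular`).
#' @export
group_network_modules <- function(matrices, density = 0.30,
                                  query_nodes = character(0),
                                  n_restarts = 100L, seed = 1L) {
  if (length(matrices) < 2L) tn_stop("group_network_modules: need >= 2 matrices")
  labels <- matrices[[1L]]$node_labels
  for (m in matrices) {
    if (!identical(m$node_labels, labels)) {
      tn_stop("group_network_modules: node labels differ across matrices")
    }
  }
  if (!all(query_nodes %in% labels)) {
    tn_stop("group_network_modules: unknown query node(s): ",
            paste(setdiff(query_nodes, labels), collapse = ", "))
  }
  mean_r <- Reduce(`+`, lapply(matrices, `[[`, "r")) / length(matrices)
  cm <- structure(list(subject_id = "group_mean", node_labels = labels,
                       r = mean_r),
                  class = "connectivity_matrix")
  adj <- threshold_by_density(cm, density)$adj[[1L]]
  part <- best_partition(adj, n_restarts, seed)
  query <- lapply(setNames(query_nodes, query_nodes), function(qn) {
    nb <- labels[adj[qn, ] == 1L]
    data.frame(neighbor = nb,
               module = unname(part$membership[nb]),
               intermodular = unname(part$membership[nb] != part$membership[qn]),
               stringsAsFactors = FALSE)
  })
  structure(list(partition = part, mean_r = cm, adjacency = adj,
                 density = density, query = query),
            class = "group_network")
}
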