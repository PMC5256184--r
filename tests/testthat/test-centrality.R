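test_that("degree and betweenness reproduce closed-form small-graph values", {
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1L
  expect_equal(unname(node_degree(star)), c(4L, 1L, 1L, 1L, 1L))
  expect_true(all(node_degree(matrix(0L, 4, 4)) == 0L))

  # path graph a-b-c: the middle node carries both ordered pairs
  path <- matrix(0L, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1L
  expect_equal(unname(node_betweenness(path)), c(0, 2, 0))

  comp <- matrix(1L, 6, 6); diag(comp) <- 0L
  expect_true(all(node_betweenness(comp) == 0))

  set.seed(1)
  a <- random_adjacency(10, 0.4)
  expect_equal(sum(node_degree(a)), sum(a))  # handshake: sum K = 2|E|
})

test_that("metrics agree with brute-force definitional oracles on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.7))
    mem <- sample(1:3, n, replace = TRUE)
    expect_equal(unname(node_degree(a)), oracle_degree(a))
    expect_equal(unname(node_betweenness(a)), oracle_betweenness(a),
                 tolerance = 1e-10)
    expect_equal(unname(within_module_degree(a, mem)),
                 oracle_within_module_degree(a, mem), tolerance = 1e-10)
    expect_equal(unname(participation_coefficient(a, mem)),
                 oracle_participation(a, mem), tolerance = 1e-10)
    expect_equal(modularity_q(a, mem), oracle_modularity(a, mem),
                 tolerance = 1e-10)
  }
})

test_that("within-module degree follows the z-score convention", {
  # 4-node module with intra-degrees {3,1,1,1}: z of the first node is
  # (3 - 1.5) / sqrt(3/4)
  a <- matrix(0L, 4, 4)
  a[1, 2:4] <- a[2:4, 1] <- 1L
  z <- within_module_degree(a, rep(1L, 4))
  expect_equal(unname(z[1]), (3 - 1.5) / sqrt(0.75), tolerance = 1e-10)

  # equal intra-module degree: all zero (sigma = 0 rule)
  ring <- matrix(0L, 4, 4)
  ring[cbind(1:4, c(2, 3, 4, 1))] <- 1L
  ring <- ring | t(ring); storage.mode(ring) <- "integer"
  expect_true(all(within_module_degree(ring, rep(1L, 4)) == 0))

  # singleton module
  b <- matrix(0L, 3, 3); b[1, 2] <- b[2, 1] <- 1L
  expect_equal(unname(within_module_degree(b, c(1L, 1L, 2L))[3]), 0)
})

test_that("participation coefficient follows its defining formula", {
  # all links inside the node's own module -> 0
  a <- two_clique_graph(4)
  mem <- rep(1:2, each = 4)
  p <- participation_coefficient(a, mem)
  expect_equal(unname(p[3]), 0)  # node 3 has no bridge

  # 4 links split 2/2 across two modules -> 1 - (1/4 + 1/4) = 0.5
  b <- matrix(0L, 5, 5)
  b[1, 2:5] <- b[2:5, 1] <- 1L
  expect_equal(unname(participation_coefficient(b, c(1, 1, 1, 2, 2))[1]), 0.5)

  # isolated node -> 0 by convention
  c_ <- matrix(0L, 3, 3); c_[1, 2] <- c_[2, 1] <- 1L
  expect_equal(unname(participation_coefficient(c_, c(1, 1, 2))[3]), 0)

  # invariance under module relabeling
  set.seed(2)
  g <- random_adjacency(10, 0.5)
  mem2 <- sample(1:3, 10, replace = TRUE)
  relab <- c(7L, 9L, 8L)[mem2]
  expect_equal(participation_coefficient(g, mem2),
               participation_coefficient(g, relab))
})

test_that("modularity maximization recovers planted structure and maximal Q", {
  a <- two_clique_graph(5)
  part <- best_partition(a, n_restarts = 20, seed = 1)
  expect_equal(length(unique(part$membership)), 2L)
  expect_equal(unname(part$membership[1:5]), rep(part$membership[[1]], 5))
  # hand-derived Newman Q for the two-clique partition: 20/21 - 1/2
  expect_equal(part$q, 20 / 21 - 0.5, tolerance = 1e-12)

  # complete graph: no split beats the trivial partition
  comp <- matrix(1L, 8, 8); diag(comp) <- 0L
  pc <- best_partition(comp, n_restarts = 10, seed = 1)
  expect_lte(length(unique(pc$membership)), 2L)
  expect_lte(abs(pc$q), 1e-12)

  # edgeless graph: single module, Q = 0, with a warning
  expect_warning(pe <- best_partition(matrix(0L, 5, 5)), "no edges")
  expect_equal(unname(pe$membership), rep(1L, 5))
  expect_equal(pe$q, 0)

  # Q is non-decreasing in the restart count on the same seed stream
  set.seed(3)
  g <- planted_partition_graph(8, 3, 0.7, 0.15)$adj
  q5 <- best_partition(g, n_restarts = 5, seed = 7)$q
  q25 <- best_partition(g, n_restarts = 25, seed = 7)$q
  expect_gte(q25, q5)

  # determinism under a fixed seed
  expect_identical(best_partition(g, 10, seed = 11),
                   best_partition(g, 10, seed = 11))
})

test_that("subject profiles cover every density and average correctly", {
  set.seed(13)
  cm <- correlation_matrix(roi_ts(matrix(rnorm(100 * 15), 100, 15)))
  grid <- density_grid(0.15, 0.35, 0.05)
  stack <- threshold_by_density(cm, grid)
  pr <- profile_subject(stack, n_restarts = 5, seed = 2)
  expect_equal(dim(pr$metrics$degree), c(15L, 5L))
  expect_equal(unname(pr$averaged$degree), unname(rowMeans(pr$metrics$degree)))
  expect_true(all(pr$metrics$participation >= 0 & pr$metrics$participation <= 1))
  expect_true(all(pr$q >= -1 & pr$q <= 1))
  # per-density purity: the profile at one density equals a fresh
  # computation on that density's graph alone
  adj <- stack$adj[[3]]
  expect_equal(pr$metrics$degree[, 3], node_degree(adj))
  expect_equal(pr$metrics$betweenness[, 3], node_betweenness(adj))
  # long format export
  long <- as.data.frame(pr)
  expect_equal(nrow(long), 15 * 5 * 4)
  expect_setequal(unique(long$metric),
                  c("degree", "betweenness", "within_module_degree", "participation"))
})

test_that("relabeling nodes permutes profile outputs consistently", {
  # graph with unambiguous modular structure so the optimum is unique
  a <- two_clique_graph(5)
  stack <- structure(list(subject_id = "s", node_labels = rownames(a),
                          densities = 0.3, adj = list("0.300" = a)),
                     class = "adjacency_stack")
  pr <- profile_subject(stack, n_restarts = 10, seed = 4)
  perm <- sample(1:10)
  ap <- a[perm, perm]
  stackp <- structure(list(subject_id = "s", node_labels = rownames(ap),
                           densities = 0.3, adj = list("0.300" = ap)),
                      class = "adjacency_stack")
  prp <- profile_subject(stackp, n_restarts = 10, seed = 4)
  for (m in names(pr$metrics)) {
    expect_equal(pr$metrics[[m]][perm, 1], prp$metrics[[m]][, 1],
                 tolerance = 1e-10)
  }
})

test_that("group-average networks expose a hub's intermodular links", {
  # identical inputs: the mean matrix equals the input
  set.seed(14)
  cm <- correlation_matrix(roi_ts(matrix(rnorm(80 * 12), 80, 12)))
  gn <- group_network_modules(list(cm, cm), density = 0.3,
                              query_nodes = cm$node_labels[1],
                              n_restarts = 5, seed = 1)
  expect_equal(gn$mean_r$r, cm$r)

  # a node connected only within its own module has no intermodular links
  a <- two_clique_graph(5)
  r <- a * 0.8 + (1 - a) * 0.05
  diag(r) <- 0
  cm1 <- structure(list(subject_id = "a", node_labels = rownames(a), r = r),
                   class = "connectivity_matrix")
  gn2 <- group_network_modules(list(cm1, cm1), density = 21 / 45,
                               query_nodes = "n3", n_restarts = 10, seed = 1)
  expect_equal(sum(gn2$query$n3$intermodular), 0L)

  # mismatched labels fail fast
  cm_bad <- cm1
  cm_bad$node_labels <- rev(cm_bad$node_labels)
  expect_error(group_network_modules(list(cm1, cm_bad), 0.3), "labels differ")
})
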