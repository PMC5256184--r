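# Builds a minimal profile list directly from a subjects x densities value
# matrix, so the statistical machinery can be tested in isolation from the
# graph stages.
fake_profiles <- function(y, node = "hub", metric = "degree") {
  lapply(rownames(y), function(sid) {
    m <- matrix(y[sid, ], nrow = 1, dimnames = list(node, NULL))
    metrics <- setNames(rep(list(m), 4),
                        c("degree", "betweenness", "within_module_degree",
                          "participation"))
    structure(list(subject_id = sid, densities = seq_len(ncol(y)),
                   q = rep(0.5, ncol(y)), metrics = metrics,
                   averaged = data.frame(node = node, degree = mean(m))),
              class = "centrality_profile")
  })
}

fake_cohort <- function(groups, seed = 1) {
  set.seed(seed)
  n <- length(groups)
  data.frame(subject_id = sprintf("s%02d", seq_len(n)), group = groups,
             age = runif(n, 45, 70), sex = rbinom(n, 1, 0.5),
             stringsAsFactors = FALSE)
}

test_that("a large constant group shift is detected decisively", {
  set.seed(21)
  groups <- rep(c("TP", "NTP", "HC"), each = 10)
  y <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(sprintf("s%02d", 1:30), NULL))
  y[groups == "TP", ] <- y[groups == "TP", ] + 5
  res <- rm_ancova(fake_profiles(y), fake_cohort(groups), "hub", "degree")
  expect_lt(res$group_p, 1e-6)
  expect_equal(res$group_df[1], 2)
  # post hoc contrasts isolate the shifted group
  ph <- res$posthoc
  involves_tp <- vapply(strsplit(ph$contrast, " - "),
                        function(x) "TP" %in% x, logical(1))
  expect_true(all(ph$p[involves_tp] < 1e-4))
  expect_gt(min(ph$p[!involves_tp]), 0.05)
  # within-subject table carries Greenhouse-Geisser output
  expect_true(all(c("gg_epsilon", "p_gg") %in% names(res$within)))
  expect_true(all(res$within$gg_epsilon <= 1 + 1e-8))
})

test_that("without covariates the balanced two-group F equals the squared t", {
  set.seed(22)
  groups <- rep(c("A", "B"), each = 12)
  y <- matrix(rnorm(24 * 6), 24, 6, dimnames = list(sprintf("s%02d", 1:24), NULL))
  y[groups == "B", ] <- y[groups == "B", ] + 0.8
  res <- rm_ancova(fake_profiles(y), fake_cohort(groups), "hub", "degree",
                   covariates = character(0))
  tt <- t.test(rowMeans(y) ~ groups, var.equal = TRUE)
  expect_equal(res$group_f, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(res$group_p, tt$p.value, tolerance = 1e-6)
})

test_that("degenerate designs fail with informative errors", {
  groups <- c("TP", "TP", "NTP", "NTP", "NTP", "HC", "HC", "HC")
  y <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(sprintf("s%02d", 1:8), NULL))
  expect_error(rm_ancova(fake_profiles(y), fake_cohort(groups), "hub", "degree"),
               "at least 3 subjects")
  groups2 <- rep(c("TP", "NTP", "HC"), each = 4)
  y2 <- matrix(1, 12, 4, dimnames = list(sprintf("s%02d", 1:12), NULL))
  expect_error(rm_ancova(fake_profiles(y2), fake_cohort(groups2), "hub", "degree"),
               "constant")
})

test_that("partial correlation reduces to Pearson and recovers planted values", {
  set.seed(23)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)

  expect_equal(partial_correlation(x, x + 0)$r, 1)
  expect_error(partial_correlation(x, rep(1, 40)), "degenerate")

  # trivariate Gaussian with known partial correlation 0.5 at n = 10,000
  set.seed(24)
  n <- 10000
  w <- rnorm(n)
  e1 <- rnorm(n)
  e2 <- 0.5 * e1 + sqrt(0.75) * rnorm(n)
  xx <- 1.5 * w + e1
  yy <- -0.7 * w + e2
  pc2 <- partial_correlation(xx, yy, cbind(w))
  expect_lt(abs(pc2$r - 0.5), 0.03)
  # and confounding is actually removed (marginal correlation differs)
  expect_gt(abs(cor(xx, yy) - 0.5), 0.1)
})

test_that("derived UPDRS scores follow the item definitions", {
  items <- data.frame(item16 = 1, item20 = 4, item21 = 3, item22 = 2,
                      item23 = 1, item24 = 2, item25 = 0, item26 = 3)
  out <- score_definitions(items)
  expect_equal(out$resting_tremor, 4)
  expect_equal(out$total_tremor, 8)
  expect_equal(out$bradykinesia, 6)
  expect_equal(out$rigidity, 2)

  zeros <- items; zeros[] <- 0
  z <- score_definitions(zeros)
  expect_true(all(z[c("resting_tremor", "total_tremor", "bradykinesia",
                      "rigidity")] == 0))

  expect_error(score_definitions(items[-2]), "item20")
})

test_that("the specificity screen reports one row per node/metric/score", {
  set.seed(25)
  groups <- rep("TP", 12)
  y <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(sprintf("s%02d", 1:12), NULL))
  cohort <- fake_cohort(groups)
  cohort$tremor_score <- rowMeans(y) + rnorm(12, 0, 0.3)
  cohort$bradykinesia <- rnorm(12)
  rep1 <- specificity_screen(fake_profiles(y), cohort, "hub", "degree",
                             "tremor_score")
  expect_equal(nrow(rep1), 1L)
  rep2 <- specificity_screen(fake_profiles(y), cohort, "hub",
                             c("degree", "participation"),
                             c("tremor_score", "bradykinesia"))
  expect_equal(nrow(rep2), 4L)
  expect_match(attr(rep2, "correction_note"), "no multiple-comparison")

  # a permuted score column kills the association on average
  set.seed(26)
  rs <- replicate(60, {
    cohort$perm <- sample(cohort$tremor_score)
    specificity_screen(fake_profiles(y), cohort, "hub", "degree", "perm")$r
  })
  expect_lt(abs(mean(rs)), 0.12)
})
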