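test_that("design validation rejects inconsistent module and correlation settings", {
  expect_error(cohort_design(n_nodes = 10, module_sizes = c(4, 4)), "sum to n_nodes")
  expect_error(cohort_design(n_nodes = 10, module_sizes = c(9, 1)), ">= 2")
  expect_error(cohort_design(within_module_corr = 0.2, between_module_corr = 0.3),
               "between_module_corr < within_module_corr")
  expect_error(cohort_design(hub_node = 999), "out of range")
  expect_error(cohort_design(affected_groups = "XX"), "subset of groups")
})

test_that("generation is reproducible from the seed and honors group structure", {
  design <- cohort_design(n_per_group = 2, n_nodes = 12, n_timepoints = 40,
                          burn_in = 5, module_sizes = c(6, 6), hub_node = 1,
                          seed = 99)
  a <- build_cohort(design)
  b <- build_cohort(design)
  expect_identical(lapply(a, `[[`, "timeseries"), lapply(b, `[[`, "timeseries"))
  expect_identical(cohort_table(a), cohort_table(b))

  tab <- cohort_table(a)
  expect_equal(nrow(tab), 6L)
  expect_equal(sort(unique(tab$group)), sort(c("TP", "NTP", "HC")))
  # tremor score: zero outside affected groups, nonnegative everywhere
  expect_true(all(tab$tremor_score[tab$group != "TP"] == 0))
  expect_true(all(tab$tremor_score >= 0))
  expect_true(all(tab$planted_hub_effect[tab$group != "TP"] == 0))
  # raw series includes the burn-in volumes
  expect_equal(nrow(a[[1]]$timeseries$values), 45L)
  expect_equal(nrow(a[[1]]$nuisance), 45L)
})

test_that("empirical correlations converge to the planted block structure", {
  design <- cohort_design(n_per_group = 1, groups = "HC", affected_groups = character(0),
                          n_nodes = 12, n_timepoints = 20000, burn_in = 0,
                          module_sizes = c(6, 6), hub_boost = 0,
                          nuisance_mix = 0, seed = 5)
  co <- build_cohort(design)
  emp <- cor(co[[1]]$timeseries$values)
  target <- matrix(0.1, 12, 12)
  target[1:6, 1:6] <- 0.5
  target[7:12, 7:12] <- 0.5
  diag(target) <- 1
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("PSD repair returns a unit-diagonal positive semi-definite matrix", {
  r <- matrix(0.1, 8, 8)
  r[1:4, 1:4] <- 0.6
  r[5:8, 5:8] <- 0.6
  diag(r) <- 1
  r[1, 5:8] <- r[5:8, 1] <- 0.95  # hub edit that breaks PSD
  expect_lt(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), 0)
  fixed <- tremornet:::psd_repair(r)
  expect_equal(diag(fixed), rep(1, 8))
  expect_gte(min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # an already-PSD matrix passes through unchanged
  ok <- diag(8)
  expect_identical(tremornet:::psd_repair(ok), ok)
})

test_that("with no hub boost the hub is exchangeable with its module peers", {
  # over replicate cohorts the hub tops its module's participation ranking
  # about 1/module-size of the time
  n_rep <- 120
  top <- logical(n_rep)
  module <- 1:5  # hub 1 sits in a 5-node module
  for (i in seq_len(n_rep)) {
    design <- cohort_design(n_per_group = 1, groups = "TP", n_nodes = 20,
                            n_timepoints = 150, burn_in = 0,
                            module_sizes = c(5, 5, 5, 5), hub_node = 1,
                            hub_boost = 0, nuisance_mix = 0, seed = 1000 + i)
    co <- build_cohort(design)
    cm <- correlation_matrix(co[[1]]$timeseries)
    stack <- threshold_by_density(cm, density_grid(0.10, 0.40, 0.02))
    pr <- profile_subject(stack, n_restarts = 3, seed = i)
    p_avg <- pr$averaged$participation[module]
    top[i] <- which.max(p_avg + runif(5) * 1e-9) == 1L  # random tie-break
  }
  # binomial check against 1/5
  expect_gt(stats::binom.test(sum(top), n_rep, p = 0.2)$p.value, 0.001)
})

test_that("cohorts round-trip through the on-disk TSV/CSV layout", {
  design <- cohort_design(n_per_group = 1, n_nodes = 8, n_timepoints = 30,
                          burn_in = 0, module_sizes = c(4, 4), hub_node = 1,
                          seed = 3)
  co <- build_cohort(design)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_length(manifest$timeseries, 3L)
  expect_length(manifest$nuisance, 3L)
  expect_true(file.exists(manifest$cohort))

  back <- read_cohort(dir)
  expect_equal(back$cohort$subject_id, cohort_table(co)$subject_id)
  for (i in seq_along(co)) {
    expect_equal(back$subjects[[i]]$timeseries$values, co[[i]]$timeseries$values,
                 tolerance = 1e-12)
    expect_equal(as.data.frame(back$subjects[[i]]$nuisance),
                 as.data.frame(co[[i]]$nuisance), tolerance = 1e-12)
  }

  # empty cohort: only the cohort CSV header
  dir2 <- withr::local_tempdir()
  m2 <- write_cohort(structure(list(), class = "synthetic_cohort"), dir2)
  expect_length(m2$timeseries, 0L)
  expect_equal(nrow(utils::read.csv(m2$cohort)), 0L)
})
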