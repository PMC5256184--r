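#' Design of a synthetic resting-state cohort
#'
#' Describes a multi-subject cohort of ROI time series with planted modular
#' covariance and a designated connector hub whose cross-module coupling is
#' elevated in selected groups. The generator exists so that every downstream
#' stage (cleaning, graph construction, centrality, group statistics, seed
#' connectivity) can be exercised and calibrated without clinical imaging
#' data.
#'
#' The default design mirrors the acquisition this package targets: 92
#' atlas nodes sampled at TR = 2 s, 175 retained volumes preceded by a
#' 10-volume unstable burn-in that the preprocessing stage discards, three
#' groups (tremor-dominant patients TP, non-tremor patients NTP, healthy
#' controls HC), and a hub at the left thalamus whose intermodular coupling
#' is raised by `hub_boost` in the TP group only.
#'
#' @param n_per_group Subjects per group.
#' @param groups Ordered group labels.
#' @param affected_groups Groups receiving the hub coupling increment (and a
#'   nonzero tremor score).
#' @param n_nodes Number of graph nodes.
#' @param n_timepoints Retained volumes per subject (after burn-in discard).
#' @param burn_in Extra leading volumes emulating unstable initial signal;
#'   written as part of the raw series and meant to be discarded downstream.
#' @param tr_seconds Sampling interval in seconds.
#' @param module_sizes Integer partition of `n_nodes` into planted modules
#'   (contiguous blocks); all sizes must be at least 2.
#' @param modules Optional explicit node-to-module assignment (length
#'   `n_nodes`); overrides the contiguous blocks derived from `module_sizes`.
#' @param within_module_corr Target correlation inside a module.
#' @param between_module_corr Baseline cross-module correlation.
#' @param hub_node Index of the planted hub node.
#' @param hub_boost Additive cross-module correlation increment for the hub
#'   in affected groups.
#' @param hub_jitter_sd SD of the subject-level jitter on the hub increment.
#' @param score_scale Scale of the simulated tremor score (UPDRS-like units)
#'   per unit of relative hub increment.
#' @param score_noise_sd SD of the additive noise on the tremor score.
#' @param nuisance_mix Fraction of each node's signal SD at which the
#'   white-matter, CSF and motion-like series are mixed into the ROI series.
#' @param confound_age_sex If `TRUE`, age is drawn with a positive
#'   association to the subject's hub increment, so covariate adjustment has
#'   a real confound to remove; off by default.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return A validated list of class `cohort_design`.
#' @seealso [build_cohort()], [write_cohort()]
#' @export
cohort_design <- function(n_per_group = 20L,
                          groups = c("TP", "NTP", "HC"),
                          affected_groups = "TP",
                          n_nodes = 92L,
                          n_timepoints = 175L,
                          burn_in = 10L,
                          tr_seconds = 2.0,
                          module_sizes = NULL,
                          modules = NULL,
                          within_module_corr = 0.5,
                          between_module_corr = 0.1,
                          hub_node = NULL,
                          hub_boost = 0.25,
                          hub_jitter_sd = 0.08,
                          score_scale = 5,
                          score_noise_sd = 2,
                          nuisance_mix = 0.1,
                          confound_age_sex = FALSE,
                          seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  if (is.null(module_sizes) && is.null(modules)) {
    base <- n_nodes %/% 4L
    module_sizes <- rep(base, 4L)
    module_sizes[4L] <- n_nodes - 3L * base
  }
  if (!is.null(modules)) {
    modules <- as.integer(modules)
    if (length(modules) != n_nodes) {
      tn_stop("cohort_design: modules must assign every node")
    }
    module_sizes <- as.integer(table(modules))
  } else {
    module_sizes <- as.integer(module_sizes)
    modules <- rep(seq_along(module_sizes), times = module_sizes)
  }
  if (sum(module_sizes) != n_nodes) {
    tn_stop("cohort_design: module_sizes must sum to n_nodes")
  }
  if (any(module_sizes < 2L)) {
    tn_stop("cohort_design: all module sizes must be >= 2")
  }
  if (!(between_module_corr >= 0 && between_module_corr < within_module_corr &&
        within_module_corr < 1)) {
    tn_stop("cohort_design: need 0 <= between_module_corr < within_module_corr < 1")
  }
  if (is.null(hub_node)) {
    hub_node <- if (n_nodes == 92L) match("Thalamus_L", aal92_labels()) else 1L
  }
  hub_node <- as.integer(hub_node)
  if (hub_node < 1L || hub_node > n_nodes) tn_stop("cohort_design: hub_node out of range")
  if (hub_boost < 0) tn_stop("cohort_design: hub_boost must be >= 0")
  if (!all(affected_groups %in% groups)) {
    tn_stop("cohort_design: affected_groups must be a subset of groups")
  }
  design <- list(
    n_per_group = as.integer(n_per_group), groups = groups,
    affected_groups = affected_groups, n_nodes = n_nodes,
    n_timepoints = as.integer(n_timepoints), burn_in = as.integer(burn_in),
    tr_seconds = tr_seconds, module_sizes = module_sizes, modules = modules,
    within_module_corr = within_module_corr,
    between_module_corr = between_module_corr,
    hub_node = hub_node, hub_boost = hub_boost,
    hub_jitter_sd = hub_jitter_sd, score_scale = score_scale,
    score_noise_sd = score_noise_sd, nuisance_mix = nuisance_mix,
    confound_age_sex = confound_age_sex, seed = as.integer(seed),
    node_labels = default_node_labels(n_nodes)
  )
  class(design) <- "cohort_design"
  design
}

# Internal: block-structured target correlation matrix for a design.
block_correlation <- function(design) {
  r <- matrix(design$between_module_corr, design$n_nodes, design$n_nodes)
  for (m in unique(design$modules)) {
    idx <- which(design$modules == m)
    r[idx, idx] <- design$within_module_corr
  }
  diag(r) <- 1
  r
}

# Internal: project a symmetric matrix to the nearest unit-diagonal positive
# semi-definite correlation matrix by clipping negative eigenvalues to a
# small positive floor and rescaling the diagonal.
psd_repair <- function(r, floor = 1e-6) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= floor) return(r)
  vals <- pmax(e$values, floor)
  fixed <- e$vectors %*% (vals * t(e$vectors))
  fixed <- stats::cov2cor(fixed)
  check <- min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values)
  if (check < -1e-10) {
    tn_stop("psd_repair: matrix not positive semi-definite after repair ",
            "(min eigenvalue ", format(check), ")")
  }
  (fixed + t(fixed)) / 2
}

# Internal: smooth low-frequency unit-SD series as a sum of random-phase
# slow sinusoids (0.005-0.05 Hz).
slow_signal <- function(n, tr) {
  tt <- seq_len(n) * tr
  freqs <- runif(5L, 0.005, 0.05)
  phases <- runif(5L, 0, 2 * pi)
  x <- rowSums(sin(outer(tt, 2 * pi * freqs) + rep(phases, each = n)))
  as.numeric(scale(x))
}

#' Generate a synthetic cohort of ROI time series
#'
#' Draws each subject's series from a zero-mean multivariate Gaussian whose
#' correlation matrix has the design's block-modular structure; for subjects
#' in affected groups the hub row/column toward out-of-module nodes is
#' raised by `hub_boost` plus subject-level jitter, after which the matrix is
#' repaired to positive semi-definiteness and rescaled to unit diagonal.
#' Motion-like drifts and white-matter/CSF-like slow signals are generated
#' per subject and partially mixed into the ROI series so the cleaning stage
#' has something real to remove. The simulated tremor score is a linear
#' function of the realized hub increment plus Gaussian noise, truncated at
#' zero, and is identically zero in unaffected groups.
#'
#' @param design A [cohort_design()].
#' @return A list of class `synthetic_cohort`; each element is a
#'   `synthetic_subject` with fields `subject_id`, `group`, `age`, `sex`,
#'   `timeseries` ([roi_ts]), `nuisance` ([nuisance_table]), `tremor_score`
#'   and `planted_hub_effect` (the realized hub increment).
#' @examples
#' design <- cohort_design(n_per_group = 2, n_nodes = 20, n_timepoints = 60,
#'                         burn_in = 0, seed = 7)
#' cohort <- build_cohort(design)
#' cohort_table(cohort)
#' @export
build_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  base_r <- block_correlation(design)
  out_module <- design$modules != design$modules[design$hub_node]
  t_total <- design$n_timepoints + design$burn_in
  subjects <- list()
  counter <- 0L
  for (g in design$groups) {
    affected <- g %in% design$affected_groups
    for (k in seq_len(design$n_per_group)) {
      counter <- counter + 1L
      sid <- sprintf("sub-%s%02d", tolower(g), k)
      b_s <- 0
      if (affected && design$hub_boost > 0) {
        b_s <- max(0, design$hub_boost + rnorm(1L, 0, design$hub_jitter_sd))
      }
      r <- base_r
      if (b_s > 0) {
        r[design$hub_node, out_module] <- pmin(0.99, r[design$hub_node, out_module] + b_s)
        r[out_module, design$hub_node] <- r[design$hub_node, out_module]
        r <- psd_repair(r)
      }
      ch <- chol(r + diag(1e-10, design$n_nodes))
      x <- matrix(rnorm(t_total * design$n_nodes), t_total) %*% ch

      # nuisance components: random-walk motion, slow WM/CSF-like signals
      motion6 <- cbind(
        apply(matrix(rnorm(t_total * 3L, 0, 0.02), t_total), 2, cumsum),
        apply(matrix(rnorm(t_total * 3L, 0, 4e-4), t_total), 2, cumsum)
      )
      wm <- slow_signal(t_total, design$tr_seconds)
      csf <- slow_signal(t_total, design$tr_seconds)
      if (design$nuisance_mix > 0) {
        motion_like <- as.numeric(scale(motion6[, 1L]))
        sds <- apply(x, 2, sd)
        x <- x + outer(wm + csf + motion_like, design$nuisance_mix * sds)
      }
      if (design$burn_in > 0L) {
        # unstable initial signal: inflated variance + decaying offset
        idx <- seq_len(design$burn_in)
        decay <- exp(-(idx - 1L) / 3)
        x[idx, ] <- x[idx, ] * 2 + outer(decay, rep(3, design$n_nodes))
      }

      score <- 0
      if (affected && design$hub_boost > 0) {
        score <- design$score_scale * (b_s / design$hub_boost) +
          rnorm(1L, 0, design$score_noise_sd)
        score <- max(0, score)
      }
      age <- runif(1L, 45, 70)
      if (design$confound_age_sex && design$hub_boost > 0) {
        age <- min(70, max(45, 57 + 40 * (b_s - design$hub_boost) + rnorm(1L, 0, 5)))
      }
      subjects[[counter]] <- structure(
        list(subject_id = sid, group = g, age = age,
             sex = rbinom(1L, 1L, 0.5),
             timeseries = roi_ts(x, design$node_labels, sid, design$tr_seconds),
             nuisance = nuisance_table(motion6, wm, csf),
             tremor_score = score, planted_hub_effect = b_s),
        class = "synthetic_subject"
      )
    }
  }
  structure(subjects, class = "synthetic_cohort", design = design)
}

#' Subject-level table of a synthetic cohort
#'
#' @param cohort A `synthetic_cohort` from [build_cohort()].
#' @return A data.frame with columns `subject_id`, `group`, `age`, `sex`,
#'   `tremor_score` and `planted_hub_effect`.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, tremor_score = s$tremor_score,
               planted_hub_effect = s$planted_hub_effect,
               stringsAsFactors = FALSE)
  }))
}

#' Write a synthetic cohort to disk
#'
#' Writes one tab-separated time-series file per subject (header row of node
#' labels, one row per time point), one nuisance table per subject, and a
#' single cohort CSV. An empty cohort yields only the cohort CSV header.
#'
#' @param cohort A `synthetic_cohort` (possibly empty list).
#' @param directory Output directory; created if missing.
#' @return Invisibly, a manifest list with elements `timeseries`, `nuisance`
#'   and `cohort` (file paths).
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  if (!dir.exists(directory)) tn_stop("write_cohort: cannot create ", directory)
  ts_paths <- character(0)
  nu_paths <- character(0)
  for (s in cohort) {
    tsp <- file.path(directory, paste0(s$subject_id, "_timeseries.tsv"))
    nup <- file.path(directory, paste0(s$subject_id, "_nuisance.tsv"))
    write.table(s$timeseries$values, tsp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(as.data.frame(s$nuisance), nup, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ts_paths <- c(ts_paths, tsp)
    nu_paths <- c(nu_paths, nup)
  }
  cohort_path <- file.path(directory, "cohort.csv")
  tab <- if (length(cohort)) cohort_table(cohort) else
    data.frame(subject_id = character(0), group = character(0),
               age = numeric(0), sex = integer(0), tremor_score = numeric(0),
               planted_hub_effect = numeric(0))
  utils::write.csv(tab, cohort_path, row.names = FALSE, quote = FALSE)
  invisible(list(timeseries = ts_paths, nuisance = nu_paths,
                 cohort = cohort_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing `cohort.csv` and per-subject TSVs.
#' @param tr_seconds Sampling interval to attach to the series.
#' @return A list with `subjects` (list of `subject_id`, `timeseries`,
#'   `nuisance`) and `cohort` (the cohort data.frame).
#' @export
read_cohort <- function(directory, tr_seconds = 2.0) {
  cohort_path <- file.path(directory, "cohort.csv")
  if (!file.exists(cohort_path)) tn_stop("read_cohort: no cohort.csv in ", directory)
  tab <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  subjects <- lapply(tab$subject_id, function(sid) {
    x <- as.matrix(read.table(file.path(directory, paste0(sid, "_timeseries.tsv")),
                              header = TRUE, sep = "\t", check.names = FALSE))
    nu <- read.table(file.path(directory, paste0(sid, "_nuisance.tsv")),
                     header = TRUE, sep = "\t")
    list(subject_id = sid,
         timeseries = roi_ts(x, colnames(x), sid, tr_seconds),
         nuisance = nuisance_table(as.matrix(nu[, 1:6]), nu$wm, nu$csf))
  })
  list(subjects = subjects, cohort = tab)
}
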