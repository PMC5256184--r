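# End-to-end orchestration: one configuration object drives simulate ->
# preprocess -> graphs -> centrality -> stats -> seed connectivity, with a
# versioned manifest (config hash, derived stage seeds, output paths) so a
# run is reproducible from a single master seed.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with defaults equal to the
#' reference acquisition and analysis settings: discard 10 initial volumes,
#' band-pass 0.01-0.08 Hz, density grid 0.10-0.40 step 0.01, 100 modularity
#' restarts, group-network density 0.30, bilateral thalami as hypothesis
#' nodes, bilateral primary motor cortices and cerebella as specificity
#' controls, bilateral putamen as seed, thalamic mask for the seed contrast.
#'
#' @param design A [cohort_design()] to simulate, or `NULL` to read a
#'   previously written cohort from `input_dir`.
#' @param input_dir Directory with a cohort written by [write_cohort()]
#'   (used when `design` is `NULL`).
#' @param out_dir Output directory for result files.
#' @param n_discard,low_hz,high_hz Preprocessing settings.
#' @param density_start,density_stop,density_step Density grid.
#' @param n_restarts Louvain restarts per graph.
#' @param group_density Density for the group-average modular summary.
#' @param hypothesis_nodes Nodes tested for the group effect.
#' @param control_nodes Nodes used for specificity checks.
#' @param seed_nodes Seed region labels (averaged into one regressor).
#' @param mask_nodes Small-volume mask for the seed contrast.
#' @param contrast Two group labels contrasted in the seed stage.
#' @param scores Clinical score columns for partial correlations.
#' @param metrics Centrality metrics to test.
#' @param n_perm Permutations for FWE correction.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = cohort_design(),
                            input_dir = NULL,
                            out_dir = tempfile("tremornet_run_"),
                            n_discard = 10L, low_hz = 0.01, high_hz = 0.08,
                            density_start = 0.10, density_stop = 0.40,
                            density_step = 0.01,
                            n_restarts = 100L, group_density = 0.30,
                            hypothesis_nodes = c("Thalamus_L", "Thalamus_R"),
                            control_nodes = c("Precentral_L", "Precentral_R",
                                              "Cerebelum_L", "Cerebelum_R"),
                            seed_nodes = c("Putamen_L", "Putamen_R"),
                            mask_nodes = c("Thalamus_L", "Thalamus_R"),
                            contrast = c("TP", "HC"),
                            scores = "tremor_score",
                            metrics = c("degree", "betweenness",
                                        "within_module_degree", "participation"),
                            n_perm = 5000L, seed = 1L) {
  config <- list(design = design, input_dir = input_dir, out_dir = out_dir,
                 n_discard = as.integer(n_discard), low_hz = low_hz,
                 high_hz = high_hz, density_start = density_start,
                 density_stop = density_stop, density_step = density_step,
                 n_restarts = as.integer(n_restarts),
                 group_density = group_density,
                 hypothesis_nodes = hypothesis_nodes,
                 control_nodes = control_nodes, seed_nodes = seed_nodes,
                 mask_nodes = mask_nodes, contrast = contrast,
                 scores = scores, metrics = metrics,
                 n_perm = as.integer(n_perm), seed = as.integer(seed))
  class(config) <- "pipeline_config"
  validate_pipeline_config(config)
  config
}

validate_pipeline_config <- function(config) {
  if (is.null(config$design) && is.null(config$input_dir)) {
    tn_stop("pipeline_config: provide a design to simulate or an input_dir")
  }
  labels <- if (!is.null(config$design)) config$design$node_labels else NULL
  if (!is.null(labels)) {
    wanted <- c(config$hypothesis_nodes, config$control_nodes,
                config$seed_nodes, config$mask_nodes)
    bad <- setdiff(wanted, labels)
    if (length(bad)) {
      tn_stop("pipeline_config: node label(s) not in the data's label set: ",
              paste(bad, collapse = ", "))
    }
  }
  density_grid(config$density_start, config$density_stop, config$density_step)
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; a `design:` block is
#' passed to [cohort_design()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design)) raw$design <- do.call(cohort_design, raw$design)
  do.call(pipeline_config, raw)
}

# Internal: small stable rolling hash of a config for the manifest.
config_hash <- function(config) {
  config$out_dir <- NULL
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> connectivity graphs ->
#' centrality profiles -> group statistics -> group-average modular summary
#' -> seed connectivity, writing result tables and a manifest (config hash,
#' derived per-stage seeds, file list) to the configured output directory.
#' Rerunning with an identical configuration reproduces every number.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with elements `cohort`, `qc`, `profiles`,
#'   `ancova`, `correlations`, `group_networks`, `seed_fc`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  say <- function(...) if (!quiet) message("tremornet: ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  stage_seeds <- vapply(
    c("simulate", "centrality", "group_network", "seed_fc"),
    function(tag) derive_seed(config$seed, tag), integer(1))

  # --- stage: cohort ---------------------------------------------------
  if (!is.null(config$design)) {
    say("simulating cohort (seed ", stage_seeds[["simulate"]], ")")
    design <- config$design
    design$seed <- stage_seeds[["simulate"]]
    cohort_obj <- build_cohort(design)
    subjects <- lapply(cohort_obj, function(s) {
      list(subject_id = s$subject_id, timeseries = s$timeseries,
           nuisance = s$nuisance)
    })
    cohort <- cohort_table(cohort_obj)
  } else {
    say("loading cohort from ", config$input_dir)
    loaded <- read_cohort(config$input_dir)
    subjects <- loaded$subjects
    cohort <- loaded$cohort
  }
  p <- file.path(config$out_dir, "cohort.csv")
  utils::write.csv(cohort, p, row.names = FALSE)
  paths <- c(paths, p)

  # --- stage: preprocess ----------------------------------------------
  say("preprocessing ", length(subjects), " subjects")
  prep <- lapply(subjects, function(s) {
    preprocess_subject(s$timeseries, s$nuisance, config$n_discard,
                       config$low_hz, config$high_hz)
  })
  qc <- do.call(rbind, lapply(seq_along(prep), function(i) {
    data.frame(subject_id = subjects[[i]]$subject_id,
               sum_translation_mm = prep[[i]]$qc$sum_translation_mm,
               sum_rotation_deg = prep[[i]]$qc$sum_rotation_deg,
               mean_fd_mm = prep[[i]]$qc$mean_fd_mm)
  }))
  p <- file.path(config$out_dir, "motion_qc.csv")
  utils::write.csv(qc, p, row.names = FALSE)
  paths <- c(paths, p)

  # --- stage: graphs + centrality -------------------------------------
  grid <- density_grid(config$density_start, config$density_stop,
                       config$density_step)
  say("building graphs over ", length(grid), " densities and profiling")
  cms <- lapply(prep, function(pp) correlation_matrix(pp$ts))
  profiles <- lapply(cms, function(cm) {
    stack <- threshold_by_density(cm, grid)
    profile_subject(stack, config$n_restarts,
                    seed = derive_seed(stage_seeds[["centrality"]], cm$subject_id))
  })
  long <- do.call(rbind, lapply(profiles, as.data.frame))
  p <- file.path(config$out_dir, "centrality_profiles.tsv")
  write.table(long, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  # --- stage: group statistics ----------------------------------------
  say("group statistics (repeated-measures ANCOVA + partial correlations)")
  test_nodes <- c(config$hypothesis_nodes, config$control_nodes)
  ancova <- list()
  for (node in test_nodes) {
    for (metric in config$metrics) {
      ancova[[paste(node, metric, sep = ".")]] <-
        rm_ancova(profiles, cohort, node, metric)
    }
  }
  ancova_tab <- do.call(rbind, lapply(ancova, function(a) {
    data.frame(node = a$node, metric = a$metric, group_f = a$group_f,
               group_p = a$group_p, stringsAsFactors = FALSE)
  }))
  rownames(ancova_tab) <- NULL
  p <- file.path(config$out_dir, "group_ancova.csv")
  utils::write.csv(ancova_tab, p, row.names = FALSE)
  paths <- c(paths, p)

  corr <- specificity_screen(profiles, cohort, test_nodes, config$metrics,
                             config$scores,
                             group = config$contrast[1L])
  p <- file.path(config$out_dir, "score_correlations.csv")
  utils::write.csv(corr, p, row.names = FALSE)
  paths <- c(paths, p)

  # --- stage: group-average modular summary ---------------------------
  say("group-average networks at density ", config$group_density)
  groups <- unique(cohort$group)
  group_networks <- lapply(setNames(groups, groups), function(g) {
    idx <- which(cohort$group == g)
    group_network_modules(cms[idx], config$group_density,
                          query_nodes = config$hypothesis_nodes,
                          n_restarts = config$n_restarts,
                          seed = stage_seeds[["group_network"]])
  })

  # --- stage: seed connectivity ---------------------------------------
  say("seed connectivity (", paste(config$seed_nodes, collapse = "+"),
      " -> mask of ", length(config$mask_nodes), " nodes)")
  betas <- lapply(prep, function(pp) {
    first_level_betas(pp$ts, config$seed_nodes)
  })
  seed_res <- group_contrast_fwe(betas, cohort, config$mask_nodes,
                                 contrast = config$contrast,
                                 n_perm = config$n_perm,
                                 seed = stage_seeds[["seed_fc"]])
  seed_corr <- beta_clinical_correlation(betas, cohort, seed_res$peak_node,
                                         config$scores,
                                         group = config$contrast[1L])
  p <- file.path(config$out_dir, "seed_contrast.csv")
  utils::write.csv(seed_res$table, p, row.names = FALSE)
  paths <- c(paths, p)

  manifest <- list(package = "tremornet",
                   version = as.character(utils::packageVersion("tremornet")),
                   config_hash = config_hash(unclass(config)),
                   master_seed = config$seed,
                   stage_seeds = as.list(stage_seeds),
                   outputs = basename(paths))
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, qc = qc, profiles = profiles,
                 ancova = ancova, correlations = corr,
                 group_networks = group_networks,
                 seed_fc = list(contrast = seed_res, clinical = seed_corr),
                 manifest = manifest))
}
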