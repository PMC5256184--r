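# ROI-level seed-based functional connectivity: per-subject GLM betas of
# every target region on a seed's mean time series, covariate-adjusted
# group contrasts within an a priori mask, and max-statistic permutation
# family-wise error (FWE) correction.

#' First-level seed connectivity betas
#'
#' Regresses every non-seed node's series on the seed regressor (the
#' unweighted mean of the seed nodes' series, e.g. a bilateral pair) in a
#' joint ordinary-least-squares model with an intercept and any nuisance
#' regressors, and returns the seed beta per target node.
#'
#' @param ts A cleaned [roi_ts].
#' @param seed_nodes Character vector of node labels forming the seed
#'   (averaged).
#' @param nuisance Optional [nuisance_table] matched to `ts` (its
#'   24-parameter motion expansion plus WM and CSF enter as covariates of no
#'   interest), or a ready T x k numeric matrix, or `NULL`.
#' @return A list of class `seed_beta_table` with `subject_id`, `seed_nodes`
#'   and `beta` (named vector over non-seed nodes).
#' @export
first_level_betas <- function(ts, seed_nodes, nuisance = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  if (!length(seed_nodes) || !all(seed_nodes %in% ts$node_labels)) {
    tn_stop("first_level_betas: seed node(s) not in series: ",
            paste(setdiff(seed_nodes, ts$node_labels), collapse = ", "))
  }
  seed_sig <- rowMeans(ts$values[, seed_nodes, drop = FALSE])
  targets <- setdiff(ts$node_labels, seed_nodes)
  nuis <- NULL
  if (inherits(nuisance, "nuisance_table")) {
    if (nrow(nuisance) != nrow(ts$values)) {
      tn_stop("first_level_betas: nuisance length does not match series")
    }
    nuis <- cbind(expand_motion24(nuisance), wm = nuisance$wm, csf = nuisance$csf)
  } else if (!is.null(nuisance)) {
    nuis <- as.matrix(nuisance)
  }
  if (!is.null(nuis)) {
    # the seed must add information beyond the nuisance span
    rank_nuis <- qr(cbind(1, nuis))$rank
    if (qr(cbind(1, nuis, seed_sig))$rank == rank_nuis) {
      tn_stop("first_level_betas: seed regressor is collinear with the ",
              "nuisance design (condition number ",
              format(kappa(cbind(1, nuis, seed_sig)), digits = 3), ")")
    }
  }
  x <- cbind(intercept = 1, seed = seed_sig, nuis)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    kept <- sort(union(1:2, qx$pivot[seq_len(qx$rank)]))
    x <- x[, kept, drop = FALSE]
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      tn_stop("first_level_betas: design remains rank deficient")
    }
  }
  cf <- qr.coef(qx, ts$values[, targets, drop = FALSE])
  structure(list(subject_id = ts$subject_id, seed_nodes = seed_nodes,
                 beta = setNames(cf["seed", ], targets)),
            class = "seed_beta_table")
}

# Internal: stack per-subject beta tables into a subjects x nodes matrix.
seed_beta_matrix <- function(beta_tables) {
  ids <- vapply(beta_tables, `[[`, "", "subject_id")
  nodes <- names(beta_tables[[1L]]$beta)
  y <- do.call(rbind, lapply(beta_tables, function(b) b$beta[nodes]))
  dimnames(y) <- list(ids, nodes)
  y
}

# Internal: t-statistics of the `col`-th design column for every response
# column of Y under OLS.
design_tstats <- function(x, y, col) {
  qx <- qr(x)
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- nrow(x) - qx$rank
  sigma2 <- colSums(res^2) / df
  ip <- order(qx$pivot)
  xtx_inv <- chol2inv(qr.R(qx))[ip, ip, drop = FALSE]
  cf[col, ] / sqrt(sigma2 * xtx_inv[col, col])
}

#' Group contrast on seed betas with permutation FWE correction
#'
#' For every node of an a priori mask, tests the two-group difference in
#' seed connectivity betas with age and sex held as covariates, and
#' corrects for the family of mask nodes by the permutation distribution of
#' the maximum absolute t under group-label exchange (covariates fixed).
#' The peak node is the largest absolute t.
#'
#' @param beta_tables List of [first_level_betas()] results (one per
#'   subject).
#' @param cohort Cohort data frame (`subject_id`, `group`, `age`, `sex`).
#' @param mask_nodes Node labels forming the small-volume mask.
#' @param contrast Length-2 character vector of group labels; the statistic
#'   is (first minus second).
#' @param covariates Covariate columns (default age and sex; may be empty).
#' @param n_perm Number of label permutations (default 5000; at least a few
#'   hundred are needed for stable FWE p-values).
#' @param seed RNG seed for the permutation stream.
#' @return A list of class `mask_contrast_result` with `table` (node, t,
#'   p_uncorrected, p_fwe), `peak_node`, `contrast`, `n_perm`.
#' @export
group_contrast_fwe <- function(beta_tables, cohort, mask_nodes,
                               contrast = c("TP", "HC"),
                               covariates = c("age", "sex"),
                               n_perm = 5000L, seed = 1L) {
  cohort <- check_cohort(cohort)
  if (!length(mask_nodes)) tn_stop("group_contrast_fwe: empty mask")
  if (length(contrast) != 2L) tn_stop("group_contrast_fwe: contrast must name 2 groups")
  keep <- cohort$group %in% contrast
  cohort <- cohort[keep, , drop = FALSE]
  if (length(unique(cohort$group)) < 2L) {
    tn_stop("group_contrast_fwe: fewer than 2 contrast groups present")
  }
  y_all <- seed_beta_matrix(beta_tables)
  miss <- setdiff(cohort$subject_id, rownames(y_all))
  if (length(miss)) tn_stop("group_contrast_fwe: no betas for: ",
                            paste(miss, collapse = ", "))
  bad <- setdiff(mask_nodes, colnames(y_all))
  if (length(bad)) tn_stop("group_contrast_fwe: mask node(s) without betas ",
                           "(seed nodes cannot be mask nodes): ",
                           paste(bad, collapse = ", "))
  y <- y_all[cohort$subject_id, mask_nodes, drop = FALSE]
  g <- as.numeric(cohort$group == contrast[1L])
  z <- if (length(covariates)) as.matrix(cohort[covariates]) else NULL
  x <- cbind(1, g = g, z)
  t_obs <- design_tstats(x, y, 2L)
  set.seed(seed)
  t_perm_max <- numeric(n_perm)
  exceed_node <- numeric(length(mask_nodes))
  for (b in seq_len(n_perm)) {
    xp <- x
    xp[, 2L] <- g[sample.int(length(g))]
    tp <- abs(design_tstats(xp, y, 2L))
    t_perm_max[b] <- max(tp)
    exceed_node <- exceed_node + (tp >= abs(t_obs))
  }
  p_unc <- (1 + exceed_node) / (1 + n_perm)
  p_fwe <- vapply(abs(t_obs), function(tt) (1 + sum(t_perm_max >= tt)) / (1 + n_perm),
                  numeric(1))
  tab <- data.frame(node = mask_nodes, t = as.numeric(t_obs),
                    p_uncorrected = p_unc, p_fwe = p_fwe,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 peak_node = mask_nodes[which.max(abs(t_obs))],
                 contrast = contrast, n_perm = as.integer(n_perm),
                 covariates = covariates),
            class = "mask_contrast_result")
}

#' @export
print.mask_contrast_result <- function(x, ...) {
  cat(sprintf("<mask_contrast_result> %s - %s, %d permutations; peak: %s\n",
              x$contrast[1], x$contrast[2], x$n_perm, x$peak_node))
  print(x$table, digits = 3)
  invisible(x)
}

#' Clinical correlations of peak seed-connectivity betas
#'
#' Age/sex-adjusted partial Pearson correlations between the per-subject
#' seed betas at a (peak) node and each clinical score, within one group.
#'
#' @param beta_tables List of [first_level_betas()] results.
#' @param cohort Cohort data frame including score columns.
#' @param node Node at which to extract betas (typically the contrast peak).
#' @param scores Score column names.
#' @param group Optional group label to restrict to.
#' @param covariates Covariate columns (default age and sex).
#' @return Data frame with columns `score`, `r`, `p`, `n`.
#' @export
beta_clinical_correlation <- function(beta_tables, cohort, node, scores,
                                      group = NULL,
                                      covariates = c("age", "sex")) {
  cohort <- check_cohort(cohort)
  if (!is.null(group)) cohort <- cohort[cohort$group %in% group, , drop = FALSE]
  y_all <- seed_beta_matrix(beta_tables)
  if (!node %in% colnames(y_all)) tn_stop("beta_clinical_correlation: unknown node ", node)
  betas <- y_all[cohort$subject_id, node]
  z <- if (length(covariates)) as.matrix(cohort[covariates]) else NULL
  out <- do.call(rbind, lapply(scores, function(sc) {
    if (is.null(cohort[[sc]])) tn_stop("beta_clinical_correlation: unknown score ", sc)
    pc <- partial_correlation(betas, cohort[[sc]], z)
    data.frame(score = sc, r = pc$r, p = pc$p, n = pc$n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
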