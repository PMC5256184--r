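# Group statistics: repeated-measures ANCOVA across network densities,
# covariate-adjusted post hoc contrasts, and partial correlations with
# clinical scores. The repeated-measures model is fit as a multivariate
# linear model with type-III tests (sum-to-zero contrasts) and
# Greenhouse-Geisser correction on within-subject terms, i.e. the standard
# GLM repeated-measures route.

# Internal: subjects x densities matrix of one node/metric across profiles,
# row order matching `subject_ids`.
profile_matrix <- function(profiles, subject_ids, node, metric) {
  ids <- vapply(profiles, `[[`, "", "subject_id")
  miss <- setdiff(subject_ids, ids)
  if (length(miss)) {
    tn_stop("no centrality profile for subject(s): ", paste(miss, collapse = ", "))
  }
  rows <- lapply(subject_ids, function(sid) {
    p <- profiles[[match(sid, ids)]]
    if (!metric %in% names(p$metrics)) tn_stop("unknown metric: ", metric)
    if (!node %in% rownames(p$metrics[[metric]])) tn_stop("unknown node: ", node)
    p$metrics[[metric]][node, ]
  })
  y <- do.call(rbind, rows)
  rownames(y) <- subject_ids
  y
}

check_cohort <- function(cohort) {
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) tn_stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$subject_id)) tn_stop("duplicated subject ids in cohort")
  if (anyNA(cohort[need])) tn_stop("missing values in cohort covariates")
  cohort
}

#' Repeated-measures ANCOVA of a centrality metric across densities
#'
#' Tests the between-subject group effect on one node's centrality metric,
#' with network density as the within-subject factor and age (mean-centered)
#' and sex as covariates. The model is fit as a multivariate linear model
#' over the density columns with type-III sums of squares and sum-to-zero
#' group contrasts; Greenhouse-Geisser-corrected p-values are reported for
#' the within-subject terms. Post hoc pairwise group contrasts are computed
#' on the density-averaged, covariate-adjusted values (no multiplicity
#' adjustment, reflecting the a priori single-node hypothesis).
#'
#' @param profiles List of [profile_subject()] results covering every cohort
#'   subject.
#' @param cohort Data frame with `subject_id`, `group`, `age`, `sex`.
#' @param node Node label to test.
#' @param metric One of `"degree"`, `"betweenness"`,
#'   `"within_module_degree"`, `"participation"`.
#' @param covariates Covariate column names (default `c("age", "sex")`; may
#'   be empty).
#' @return A list of class `rm_ancova` with `group_f`, `group_df`,
#'   `group_p`, `within` (data.frame of within-subject terms with
#'   Greenhouse-Geisser epsilon and corrected p), `posthoc` (data.frame of
#'   pairwise contrasts on adjusted density-averaged values), and
#'   `adjusted_means`.
#' @export
rm_ancova <- function(profiles, cohort, node, metric,
                      covariates = c("age", "sex")) {
  cohort <- check_cohort(cohort)
  if (any(table(cohort$group) < 3L)) {
    tn_stop("rm_ancova: every group needs at least 3 subjects")
  }
  y <- profile_matrix(profiles, cohort$subject_id, node, metric)
  if (anyNA(y)) tn_stop("rm_ancova: missing density values for ", node, "/", metric)
  if (var(as.vector(y)) < .Machine$double.eps * 100) {
    tn_stop("rm_ancova: dependent variable is constant for ", node, "/", metric,
            "; no variance to model")
  }
  dat <- data.frame(group = factor(cohort$group), row.names = NULL)
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.null(v)) tn_stop("rm_ancova: cohort lacks covariate ", cv)
    dat[[cv]] <- if (cv == "age") as.numeric(scale(v, scale = FALSE)) else as.numeric(v)
  }
  rhs <- paste(c("group", covariates), collapse = " + ")
  mlm <- lm(as.formula(paste("y ~", rhs)), data = dat,
            contrasts = list(group = contr.sum))
  idata <- data.frame(density = factor(seq_len(ncol(y))))
  an <- car::Anova(mlm, idata = idata, idesign = ~density, type = 3)
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  uni <- s$univariate.tests
  gi <- match("group", rownames(uni))
  within_rows <- grep("density", rownames(uni))
  adj <- s$pval.adjustments
  within <- data.frame(
    term = rownames(uni)[within_rows],
    f = uni[within_rows, "F value"],
    num_df = uni[within_rows, "num Df"],
    den_df = uni[within_rows, "den Df"],
    p_uncorrected = uni[within_rows, "Pr(>F)"],
    gg_epsilon = adj[rownames(uni)[within_rows], "GG eps"],
    p_gg = adj[rownames(uni)[within_rows], "Pr(>F[GG])"],
    row.names = NULL
  )

  # post hoc: covariate-adjusted contrasts on density-averaged values
  dat$avg <- rowMeans(y)
  fit_avg <- lm(as.formula(paste("avg ~", rhs)), data = dat)
  emm <- emmeans::emmeans(fit_avg, "group")
  ph <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"), adjust = "none"))
  posthoc <- data.frame(contrast = as.character(ph$contrast),
                        estimate = ph$estimate, se = ph$SE, df = ph$df,
                        t = ph$t.ratio, p = ph$p.value)
  structure(
    list(node = node, metric = metric,
         group_f = unname(uni[gi, "F value"]),
         group_df = unname(c(uni[gi, "num Df"], uni[gi, "den Df"])),
         group_p = unname(uni[gi, "Pr(>F)"]),
         within = within, posthoc = posthoc,
         adjusted_means = as.data.frame(summary(emm)),
         n_per_group = as.integer(table(dat$group)),
         correction_note = "no multiple-comparison correction across nodes/metrics (a priori hypothesis)"),
    class = "rm_ancova"
  )
}

#' @export
print.rm_ancova <- function(x, ...) {
  cat(sprintf("<rm_ancova> %s / %s: group F(%g, %g) = %.3f, p = %.4g\n",
              x$node, x$metric, x$group_df[1], x$group_df[2], x$group_f,
              x$group_p))
  print(x$posthoc, digits = 3)
  invisible(x)
}

#' Partial Pearson correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after linear
#' regression on the covariates (with intercept). The p-value uses a t
#' reference with n - 2 - k degrees of freedom, k the number of covariates.
#' With no covariates this reduces to the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix / data.frame of covariate
#'   columns.
#' @return A list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) tn_stop("partial_correlation: x and y lengths differ")
  k <- 0L
  if (!is.null(covariates)) {
    z <- as.matrix(covariates)
    if (nrow(z) != n) tn_stop("partial_correlation: covariate rows differ from n")
    k <- ncol(z)
    if (n <= k + 2L) tn_stop("partial_correlation: need n > covariates + 2")
    qz <- qr(cbind(1, z))
    x <- qr.resid(qz, x)
    y <- qr.resid(qz, y)
  }
  if (sd(x) < .Machine$double.eps * 100 || sd(y) < .Machine$double.eps * 100) {
    tn_stop("partial_correlation: degenerate residual variance")
  }
  r <- cor(x, y)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  list(r = r, p = p, df = df, n = n)
}

#' Derived UPDRS score columns
#'
#' Adds the standard derived scores to a raw UPDRS item table:
#' resting tremor = item 20; total tremor = items 16 + 20 + 21;
#' bradykinesia = items 23 + 24 + 25 + 26; rigidity = item 22.
#'
#' @param items Data frame with columns `item16`, `item20`, `item21`,
#'   `item22`, `item23`, `item24`, `item25`, `item26` (other columns pass
#'   through).
#' @return The input with columns `resting_tremor`, `total_tremor`,
#'   `bradykinesia`, `rigidity` appended.
#' @export
score_definitions <- function(items) {
  need <- paste0("item", c(16, 20, 21, 22, 23, 24, 25, 26))
  miss <- setdiff(need, names(items))
  if (length(miss)) {
    tn_stop("score_definitions: missing item column(s): ",
            paste(miss, collapse = ", "))
  }
  items$resting_tremor <- items$item20
  items$total_tremor <- items$item16 + items$item20 + items$item21
  items$bradykinesia <- items$item23 + items$item24 + items$item25 + items$item26
  items$rigidity <- items$item22
  items
}

#' Partial-correlation screen of centrality metrics against clinical scores
#'
#' Computes age/sex-adjusted partial Pearson correlations between
#' density-averaged centrality values and every requested clinical score,
#' over a grid of nodes and metrics, optionally within one group. Used both
#' for the hypothesis scores (tremor) and for specificity scores
#' (bradykinesia, rigidity, total scores), with no multiplicity correction
#' by design.
#'
#' @param profiles List of [profile_subject()] results.
#' @param cohort Cohort data frame including the score columns.
#' @param nodes,metrics Character vectors defining the grid.
#' @param scores Score column names in `cohort`.
#' @param group Optional single group label to restrict to.
#' @param covariates Covariate column names (default age and sex).
#' @return A data.frame of class `stat_report` with columns `node`,
#'   `metric`, `score`, `r`, `p`, `n`; the no-correction policy is recorded
#'   in attribute `correction_note`.
#' @export
specificity_screen <- function(profiles, cohort, nodes, metrics, scores,
                               group = NULL, covariates = c("age", "sex")) {
  cohort <- check_cohort(cohort)
  if (!is.null(group)) cohort <- cohort[cohort$group %in% group, , drop = FALSE]
  if (!nrow(cohort)) tn_stop("specificity_screen: no subjects selected")
  miss <- setdiff(scores, names(cohort))
  if (length(miss)) tn_stop("specificity_screen: unknown score(s): ",
                            paste(miss, collapse = ", "))
  z <- if (length(covariates)) as.matrix(cohort[covariates]) else NULL
  rows <- list()
  for (node in nodes) {
    for (metric in metrics) {
      avg <- rowMeans(profile_matrix(profiles, cohort$subject_id, node, metric))
      for (score in scores) {
        pc <- partial_correlation(avg, cohort[[score]], z)
        rows[[length(rows) + 1L]] <- data.frame(
          node = node, metric = metric, score = score,
          r = pc$r, p = pc$p, n = pc$n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "correction_note") <-
    "no multiple-comparison correction across nodes/metrics/scores (a priori hypothesis)"
  class(out) <- c("stat_report", "data.frame")
  out
}
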