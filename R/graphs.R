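#' Pearson connectivity matrix of a cleaned series
#'
#' Pairwise Pearson correlation between every pair of node series, with the
#' diagonal fixed to zero. Zero-variance nodes get zero correlations with a
#' warning naming them.
#'
#' @param ts A [roi_ts] (normally the cleaned series).
#' @return A list of class `connectivity_matrix` with fields `subject_id`,
#'   `node_labels` and `r` (N x N symmetric, zero diagonal).
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  if (nrow(ts$values) < 3L) tn_stop("correlation_matrix: need T >= 3")
  sds <- apply(ts$values, 2, sd)
  flat <- sds == 0
  vals <- ts$values
  if (any(flat)) {
    warning("correlation_matrix: zero-variance node(s): ",
            paste(ts$node_labels[flat], collapse = ", "), call. = FALSE)
    # give them a unit dummy so cor() does not error; zero the rows after
    vals[, flat] <- rnorm(nrow(vals) * sum(flat))
  }
  r <- cor(vals)
  if (any(flat)) {
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  r <- (r + t(r)) / 2
  diag(r) <- 0
  dimnames(r) <- list(ts$node_labels, ts$node_labels)
  structure(list(subject_id = ts$subject_id, node_labels = ts$node_labels,
                 r = r),
            class = "connectivity_matrix")
}

#' Density grid for network thresholding
#'
#' The ordered set of connection densities at which a connectivity matrix is
#' binarized. The defaults (0.10 to 0.40 in steps of 0.01) give the
#' conventional 31-density grid over which small-world organization of
#' resting-state graphs is retained.
#'
#' @param start,stop,step Grid parameters; all densities must lie in (0, 1).
#' @return Numeric vector of class `density_grid`.
#' @examples
#' length(density_grid())  # 31
#' @export
density_grid <- function(start = 0.10, stop = 0.40, step = 0.01) {
  if (!(start > 0 && stop < 1 && start <= stop && step > 0)) {
    tn_stop("density_grid: need 0 < start <= stop < 1 and step > 0")
  }
  n <- round((stop - start) / step) + 1L
  d <- start + step * (seq_len(n) - 1L)
  if (any(diff(d) <= 0)) tn_stop("density_grid: grid not strictly increasing")
  structure(d, class = "density_grid")
}

#' Threshold a connectivity matrix into a binary adjacency stack
#'
#' For each density d the `round(d * N * (N - 1) / 2)` strongest
#' (largest signed, or largest absolute with `absolute = TRUE`) off-diagonal
#' correlations are kept as undirected edges; everything else is zero. Edge
#' sets are nested across densities by construction. Ties are broken by
#' lexicographic (row, column) order of the upper triangle for determinism.
#'
#' @param cm A [correlation_matrix()] result.
#' @param grid A [density_grid()] (or numeric vector of densities).
#' @param absolute Rank by absolute correlation instead of signed value.
#' @return A list of class `adjacency_stack` with fields `subject_id`,
#'   `node_labels`, `densities` and `adj` (named list of binary N x N
#'   matrices).
#' @export
threshold_by_density <- function(cm, grid = density_grid(), absolute = FALSE) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  n <- length(cm$node_labels)
  n_pairs <- n * (n - 1L) / 2L
  ut <- which(upper.tri(cm$r))
  strength <- cm$r[ut]
  if (absolute) strength <- abs(strength)
  # order: decreasing strength, ties by position (lexicographic in column-
  # major upper triangle, i.e. by (j, i); fixed and documented)
  ord <- order(-strength, ut)
  stack <- list()
  for (d in as.numeric(grid)) {
    k <- round(d * n_pairs)
    if (k > n_pairs) {
      tn_stop("threshold_by_density: density ", d, " requests ", k,
              " edges but only ", n_pairs, " pairs exist")
    }
    a <- matrix(0L, n, n, dimnames = list(cm$node_labels, cm$node_labels))
    keep <- ut[ord[seq_len(k)]]
    a[keep] <- 1L
    a <- a + t(a)
    stack[[sprintf("%.3f", d)]] <- a
  }
  structure(list(subject_id = cm$subject_id, node_labels = cm$node_labels,
                 densities = as.numeric(grid), adj = stack),
            class = "adjacency_stack")
}
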