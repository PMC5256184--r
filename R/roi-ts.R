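#' ROI time-series container
#'
#' Bundles one subject's region-of-interest (ROI) signal matrix with its node
#' labels and sampling interval. The matrix is time (rows) by node (columns).
#'
#' @param values Numeric T x N matrix, one column per ROI.
#' @param node_labels Character vector of length N. Defaults to the 92-region
#'   atlas labels when N = 92, generic `roi_###` labels otherwise.
#' @param subject_id Subject identifier.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @return An object of class `roi_ts`.
#' @examples
#' ts <- roi_ts(matrix(rnorm(50 * 4), 50, 4), subject_id = "s01")
#' dim(ts)
#' @export
roi_ts <- function(values, node_labels = NULL, subject_id = "subject",
                   tr_seconds = 2.0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) tn_stop("roi_ts: values contain missing entries")
  if (nrow(values) < 2L) tn_stop("roi_ts: need at least 2 time points")
  if (is.null(node_labels)) {
    node_labels <- if (!is.null(colnames(values))) colnames(values) else
      default_node_labels(ncol(values))
  }
  if (length(node_labels) != ncol(values)) {
    tn_stop("roi_ts: ", length(node_labels), " labels for ",
            ncol(values), " columns")
  }
  if (anyDuplicated(node_labels)) tn_stop("roi_ts: duplicated node labels")
  if (tr_seconds <= 0) tn_stop("roi_ts: tr_seconds must be positive")
  colnames(values) <- node_labels
  structure(
    list(subject_id = as.character(subject_id),
         node_labels = as.character(node_labels),
         values = values,
         tr_seconds = tr_seconds),
    class = "roi_ts"
  )
}

#' @export
dim.roi_ts <- function(x) dim(x$values)

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject '%s': %d time points x %d nodes, TR = %gs\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Nuisance regressor table
#'
#' Holds the per-volume nuisance series used for time-series cleaning: six
#' rigid-body motion parameters (translations in mm, rotations in radians)
#' plus mean white-matter and cerebrospinal-fluid signals.
#'
#' @param motion6 Numeric T x 6 matrix, columns tx, ty, tz, rx, ry, rz.
#' @param wm,csf Numeric vectors of length T.
#' @param rotation_unit `"radians"` (default) or `"degrees"`; degrees are
#'   converted to radians on construction.
#' @return A data.frame of class `nuisance_table` with columns
#'   tx, ty, tz, rx, ry, rz, wm, csf.
#' @export
nuisance_table <- function(motion6, wm, csf, rotation_unit = c("radians", "degrees")) {
  rotation_unit <- match.arg(rotation_unit)
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) tn_stop("nuisance_table: motion6 must have 6 columns")
  t_n <- nrow(motion6)
  if (length(wm) != t_n || length(csf) != t_n) {
    tn_stop("nuisance_table: wm/csf length must match motion6 rows")
  }
  if (rotation_unit == "degrees") {
    motion6[, 4:6] <- motion6[, 4:6] * pi / 180
  }
  out <- data.frame(motion6, wm = as.numeric(wm), csf = as.numeric(csf))
  names(out) <- c("tx", "ty", "tz", "rx", "ry", "rz", "wm", "csf")
  class(out) <- c("nuisance_table", "data.frame")
  out
}
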