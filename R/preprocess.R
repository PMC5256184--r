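#' Discard unstable initial volumes
#'
#' Removes the first `n_discard` time points of a series (and, optionally, of
#' a matching nuisance table) to drop the initial scanner-equilibration
#' period. With the default acquisition of 185 volumes this leaves 175.
#'
#' @param ts A [roi_ts].
#' @param n_discard Number of leading volumes to drop (default 10).
#' @param nuisance Optional [nuisance_table] trimmed in lockstep.
#' @return The trimmed `roi_ts`, or a list `list(ts, nuisance)` when a
#'   nuisance table is supplied.
#' @export
discard_initial <- function(ts, n_discard = 10L, nuisance = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) tn_stop("discard_initial: n_discard must be >= 0")
  if (n_discard >= nrow(ts$values)) {
    tn_stop("discard_initial: n_discard (", n_discard,
            ") must be smaller than the number of time points (",
            nrow(ts$values), ")")
  }
  keep <- if (n_discard == 0L) seq_len(nrow(ts$values)) else -seq_len(n_discard)
  out <- roi_ts(ts$values[keep, , drop = FALSE], ts$node_labels,
                ts$subject_id, ts$tr_seconds)
  if (is.null(nuisance)) return(out)
  nu <- nuisance[keep, , drop = FALSE]
  class(nu) <- class(nuisance)
  list(ts = out, nuisance = nu)
}

#' Expand 6 rigid-body motion parameters to 24 regressors
#'
#' Produces the strict 24-parameter motion model: the six rigid-body
#' parameters, their first derivatives (backward differences, first row
#' zero-padded), and the squares of those twelve series.
#'
#' @param motion6 Numeric T x 6 matrix (or the motion columns of a
#'   [nuisance_table]).
#' @return Numeric T x 24 matrix with descriptive column names.
#' @examples
#' m <- matrix(rnorm(60), 10, 6)
#' ncol(expand_motion24(m))
#' @export
expand_motion24 <- function(motion6) {
  if (inherits(motion6, "nuisance_table")) {
    motion6 <- as.matrix(motion6[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  }
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) {
    tn_stop("expand_motion24: expected 6 columns, got ", ncol(motion6))
  }
  d <- rbind(0, diff(motion6))
  out <- cbind(motion6, d, motion6^2, d^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0("d_", base), paste0(base, "_sq"),
                     paste0("d_", base, "_sq"))
  out
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least-squares residualization of every node series on the given
#' regressors plus an intercept. Collinear (rank-deficient) columns are
#' dropped with a warning naming them. Residuals are orthogonal to every
#' retained regressor and are mean-zero.
#'
#' @param ts A [roi_ts].
#' @param regressors Numeric T x k matrix (e.g. the 24 motion regressors
#'   plus WM and CSF columns).
#' @return A `roi_ts` of residuals, with an attribute `dropped_regressors`
#'   naming any removed columns.
#' @export
regress_nuisance <- function(ts, regressors) {
  stopifnot(inherits(ts, "roi_ts"))
  x <- cbind(intercept = 1, as.matrix(regressors))
  if (nrow(x) != nrow(ts$values)) {
    tn_stop("regress_nuisance: regressors have ", nrow(x),
            " rows but series has ", nrow(ts$values))
  }
  if (nrow(x) <= ncol(x)) {
    tn_stop("regress_nuisance: fewer time points (", nrow(x),
            ") than regressors (", ncol(x), ")")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("reg", seq_len(ncol(x)))
  qrx <- qr(x)
  dropped <- character(0)
  if (qrx$rank < ncol(x)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
    warning("regress_nuisance: dropping collinear regressor(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    qrx <- qr(x[, keep, drop = FALSE])
  }
  res <- qr.resid(qrx, ts$values)
  out <- roi_ts(res, ts$node_labels, ts$subject_id, ts$tr_seconds)
  attr(out, "dropped_regressors") <- dropped
  out
}

#' Zero-phase band-pass filter
#'
#' Applies a second-order Butterworth band-pass forward and backward
#' (zero-phase) to every node series. Defaults to the conventional
#' resting-state band 0.01-0.08 Hz.
#'
#' @param ts A [roi_ts].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < ` Nyquist (`1 / (2 * tr_seconds)`).
#' @return The filtered `roi_ts`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "roi_ts"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    tn_stop("bandpass: need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyquist) {
    tn_stop("bandpass: high_hz (", high_hz, " Hz) must be below the Nyquist ",
            "frequency ", nyquist, " Hz for TR = ", ts$tr_seconds, " s")
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  # demean first: DC is outside the passband, and removing it up front
  # avoids start-up transients of the forward-backward pass
  filt <- apply(ts$values, 2, function(col) {
    signal::filtfilt(bf, col - mean(col))
  })
  roi_ts(filt, ts$node_labels, ts$subject_id, ts$tr_seconds)
}

#' Head-motion quality-control summaries
#'
#' Computes three scalar summaries of a subject's six rigid-body motion
#' parameters: the summed volume-to-volume translational excursion
#' (root-mean-square over the three axes, in mm), the summed rotational
#' excursion (converted to degrees), and the mean framewise displacement
#' (sum of absolute translation steps plus rotation steps scaled by a 50-mm
#' head radius). The framewise displacement is the standard scalar
#' convention computed from the six parameters; it is not a voxel-level
#' quantity.
#'
#' @param motion6 Numeric T x 6 matrix or [nuisance_table] (rotations in
#'   radians).
#' @return A list of class `motion_qc` with fields `sum_translation_mm`,
#'   `sum_rotation_deg`, `mean_fd_mm`.
#' @export
motion_qc <- function(motion6) {
  if (inherits(motion6, "nuisance_table")) {
    motion6 <- as.matrix(motion6[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  }
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) tn_stop("motion_qc: expected 6 columns")
  if (nrow(motion6) < 2L) tn_stop("motion_qc: need at least 2 volumes")
  d <- diff(motion6)
  sum_trans <- sum(sqrt(rowSums(d[, 1:3, drop = FALSE]^2)))
  sum_rot <- sum(sqrt(rowSums(d[, 4:6, drop = FALSE]^2))) * 180 / pi
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    50 * rowSums(abs(d[, 4:6, drop = FALSE]))
  structure(list(sum_translation_mm = sum_trans,
                 sum_rotation_deg = sum_rot,
                 mean_fd_mm = mean(fd)),
            class = "motion_qc")
}

#' @export
print.motion_qc <- function(x, ...) {
  cat(sprintf(
    "<motion_qc> sum translation %.3f mm | sum rotation %.3f deg | mean FD %.4f mm\n",
    x$sum_translation_mm, x$sum_rotation_deg, x$mean_fd_mm))
  invisible(x)
}

#' Clean one subject's ROI time series
#'
#' Runs the fixed cleaning order: discard initial volumes, regress out the
#' 24-parameter motion expansion plus WM and CSF signals (with intercept),
#' then band-pass filter the residuals. Motion QC is computed on the
#' retained (post-discard) volumes.
#'
#' @param ts A raw [roi_ts].
#' @param nuisance The subject's [nuisance_table] (same length as the raw
#'   series).
#' @param n_discard Leading volumes to drop (default 10).
#' @param low_hz,high_hz Band-pass edges in Hz.
#' @return A list of class `preprocessed_subject` with fields `ts` (cleaned
#'   series), `qc` ([motion_qc]) and `meta` (n_discard, band edges,
#'   regressor count, dropped regressors).
#' @export
preprocess_subject <- function(ts, nuisance, n_discard = 10L,
                               low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "roi_ts"))
  if (nrow(nuisance) != nrow(ts$values)) {
    tn_stop("preprocess_subject: nuisance rows (", nrow(nuisance),
            ") must match raw series length (", nrow(ts$values), ")")
  }
  trimmed <- discard_initial(ts, n_discard, nuisance)
  motion24 <- expand_motion24(trimmed$nuisance)
  regs <- cbind(motion24, wm = trimmed$nuisance$wm, csf = trimmed$nuisance$csf)
  resid <- regress_nuisance(trimmed$ts, regs)
  clean <- bandpass(resid, low_hz, high_hz)
  structure(
    list(ts = clean,
         qc = motion_qc(trimmed$nuisance),
         meta = list(n_discard = as.integer(n_discard),
                     low_hz = low_hz, high_hz = high_hz,
                     n_regressors = ncol(regs) + 1L,
                     dropped_regressors = attr(resid, "dropped_regressors"))),
    class = "preprocessed_subject"
  )
}
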