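#' Normalize retention times against the common-peak template
#'
#' Applies a piecewise-linear time warp mapping each matched common-peak
#' apex onto its expected retention time (the calibration and
#' normalization step of standardized fingerprinting). Outside the
#' outermost anchors the nearest segment's slope is extended. The
#' intensity trace is then resampled by linear interpolation onto the
#' grid supplied (by default the chromatogram's own grid).
#'
#' @param chrom A [chromatogram()].
#' @param matched Matched peak table for this sample (rows of the
#'   [match_common_peaks()] output), needing `apex_time` and
#'   `common_index`; at least two anchors.
#' @param reference_times Expected retention times by common index.
#' @param grid Output time grid; defaults to `chrom$time`.
#' @return A [chromatogram()] on `grid` with warped retention times.
#' @export
normalize_retention <- function(chrom, matched,
                                reference_times = default_peak_specs()$rt,
                                grid = NULL) {
  matched <- matched[!is.na(matched$common_index), , drop = FALSE]
  if (nrow(matched) < 2L)
    stop("need at least two matched anchor peaks to define the warp")
  obs <- matched$apex_time
  expd <- reference_times[matched$common_index]
  o <- order(obs)
  obs <- obs[o]; expd <- expd[o]
  warped <- piecewise_warp(chrom$time, obs, expd)
  if (is.null(grid)) grid <- chrom$time
  y <- stats::approx(warped, chrom$intensity, xout = grid, rule = 2)$y
  chromatogram(grid, y, sample_id = attr(chrom, "sample_id"),
               metadata = attr(chrom, "metadata"))
}

# piecewise-linear map anchored at (obs -> expd); linear extrapolation
# with the first/last segment slope outside the anchors
piecewise_warp <- function(t, obs, expd) {
  n <- length(obs)
  out <- stats::approx(obs, expd, xout = t, rule = 1)$y
  slope_lo <- (expd[2] - expd[1]) / (obs[2] - obs[1])
  slope_hi <- (expd[n] - expd[n - 1]) / (obs[n] - obs[n - 1])
  lo <- t < obs[1]; hi <- t > obs[n]
  out[lo] <- expd[1] + slope_lo * (t[lo] - obs[1])
  out[hi] <- expd[n] + slope_hi * (t[hi] - obs[n])
  out
}

#' Build a fingerprint vector from a chromatogram or a peak table
#'
#' Two modes are supported: `"trace"` uses the full standardized trace
#' with a running-median baseline subtracted (the whole-chromatogram
#' fingerprint used for similarity analysis); `"peaks"` uses the vector of
#' common-peak areas (missing common peaks contribute 0), the compact
#' fingerprint used for clustering and quantification.
#'
#' @param x A [chromatogram()] (trace mode) or the matched peak rows of
#'   one sample (peak mode).
#' @param mode `"trace"` or `"peaks"`.
#' @param n_common Number of common peaks (peak mode).
#' @param baseline_window Running-median window, minutes (trace mode).
#' @return A numeric fingerprint vector with attributes `mode` and
#'   `sample_id`.
#' @export
fingerprint_vector <- function(x, mode = c("trace", "peaks"),
                               n_common = 10L, baseline_window = 2) {
  mode <- match.arg(mode)
  if (mode == "trace") {
    stopifnot(inherits(x, "chromatogram"))
    dt <- stats::median(diff(x$time))
    k <- max(3L, 2L * floor(baseline_window / dt / 2) + 1L)
    k <- min(k, 2L * floor((nrow(x) - 1) / 2) + 1L)
    base <- stats::runmed(x$intensity, k, endrule = "median")
    v <- pmax(x$intensity - base, 0)
    sid <- attr(x, "sample_id")
  } else {
    stopifnot(is.data.frame(x), "common_index" %in% names(x))
    v <- numeric(n_common)
    v[x$common_index] <- x$area
    sid <- if (nrow(x)) x$sample_id[1] else NA_character_
  }
  structure(v, mode = mode, sample_id = sid)
}

#' Mean-reference fingerprint
#'
#' The reference ("mean chromatogram") is the pointwise arithmetic mean of
#' the standardized fingerprints; a median reference is available for
#' robustness checks.
#'
#' @param vectors List of equal-length fingerprint vectors.
#' @param fun `"mean"` (default) or `"median"`.
#' @return A fingerprint vector of the same length.
#' @export
build_reference <- function(vectors, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  stopifnot(length(vectors) >= 1L)
  lens <- vapply(vectors, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("fingerprint vectors must share one dimension")
  m <- do.call(cbind, lapply(vectors, as.numeric))
  v <- if (fun == "mean") rowMeans(m) else apply(m, 1, stats::median)
  structure(v, mode = attr(vectors[[1]], "mode"), sample_id = "reference")
}

#' Cosine and Pearson similarity of two fingerprints
#'
#' @param x,y Equal-length numeric vectors; `y` must not be all-zero.
#' @return A list with `cosine` and `correlation`.
#' @export
similarity <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("fingerprints must share one dimension")
  ny <- sqrt(sum(y^2))
  if (ny == 0) stop("reference fingerprint has zero norm")
  nx <- sqrt(sum(x^2))
  if (nx == 0) {
    warning("zero-norm sample fingerprint; similarity undefined")
    return(list(cosine = NA_real_, correlation = NA_real_))
  }
  list(cosine = sum(x * y) / (nx * ny),
       correlation = stats::cor(x, y))
}

#' Score every sample against a reference fingerprint
#'
#' @param vectors Named list of sample fingerprint vectors.
#' @param reference Reference fingerprint, e.g. from [build_reference()].
#' @param classes Optional named vector mapping sample id to class for
#'   class-level mean similarity.
#' @return A data frame: sample_id, cosine, correlation (attribute
#'   `class_means`: per-class mean cosine when `classes` given).
#' @export
similarity_report <- function(vectors, reference, classes = NULL) {
  res <- do.call(rbind, lapply(names(vectors), function(sid) {
    s <- similarity(vectors[[sid]], reference)
    data.frame(sample_id = sid, cosine = s$cosine,
               correlation = s$correlation, stringsAsFactors = FALSE)
  }))
  if (!is.null(classes)) {
    cls <- classes[res$sample_id]
    attr(res, "class_means") <-
      tapply(res$cosine, cls, mean)
    res$class <- unname(cls)
  }
  res
}
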