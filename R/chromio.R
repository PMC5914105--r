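#' Construct a chromatogram
#'
#' @param time Numeric vector of retention times, minutes, strictly
#'   increasing.
#' @param intensity Numeric vector of detector response, same length.
#' @param sample_id Sample identifier.
#' @param metadata Named list (class, batch, instrument, column, flow rate,
#'   temperature, injection volume, ...).
#' @return A data frame of class `chromatogram` with columns `time` and
#'   `intensity` and attributes `sample_id` and `metadata`.
#' @export
chromatogram <- function(time, intensity, sample_id = "sample",
                         metadata = list()) {
  if (length(time) != length(intensity))
    stop("time and intensity must have equal length")
  if (!all(is.finite(time)) || !all(is.finite(intensity)))
    stop("chromatogram values must be finite")
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  out <- data.frame(time = as.numeric(time),
                    intensity = as.numeric(intensity))
  attr(out, "sample_id") <- sample_id
  attr(out, "metadata") <- metadata
  class(out) <- c("chromatogram", "data.frame")
  out
}

#' Read a chromatogram from two-column delimited text
#'
#' Accepts whitespace-, comma- or tab-delimited files with two numeric
#' columns (time in minutes, detector response); a single header line is
#' detected and skipped.
#'
#' @param path File to read.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param metadata Named list of acquisition metadata.
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path, sample_id = NULL, metadata = list()) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty chromatogram file: ", path)
  split_line <- function(x) strsplit(trimws(x), "[,\t ]+")[[1]]
  first <- suppressWarnings(as.numeric(split_line(lines[1])))
  start <- if (anyNA(first)) 2L else 1L
  if (start > length(lines)) stop("no data rows in ", path)
  n <- length(lines) - start + 1L
  tm <- numeric(n); iy <- numeric(n)
  for (i in seq_len(n)) {
    cells <- suppressWarnings(as.numeric(split_line(lines[start + i - 1L])))
    if (length(cells) < 2L || anyNA(cells[1:2]))
      stop(sprintf("non-numeric or malformed row at line %d of %s",
                   start + i - 1L, path))
    tm[i] <- cells[1]; iy[i] <- cells[2]
  }
  if (is.unsorted(tm, strictly = TRUE))
    stop("time column is not strictly increasing in ", path)
  chromatogram(tm, iy, sample_id = sample_id, metadata = metadata)
}

#' Write a chromatogram as two-column delimited text
#'
#' Values are written with full double precision so that
#' `read_chromatogram(write_chromatogram(x))` round-trips exactly.
#'
#' @param chrom A [chromatogram()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  lines <- c("time_min\tintensity",
             sprintf("%.17g\t%.17g", chrom$time, chrom$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Estimate detector noise in a peak-free window
#'
#' Detrends the window with a linear fit and returns the median absolute
#' deviation of the residuals scaled to the normal (a robust standard
#' deviation). This is the amplitude used in signal-to-noise thresholds and
#' in the 3:1 / 10:1 LOD/LOQ definitions.
#'
#' @param chrom A [chromatogram()].
#' @param window Numeric length-2 vector, start/end of a peak-free interval
#'   in minutes (at least 20 grid points).
#' @param peak_times Optional known peak apex times; an error is raised if
#'   any falls inside the window (widened by `peak_margin`).
#' @param peak_margin Margin (minutes) around `peak_times` that must not
#'   intersect the window.
#' @return Noise amplitude in detector units (0 for a constant window).
#' @export
estimate_noise <- function(chrom, window, peak_times = NULL,
                           peak_margin = 1) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (window[1] < min(chrom$time) || window[2] > max(chrom$time))
    stop("noise window lies outside the time grid")
  if (!is.null(peak_times) &&
      any(peak_times + peak_margin > window[1] &
          peak_times - peak_margin < window[2]))
    stop("noise window overlaps a configured peak")
  sel <- chrom$time >= window[1] & chrom$time <= window[2]
  if (sum(sel) < 20L) stop("noise window must contain at least 20 points")
  t <- chrom$time[sel]; y <- chrom$intensity[sel]
  res <- stats::residuals(stats::lm(y ~ t))
  stats::mad(res, center = 0)
}

#' Detect peaks in a chromatogram
#'
#' Smooths the trace with a Savitzky-Golay filter, locates local maxima
#' whose baseline-corrected height reaches `min_snr x noise`, and sets each
#' peak's integration bounds at the flanking valleys or at baseline return,
#' capped at five sigma-equivalents (from the full width at half maximum)
#' on either side of the apex. Apexes closer than `min_separation` are
#' merged, keeping the taller.
#'
#' @param chrom A [chromatogram()].
#' @param noise Noise amplitude (detector units), e.g. from
#'   [estimate_noise()].
#' @param min_snr Minimum signal-to-noise ratio for a reported peak.
#' @param sg_window Savitzky-Golay window length in points (odd).
#' @param min_separation Minimum apex separation, minutes.
#' @return A data frame of peaks: `apex_time`, `height` (baseline
#'   corrected), `area` (chord-baseline trapezoid, see
#'   [integrate_peak()]), `left_bound`, `right_bound`, sorted by apex time.
#' @export
detect_peaks <- function(chrom, noise, min_snr = 10, sg_window = 21L,
                         min_separation = 0.3) {
  if (min_snr <= 0) stop("min_snr must be positive")
  if (noise < 0) stop("noise must be non-negative")
  n <- nrow(chrom)
  if (n == 0L) stop("empty chromatogram")
  empty <- data.frame(apex_time = numeric(), height = numeric(),
                      area = numeric(), left_bound = numeric(),
                      right_bound = numeric())
  if (n < sg_window + 2L) return(empty)
  t <- chrom$time
  y <- signal::sgolayfilt(chrom$intensity, p = 3, n = sg_window)
  dy <- diff(y)
  # interior local maxima of the smoothed trace
  apexes <- which(dy[-length(dy)] > 0 & dy[-1] <= 0) + 1L
  if (!length(apexes)) return(empty)

  # with zero noise, suppress numerical smoothing ripples with a small
  # floor relative to the trace amplitude
  floor_level <- if (noise > 0) noise else 1e-6 * diff(range(y))
  peaks <- list()
  for (a in apexes) {
    # walk to flanking valleys or baseline return (smoothed trace within
    # 2x noise of its local minimum on that side)
    l <- a
    while (l > 1L && y[l - 1L] <= y[l]) l <- l - 1L
    r <- a
    while (r < n && y[r + 1L] <= y[r]) r <- r + 1L
    base <- (y[l] + y[r]) / 2
    height <- y[a] - base
    if (noise > 0) {
      if (height < min_snr * floor_level) next
    } else if (height <= floor_level) next
    # cap bounds at +/- 5 sigma-equivalents from FWHM
    half <- base + height / 2
    li <- a; while (li > l && y[li - 1L] > half) li <- li - 1L
    ri <- a; while (ri < r && y[ri + 1L] > half) ri <- ri + 1L
    fwhm <- t[ri] - t[li]
    sigma_eq <- max(fwhm / 2.3548, 2 * (t[2] - t[1]))
    l <- max(l, which.min(abs(t - (t[a] - 5 * sigma_eq))))
    r <- min(r, which.min(abs(t - (t[a] + 5 * sigma_eq))))
    if (l >= a || r <= a) next
    peaks[[length(peaks) + 1L]] <- data.frame(
      apex_time = t[a], height = height, apex_idx = a,
      left_bound = t[l], right_bound = t[r])
  }
  if (!length(peaks)) return(empty)
  pk <- do.call(rbind, peaks)
  pk <- pk[order(pk$apex_time), , drop = FALSE]
  # merge apexes closer than min_separation, keeping the taller
  keep <- rep(TRUE, nrow(pk))
  i <- 1L
  while (i < nrow(pk)) {
    j <- i + 1L
    while (j <= nrow(pk) && keep[j] == FALSE) j <- j + 1L
    if (j > nrow(pk)) break
    if (pk$apex_time[j] - pk$apex_time[i] < min_separation) {
      if (pk$height[j] >= pk$height[i]) { keep[i] <- FALSE; i <- j }
      else keep[j] <- FALSE
    } else i <- j
  }
  pk <- pk[keep, , drop = FALSE]
  pk$area <- vapply(seq_len(nrow(pk)), function(k)
    integrate_peak(chrom, pk[k, ]), numeric(1))
  rownames(pk) <- NULL
  pk[, c("apex_time", "height", "area", "left_bound", "right_bound")]
}

#' Integrate a peak with a chord baseline
#'
#' Trapezoidal integral of the intensity minus the straight line (chord)
#' joining the intensities at the two bounds. Bound intensities are
#' averaged over a few neighbouring points to stabilise the chord against
#' detector noise.
#'
#' @param chrom A [chromatogram()].
#' @param peak A list or one-row data frame with `left_bound` and
#'   `right_bound` (minutes).
#' @param anchor_pts Half-width, in points, of the window averaged at each
#'   bound for the chord anchors.
#' @return Peak area in detector units x minutes (0 for zero-width
#'   bounds).
#' @export
integrate_peak <- function(chrom, peak, anchor_pts = 3L) {
  lb <- peak$left_bound; rb <- peak$right_bound
  if (lb > rb) stop("peak bounds are reversed")
  if (lb < min(chrom$time) || rb > max(chrom$time))
    stop("peak bounds lie outside the time grid")
  sel <- which(chrom$time >= lb & chrom$time <= rb)
  if (length(sel) < 2L) return(0)
  t <- chrom$time[sel]; y <- chrom$intensity[sel]
  n <- nrow(chrom)
  anchor <- function(i) {
    win <- max(1L, i - anchor_pts):min(n, i + anchor_pts)
    mean(chrom$intensity[win])
  }
  y0 <- anchor(sel[1]); y1 <- anchor(sel[length(sel)])
  baseline <- y0 + (y1 - y0) * (t - t[1]) / (t[length(t)] - t[1])
  z <- y - baseline
  sum(diff(t) * (z[-1] + z[-length(z)]) / 2)
}

#' Match detected peaks to the common-peak template
#'
#' Assigns each detected peak to the nearest expected retention time when
#' the relative deviation is within `rel_tolerance`; at most one peak per
#' common index is kept per sample (the closest wins; ties go to the larger
#' area). Relative retention times (RRT) and relative peak areas (RPA) are
#' computed against the internal reference peak (adenosine by default).
#' Samples whose reference peak is missing are flagged and get `NA`
#' RRT/RPA, with a warning.
#'
#' @param peak_tables Named list of peak data frames from [detect_peaks()]
#'   (names are sample ids), or a single data frame.
#' @param reference_times Expected retention times of the common peaks,
#'   sorted increasing.
#' @param reference_analytes Analyte labels, one per reference time.
#' @param reference_index Common-peak index of the internal reference
#'   (default: the adenosine position).
#' @param rel_tolerance Maximum |observed - expected| / expected for a
#'   match, in (0, 0.1].
#' @return A data frame: sample_id, common_index, analyte, apex_time,
#'   height, area, left_bound, right_bound, rrt, rpa, with attribute
#'   `flagged` listing samples lacking the reference peak.
#' @export
match_common_peaks <- function(peak_tables,
                               reference_times = default_peak_specs()$rt,
                               reference_analytes = default_peak_specs()$analyte,
                               reference_index = which(reference_analytes == "adenosine"),
                               rel_tolerance = 0.02) {
  if (rel_tolerance <= 0 || rel_tolerance > 0.1)
    stop("rel_tolerance must lie in (0, 0.1]")
  if (is.unsorted(reference_times, strictly = TRUE))
    stop("reference_times must be sorted increasing")
  if (is.data.frame(peak_tables)) peak_tables <- list(sample = peak_tables)
  if (is.null(names(peak_tables)))
    names(peak_tables) <- sprintf("sample_%d", seq_along(peak_tables))
  out <- list(); flagged <- character()
  for (sid in names(peak_tables)) {
    pk <- peak_tables[[sid]]
    if (!nrow(pk)) next
    nearest <- vapply(pk$apex_time, function(rt)
      which.min(abs(reference_times - rt)), integer(1))
    reldev <- abs(pk$apex_time - reference_times[nearest]) /
      reference_times[nearest]
    cand <- data.frame(pk, common_index = nearest, reldev = reldev)
    cand <- cand[cand$reldev <= rel_tolerance, , drop = FALSE]
    # at most one peak per common index: closest, ties to larger area
    cand <- cand[order(cand$common_index, cand$reldev, -cand$area), ,
                 drop = FALSE]
    cand <- cand[!duplicated(cand$common_index), , drop = FALSE]
    ref_row <- cand[cand$common_index == reference_index, , drop = FALSE]
    if (!nrow(ref_row)) {
      flagged <- c(flagged, sid)
      cand$rrt <- NA_real_; cand$rpa <- NA_real_
    } else {
      cand$rrt <- cand$apex_time / ref_row$apex_time
      cand$rpa <- cand$area / ref_row$area
    }
    cand$analyte <- reference_analytes[cand$common_index]
    cand$sample_id <- sid
    out[[sid]] <- cand[, c("sample_id", "common_index", "analyte",
                           "apex_time", "height", "area", "left_bound",
                           "right_bound", "rrt", "rpa")]
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), common_index = integer(),
               analyte = character(), apex_time = numeric(),
               height = numeric(), area = numeric(),
               left_bound = numeric(), right_bound = numeric(),
               rrt = numeric(), rpa = numeric())
  rownames(res) <- NULL
  if (length(flagged))
    warning("reference peak missing in: ", paste(flagged, collapse = ", "))
  attr(res, "flagged") <- flagged
  res
}
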