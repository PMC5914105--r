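#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on standard concentration,
#' `area = slope x conc + intercept`; the coefficient of determination is
#' the squared Pearson correlation of the points.
#'
#' @param conc Standard concentrations, ug/mL (at least 3, not all equal).
#' @param area Peak areas at those concentrations.
#' @param analyte Analyte label.
#' @param height Optional peak heights at the same levels; fitted the same
#'   way to give the auxiliary height-per-concentration slope used for
#'   signal-to-noise based LOD/LOQ.
#' @param noise Optional noise amplitude; with `height` given, LOD/LOQ are
#'   filled in via [lod_loq()].
#' @return A list of class `calibration_curve`: analyte, slope, intercept,
#'   r_squared, linear_range, height_slope, lod, loq, n.
#' @export
fit_calibration <- function(conc, area, analyte = "analyte",
                            height = NULL, noise = NULL) {
  stopifnot(length(conc) == length(area))
  if (length(conc) < 3L) stop("need at least three calibration points")
  if (length(unique(conc)) < 2L)
    stop("calibration concentrations are all equal; fit is singular")
  fit <- stats::lm(area ~ conc)
  co <- stats::coef(fit)
  height_slope <- NA_real_
  if (!is.null(height))
    height_slope <- unname(stats::coef(stats::lm(height ~ conc))[2])
  lodloq <- c(lod = NA_real_, loq = NA_real_)
  if (!is.null(noise) && !is.na(height_slope))
    lodloq <- lod_loq(noise, height_slope)
  structure(
    list(analyte = analyte, slope = unname(co[2]),
         intercept = unname(co[1]),
         r_squared = stats::cor(conc, area)^2,
         linear_range = range(conc), height_slope = height_slope,
         lod = unname(lodloq["lod"]), loq = unname(lodloq["loq"]),
         n = length(conc)),
    class = "calibration_curve"
  )
}

#' Detection and quantification limits from signal-to-noise
#'
#' The limit of detection is the concentration whose peak height equals 3
#' times the noise amplitude, and the limit of quantification the
#' concentration at 10 times the noise, so `loq / lod = 10 / 3` always.
#'
#' @param noise Noise amplitude, detector units (>= 0).
#' @param height_slope Peak height per unit concentration (> 0).
#' @return Named vector `c(lod, loq)` in ug/mL.
#' @export
lod_loq <- function(noise, height_slope) {
  if (noise < 0) stop("noise must be non-negative")
  if (height_slope <= 0) stop("height_slope must be positive")
  c(lod = 3 * noise / height_slope, loq = 10 * noise / height_slope)
}

#' External standard quantification
#'
#' Inverts the analyte's own calibration line to a solution concentration,
#' converts to mass in the extract (`m = C x V`), and reports content per
#' gram of product.
#'
#' @param area Peak area.
#' @param curve A [fit_calibration()] curve (or list with `slope`,
#'   `intercept`, optionally `linear_range`).
#' @param extract_volume Extract volume, mL.
#' @param sample_mass Sample mass, g (> 0).
#' @return Content in mg/g. Areas below the intercept give 0 with a
#'   warning; areas outside the fitted range warn.
#' @export
esm_quantify <- function(area, curve, extract_volume = 50,
                         sample_mass = 1.00) {
  if (sample_mass <= 0) stop("sample_mass must be positive")
  conc <- (area - curve$intercept) / curve$slope
  if (!is.null(curve$linear_range)) {
    span <- curve$slope * curve$linear_range + curve$intercept
    if (any(area > max(span)) || any(area < min(span)))
      warning("area outside the fitted calibration span for ",
              curve$analyte %||% "analyte")
  }
  below <- conc < 0
  if (any(below)) {
    warning("area below the calibration intercept; content reported as 0")
    conc[below] <- 0
  }
  conc * extract_volume / 1000 / sample_mass
}

#' Precision and recovery statistics
#'
#' Relative standard deviation uses the sample (n-1) standard deviation,
#' the convention under which the published per-volume relative correction
#' factors reproduce their reported RSDs. With a spiking design supplied,
#' recovery is `100 x (measured - base) / spiked`.
#'
#' @param values Replicate measurements (at least 2, non-zero mean).
#' @param base Unspiked amount (for recovery).
#' @param spiked Spiked amount added (for recovery).
#' @return A list: n, mean, sd, rsd_percent, and recovery_percent when the
#'   spiking arguments are given.
#' @export
precision_stats <- function(values, base = NULL, spiked = NULL) {
  if (length(values) < 2L) stop("need at least two replicates")
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero; RSD undefined")
  out <- list(n = length(values), mean = m, sd = stats::sd(values),
              rsd_percent = 100 * stats::sd(values) / m)
  if (!is.null(base) && !is.null(spiked)) {
    if (spiked <= 0) stop("spiked amount must be positive")
    out$recovery_percent <- 100 * (m - base) / spiked
  }
  out
}
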