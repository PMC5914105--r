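#' Default peak specifications for the ten common fingerprint peaks
#'
#' Defines the common-peak layout used throughout the package: ten
#' baseline-separated peaks within a 30 min acquisition window, of which
#' peaks 4, 7, 8, 9 and 10 are the identified nucleosides (uracil, uridine,
#' adenine, guanosine and adenosine) and the remaining five are unidentified
#' common constituents. Detector response factors for the nucleosides equal
#' the slopes of their linear calibration curves (area units per ug/mL), so
#' that simulated areas are consistent with external-standard calibration.
#'
#' @return A data frame with one row per common peak and columns
#'   `common_index`, `analyte`, `rt` (retention time, minutes),
#'   `width_sigma` (Gaussian standard deviation, minutes) and
#'   `response_factor` (peak area units per ug/mL).
#' @export
default_peak_specs <- function() {
  specs <- data.frame(
    common_index = 1:10,
    analyte = c("unknown_1", "unknown_2", "unknown_3", "uracil",
                "unknown_5", "unknown_6", "uridine", "adenine",
                "guanosine", "adenosine"),
    rt = c(2.2, 3.0, 5.3, 6.8, 13.5, 20.0, 21.5, 23.2, 25.0, 27.5),
    width_sigma = c(0.06, 0.07, 0.08, 0.08, 0.10, 0.12, 0.12, 0.13,
                    0.14, 0.15),
    response_factor = c(30, 30, 30, 41.219, 30, 30, 23.568, 62.462,
                        22.077, 28.112),
    stringsAsFactors = FALSE
  )
  validate_peak_specs(specs)
  specs
}

validate_peak_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("common_index", "analyte", "rt", "width_sigma",
                  "response_factor") %in% names(specs)))
  if (any(specs$rt <= 0)) stop("retention times must be positive")
  if (any(specs$width_sigma <= 0)) stop("peak widths must be positive")
  if (any(specs$response_factor <= 0)) stop("response factors must be positive")
  if (is.unsorted(specs$rt, strictly = TRUE))
    stop("peak specs must be ordered by strictly increasing retention time")
  invisible(specs)
}

#' Construct a product-class content profile
#'
#' A class profile gives the mean content of each common-peak constituent
#' (mg per g of product) for one product class, the relative between-sample
#' variability, and the set of common peaks that are essentially absent in
#' that class.
#'
#' @param class_name Label for the product class.
#' @param mean_contents Numeric vector of mean contents (mg/g), one per
#'   common peak, named by analyte.
#' @param content_cv Shared between-sample coefficient of variation
#'   (fraction in `[0, 1)`); models batch-to-batch potency/dilution
#'   variation common to all constituents of a sample.
#' @param analyte_cv Small per-analyte coefficient of variation on top of
#'   the shared factor.
#' @param missing_peaks Integer vector of common-peak indices suppressed
#'   (near-zero amplitude) in this class.
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(class_name, mean_contents, content_cv = 0.08,
                          analyte_cv = 0.015, missing_peaks = integer()) {
  stopifnot(is.character(class_name), length(class_name) == 1L,
            is.numeric(mean_contents), all(mean_contents >= 0),
            content_cv >= 0, content_cv < 1, analyte_cv >= 0)
  structure(
    list(class_name = class_name, mean_contents = mean_contents,
         content_cv = content_cv, analyte_cv = analyte_cv,
         missing_peaks = as.integer(missing_peaks)),
    class = "class_profile"
  )
}

#' Default class profiles for the three fermented Cordyceps product classes
#'
#' Mean contents (mg/g) follow the per-class content orderings reported for
#' the three marketed products: Jinshuibao capsules and tablets show
#' adenosine > uridine > guanosine > adenine > uracil, while Bailing
#' capsules show adenosine > guanosine > uridine > uracil > adenine.
#' Bailing-like samples lack the unidentified constituents eluting at 5.3,
#' 13.5 and 20.0 min (common peaks 3, 5 and 6); tablet-like samples carry
#' the lowest level of the 3.0 min constituent (common peak 2).
#'
#' @param content_cv Shared between-sample coefficient of variation.
#' @param analyte_cv Per-analyte coefficient of variation.
#' @return A named list of three [class_profile()] objects:
#'   `capsule_A` (Jinshuibao-capsule-like), `tablet_B`
#'   (Jinshuibao-tablet-like) and `capsule_C` (Bailing-capsule-like).
#' @export
default_class_profiles <- function(content_cv = 0.08, analyte_cv = 0.015) {
  analytes <- default_peak_specs()$analyte
  mk <- function(x) stats::setNames(x, analytes)
  list(
    capsule_A = class_profile(
      "capsule_A",
      mk(c(0.50, 0.45, 0.40, 0.165, 0.35, 0.30, 2.48, 0.30, 2.40, 2.70)),
      content_cv, analyte_cv),
    tablet_B = class_profile(
      "tablet_B",
      mk(c(0.45, 0.08, 0.35, 0.120, 0.30, 0.25, 1.75, 0.22, 1.55, 1.80)),
      content_cv, analyte_cv),
    capsule_C = class_profile(
      "capsule_C",
      mk(c(0.40, 0.40, 0.00, 0.105, 0.00, 0.00, 1.10, 0.075, 2.00, 2.14)),
      content_cv, analyte_cv, missing_peaks = c(3L, 5L, 6L))
  )
}

#' Simulation configuration
#'
#' Bundles everything that determines a synthetic study: the common-peak
#' layout, the per-class content profiles, the sample design, the time
#' grid, and the noise/drift/jitter model. A configuration plus its seed
#' fully determines the generated data.
#'
#' @param peak_specs Data frame as returned by [default_peak_specs()].
#' @param class_profiles Named list of [class_profile()] objects.
#' @param samples_per_class Samples generated per class.
#' @param t_start,t_end Acquisition window, minutes.
#' @param dt Sampling interval, minutes.
#' @param noise_sd Gaussian detector noise standard deviation (detector
#'   units).
#' @param baseline_amp Baseline drift amplitude (detector units); drift is
#'   a gentle linear ramp plus one slow sine cycle.
#' @param baseline_cycles Number of sine cycles across the window.
#' @param rt_warp_sd Standard deviation of the per-sample multiplicative
#'   retention-time warp (fraction; run-to-run shift shared by all peaks).
#' @param rt_jitter_sd Standard deviation of the additional per-peak
#'   retention-time jitter, minutes.
#' @param extract_volume Extraction volume, mL (content to solution
#'   conversion).
#' @param sample_mass Extracted sample mass, g.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(peak_specs = default_peak_specs(),
                       class_profiles = default_class_profiles(),
                       samples_per_class = 10L,
                       t_start = 0, t_end = 30, dt = 0.005,
                       noise_sd = 0.5,
                       baseline_amp = 2, baseline_cycles = 1,
                       rt_warp_sd = 0.004, rt_jitter_sd = 0.008,
                       extract_volume = 50, sample_mass = 1.00,
                       seed = 1L) {
  if (dt <= 0) stop("sampling interval must be positive")
  if (t_end <= t_start) stop("time window must have positive length")
  validate_peak_specs(peak_specs)
  if (length(class_profiles) == 0L) stop("class_profiles must be non-empty")
  if (max(peak_specs$rt) >= t_end || min(peak_specs$rt) <= t_start)
    stop("time window must cover all retention times")
  if (samples_per_class < 1L) stop("samples_per_class must be >= 1")
  structure(
    list(peak_specs = peak_specs, class_profiles = class_profiles,
         samples_per_class = as.integer(samples_per_class),
         t_start = t_start, t_end = t_end, dt = dt,
         noise_sd = noise_sd, baseline_amp = baseline_amp,
         baseline_cycles = baseline_cycles,
         rt_warp_sd = rt_warp_sd, rt_jitter_sd = rt_jitter_sd,
         extract_volume = extract_volume, sample_mass = sample_mass,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Only scalar fields may be overridden in the file; peak specs and class
#' profiles beyond the defaults must be constructed in code.
#'
#' @param path Path to a YAML file whose keys match [sim_config()]
#'   arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(sim_config)),
                     c("peak_specs", "class_profiles"))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown or non-scalar config fields: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

time_grid <- function(config) {
  seq(config$t_start, config$t_end, by = config$dt)
}

# Content (mg/g) -> solution concentration (ug/mL) under the standard
# preparation: `sample_mass` g extracted into `extract_volume` mL.
content_to_conc <- function(content, extract_volume = 50, sample_mass = 1) {
  content * sample_mass * 1000 / extract_volume
}

conc_to_content <- function(conc, extract_volume = 50, sample_mass = 1) {
  conc * extract_volume / 1000 / sample_mass
}

gaussian_profile <- function(t, rt, sigma, area) {
  height <- area / (sigma * sqrt(2 * pi))
  height * exp(-(t - rt)^2 / (2 * sigma^2))
}

baseline_profile <- function(t, config) {
  if (config$baseline_amp == 0) return(rep(0, length(t)))
  span <- config$t_end - config$t_start
  u <- (t - config$t_start) / span
  config$baseline_amp * (u + 0.5 * sin(2 * pi * config$baseline_cycles * u))
}

#' Simulate a single chromatogram
#'
#' Builds a trace as a sum of Gaussian peaks plus baseline drift and white
#' detector noise. Each peak's true area is `amount x response_factor`, so
#' the Gaussian height is `area / (sigma * sqrt(2*pi))`.
#'
#' @param peaks Data frame of peak specs (see [default_peak_specs()]) with
#'   an additional `amount` column in ug/mL, or the spec data frame plus an
#'   `amounts` vector.
#' @param amounts Optional numeric vector of solution concentrations
#'   (ug/mL), one per row of `peaks`.
#' @param config A [sim_config()] controlling grid, noise, drift and
#'   jitter.
#' @param seed Integer seed for this trace.
#' @param sample_id Sample identifier stored on the chromatogram.
#' @param metadata Named list of acquisition metadata.
#' @param warp Per-sample multiplicative retention-time warp factor; if
#'   `NULL`, drawn from `Normal(1, rt_warp_sd)`.
#' @return A [chromatogram()] with attribute `true_peaks`: a data frame of
#'   true areas and jittered retention times.
#' @export
simulate_chromatogram <- function(peaks, amounts = NULL, config = sim_config(),
                                  seed = config$seed, sample_id = "sample",
                                  metadata = list(), warp = NULL) {
  if (!is.null(amounts)) peaks$amount <- amounts
  stopifnot(!is.null(peaks$amount))
  if (any(peaks$amount < 0)) stop("amounts must be non-negative")
  set.seed(seed)
  t <- time_grid(config)
  if (is.null(warp)) warp <- stats::rnorm(1, 1, config$rt_warp_sd)
  rt_true <- peaks$rt * warp +
    stats::rnorm(nrow(peaks), 0, config$rt_jitter_sd)
  area_true <- peaks$amount * peaks$response_factor
  y <- baseline_profile(t, config)
  for (k in seq_len(nrow(peaks))) {
    if (area_true[k] > 0)
      y <- y + gaussian_profile(t, rt_true[k], peaks$width_sigma[k],
                                area_true[k])
  }
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(length(t), 0, config$noise_sd)
  chrom <- chromatogram(t, y, sample_id = sample_id, metadata = metadata)
  attr(chrom, "true_peaks") <- data.frame(
    common_index = peaks$common_index %||% seq_len(nrow(peaks)),
    analyte = peaks$analyte,
    rt_nominal = peaks$rt, rt_true = rt_true,
    amount = peaks$amount, area_true = area_true,
    stringsAsFactors = FALSE)
  chrom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a calibration series of standard-mixture chromatograms
#'
#' Each level's true peak area follows the analyte's calibration line
#' `area = slope x concentration + intercept`; the standards are simulated
#' traces carrying those areas (plus detector noise), and the returned
#' truth table records the exact values.
#'
#' @param curve A list or one-row data frame with `analyte`, `slope`,
#'   `intercept` (and optionally `rt`, `width_sigma`; defaults come from
#'   [default_peak_specs()]).
#' @param levels Concentrations, ug/mL (at least two, non-negative).
#' @param noise_sd Detector noise for the standard traces.
#' @param seed Integer seed.
#' @param config A [sim_config()]; its grid and drift settings are reused,
#'   `noise_sd` is overridden by the argument.
#' @return A list with `standards` (list of chromatograms, one per level)
#'   and `truth` (data frame: level, concentration, true_area).
#' @export
generate_calibration_series <- function(curve, levels, noise_sd = 0,
                                        seed = 1L, config = sim_config()) {
  if (length(levels) < 2L) stop("need at least two calibration levels")
  if (any(levels < 0)) stop("concentrations must be non-negative")
  curve <- as.list(curve)
  specs <- default_peak_specs()
  row <- specs[specs$analyte == curve$analyte, ]
  rt <- curve$rt %||% (if (nrow(row)) row$rt else 10)
  sigma <- curve$width_sigma %||% (if (nrow(row)) row$width_sigma else 0.1)
  true_area <- curve$slope * levels + curve$intercept
  if (any(true_area < 0))
    stop("calibration line gives negative area at the lowest level(s)")
  cfg <- config
  cfg$noise_sd <- noise_sd
  cfg$rt_warp_sd <- 0
  cfg$rt_jitter_sd <- 0
  standards <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    pk <- data.frame(common_index = 1L, analyte = curve$analyte, rt = rt,
                     width_sigma = sigma, response_factor = 1,
                     amount = true_area[i], stringsAsFactors = FALSE)
    standards[[i]] <- simulate_chromatogram(
      pk, config = cfg, seed = seed + i,
      sample_id = sprintf("std_%s_L%d", curve$analyte, i),
      metadata = list(role = "standard", analyte = curve$analyte,
                      level = i))
  }
  list(standards = standards,
       truth = data.frame(level = seq_along(levels), concentration = levels,
                          true_area = true_area))
}

#' Generate a full synthetic study
#'
#' Produces `samples_per_class` chromatograms for each configured product
#' class together with the complete ground truth. Per-sample contents are
#' the class means scaled by a shared lognormal potency factor
#' (`content_cv`) and small per-analyte lognormal noise (`analyte_cv`);
#' peaks listed in a class's `missing_peaks` are suppressed to zero.
#'
#' @param config A [sim_config()].
#' @return A list with `samples` (list of chromatograms, each carrying
#'   class metadata), `metadata` (data frame: sample_id, class, instrument,
#'   column, flow_rate, temperature, injection_volume) and `truth` (data
#'   frame per sample x peak: true content mg/g, solution concentration
#'   ug/mL, true area, true retention time).
#' @export
generate_study <- function(config = sim_config()) {
  if (length(config$class_profiles) == 0L)
    stop("class_profiles must be non-empty")
  specs <- config$peak_specs
  samples <- list()
  truth <- list()
  meta <- list()
  idx <- 0L
  for (profile in config$class_profiles) {
    for (j in seq_len(config$samples_per_class)) {
      idx <- idx + 1L
      sample_seed <- config$seed + 1000L * idx
      set.seed(sample_seed)
      shared <- exp(stats::rnorm(1, 0, sqrt(log(1 + profile$content_cv^2))) -
                      log(1 + profile$content_cv^2) / 2)
      per_analyte <- exp(stats::rnorm(
        nrow(specs), 0, sqrt(log(1 + profile$analyte_cv^2))) -
          log(1 + profile$analyte_cv^2) / 2)
      contents <- profile$mean_contents * shared * per_analyte
      contents[profile$missing_peaks] <- 0
      conc <- content_to_conc(contents, config$extract_volume,
                              config$sample_mass)
      sid <- sprintf("%s_%02d", profile$class_name, j)
      md <- list(class = profile$class_name, batch = j,
                 instrument = "Agilent 1260", column = "Agilent",
                 flow_rate = 1.0, temperature = 30, injection_volume = 10)
      chrom <- simulate_chromatogram(specs, amounts = conc, config = config,
                                     seed = sample_seed + 1L,
                                     sample_id = sid, metadata = md)
      tp <- attr(chrom, "true_peaks")
      truth[[idx]] <- data.frame(
        sample_id = sid, class = profile$class_name,
        common_index = specs$common_index, analyte = specs$analyte,
        content = unname(contents), concentration = unname(conc),
        area_true = tp$area_true, rt_true = tp$rt_true,
        stringsAsFactors = FALSE)
      meta[[idx]] <- data.frame(
        sample_id = sid, class = profile$class_name, batch = j,
        instrument = md$instrument, column = md$column,
        flow_rate = md$flow_rate, temperature = md$temperature,
        injection_volume = md$injection_volume, stringsAsFactors = FALSE)
      samples[[idx]] <- chrom
    }
  }
  names(samples) <- vapply(samples, function(s) attr(s, "sample_id"), "")
  list(samples = samples,
       metadata = do.call(rbind, meta),
       truth = do.call(rbind, truth))
}
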