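test_that("chromatogram files round-trip exactly", {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  writeLines(c("time_min,intensity", "0.1,5", "0.2,7.25", "0.3,6"), path)
  ch <- read_chromatogram(path)
  expect_s3_class(ch, "chromatogram")
  expect_equal(nrow(ch), 3L)
  expect_equal(ch$intensity, c(5, 7.25, 6))

  cfg <- sim_config(seed = 3L)
  pk <- default_peak_specs()
  sim <- simulate_chromatogram(pk, amounts = rep(20, 10), config = cfg,
                               seed = 3L)
  write_chromatogram(sim, path)
  back <- read_chromatogram(path)
  expect_identical(back$time, sim$time)
  expect_identical(back$intensity, sim$intensity)
})

test_that("malformed chromatogram files are rejected with diagnostics", {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  writeLines(c("0.3 5", "0.2 6"), path)
  expect_error(read_chromatogram(path), "strictly increasing")
  writeLines(c("time intensity", "0.1 5", "0.2 abc"), path)
  expect_error(read_chromatogram(path), "line 3")
  expect_error(chromatogram(c(1, 2), c(1, NA)), "finite")
  expect_error(chromatogram(c(1, 2, 2), c(1, 2, 3)), "strictly increasing")
})

test_that("noise estimation is robust and honours its preconditions", {
  t <- seq(0, 30, by = 0.005)
  flat <- chromatogram(t, rep(4, length(t)))
  expect_equal(estimate_noise(flat, c(5, 10)), 0)

  set.seed(11)
  noisy <- chromatogram(seq_len(2000) * 0.01, rnorm(2000, 0, 0.5))
  est <- estimate_noise(noisy, c(0.01, 20))
  expect_lt(abs(est - 0.5) / 0.5, 0.10)

  expect_error(estimate_noise(flat, c(29, 35)), "outside")
  expect_error(estimate_noise(flat, c(5, 10), peak_times = 9.5),
               "overlaps")
  expect_error(estimate_noise(flat, c(5, 5.05)), "20 points")
})

test_that("peak detection finds exactly the configured standards", {
  cfg <- sim_config(seed = 21L, rt_warp_sd = 0, rt_jitter_sd = 0)
  conc <- standard_mixture_conc()
  specs <- default_peak_specs()
  specs <- specs[specs$analyte %in% names(conc), ]
  ch <- simulate_chromatogram(specs, amounts = unname(conc[specs$analyte]),
                              config = cfg, seed = 21L)
  noise <- estimate_noise(ch, default_noise_window())
  pk <- detect_peaks(ch, noise = noise)
  expect_equal(nrow(pk), 5L)
  expect_true(all(abs(pk$apex_time - specs$rt) <= 0.02))

  # without detector noise the apexes land on the grid points
  quiet <- simulate_chromatogram(specs, amounts = unname(conc[specs$analyte]),
                                 config = quiet_config(), seed = 21L)
  pkq <- detect_peaks(quiet, noise = 0)
  expect_equal(nrow(pkq), 5L)
  expect_true(all(abs(pkq$apex_time - specs$rt) <= cfg$dt))

  flat <- chromatogram(ch$time, rep(0, nrow(ch)))
  expect_equal(nrow(detect_peaks(flat, noise = 1)), 0L)
  expect_error(detect_peaks(chromatogram(1, 1)[0, ], noise = 1), "empty")
})

test_that("peaks below the SNR threshold are not reported", {
  cfg <- quiet_config()
  noise <- 2; min_snr <- 10
  height <- 0.5 * min_snr * noise
  area <- height * 0.1 * sqrt(2 * pi)
  pk <- data.frame(common_index = 1L, analyte = "x", rt = 15,
                   width_sigma = 0.1, response_factor = 1)
  ch <- simulate_chromatogram(pk, amounts = area, config = cfg, seed = 1L)
  expect_equal(nrow(detect_peaks(ch, noise = noise, min_snr = min_snr)), 0L)
  # the same peak at 2x the threshold is found
  ch2 <- simulate_chromatogram(pk, amounts = 4 * area, config = cfg, seed = 1L)
  expect_equal(nrow(detect_peaks(ch2, noise = noise, min_snr = min_snr)), 1L)
})

test_that("chord-baseline integration matches the closed-form Gaussian area", {
  cfg <- quiet_config()
  area_true <- 100 * 0.05 * sqrt(2 * pi)
  pk <- data.frame(common_index = 1L, analyte = "x", rt = 10,
                   width_sigma = 0.05, response_factor = 1)
  ch <- simulate_chromatogram(pk, amounts = area_true, config = cfg, seed = 1L)
  peak <- list(left_bound = 9, right_bound = 11)
  expect_equal(integrate_peak(ch, peak), 12.533, tolerance = 5e-3)
  # constant baseline offset is removed by the chord
  ch50 <- chromatogram(ch$time, ch$intensity + 50)
  expect_equal(integrate_peak(ch50, peak), 12.533, tolerance = 5e-3)
  # degenerate bounds
  expect_equal(integrate_peak(ch, list(left_bound = 10, right_bound = 10)), 0)
  expect_error(integrate_peak(ch, list(left_bound = 11, right_bound = 9)),
               "reversed")
  expect_error(integrate_peak(ch, list(left_bound = -1, right_bound = 9)),
               "outside")
})

test_that("common-peak matching assigns all ten peaks with unit reference ratios", {
  cfg <- quiet_config()
  specs <- default_peak_specs()
  ch <- simulate_chromatogram(specs, amounts = rep(20, 10), config = cfg,
                              seed = 1L)
  pk <- detect_peaks(ch, noise = 0)
  m <- match_common_peaks(list(s = pk))
  expect_equal(sort(m$common_index), 1:10)
  ref <- m[m$analyte == "adenosine", ]
  expect_equal(ref$rrt, 1)
  expect_equal(ref$rpa, 1)
  expect_true(all(m$rrt[order(m$common_index)] ==
                    sort(m$rrt[order(m$common_index)])))
})

test_that("suppressed and out-of-tolerance peaks stay unmatched", {
  cfg <- quiet_config()
  specs <- default_peak_specs()
  amounts <- rep(20, 10); amounts[3] <- 0   # capsule_C-style suppression
  ch <- simulate_chromatogram(specs, amounts = amounts, config = cfg, seed = 1L)
  pk <- detect_peaks(ch, noise = 0)
  m <- match_common_peaks(list(s = pk))
  expect_equal(sort(m$common_index), setdiff(1:10, 3L))

  # spurious peaks far from any expected time are dropped
  spurious <- data.frame(apex_time = c(9.9, 16.9), height = c(5, 5),
                         area = c(1, 1), left_bound = c(9.8, 16.8),
                         right_bound = c(10, 17))
  m2 <- match_common_peaks(list(s = rbind(pk, spurious)))
  expect_equal(sort(m2$common_index), setdiff(1:10, 3L))
})

test_that("a sample without the reference peak is flagged", {
  cfg <- quiet_config()
  specs <- default_peak_specs()
  amounts <- rep(20, 10); amounts[10] <- 0  # no adenosine
  ch <- simulate_chromatogram(specs, amounts = amounts, config = cfg, seed = 1L)
  pk <- detect_peaks(ch, noise = 0)
  expect_warning(m <- match_common_peaks(list(bad = pk)), "reference peak")
  expect_identical(attr(m, "flagged"), "bad")
  expect_true(all(is.na(m$rrt)))
})

test_that("matching is invariant to sample order", {
  pl <- cached_pipeline()
  pk <- pl$peaks
  m1 <- match_common_peaks(pk)
  m2 <- match_common_peaks(rev(pk))
  key <- function(m) m[order(m$sample_id, m$common_index),
                       c("sample_id", "common_index", "area")]
  a <- key(m1); b <- key(m2)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("integrated areas recover truth within 2% at high SNR", {
  pl <- cached_pipeline()
  st <- pl$study
  m <- pl$matched
  tr <- st$truth
  idx <- match(paste(m$sample_id, m$common_index),
               paste(tr$sample_id, tr$common_index))
  truth_area <- tr$area_true[idx]
  # all simulated common peaks sit far above SNR 50 at the default noise
  rel_err <- abs(m$area / truth_area - 1)
  expect_gt(nrow(m), 100L)
  expect_lt(max(rel_err), 0.02)
})

test_that("area never decreases with amount (noiseless)", {
  cfg <- quiet_config()
  pk <- default_peak_specs()[9, ]
  amounts <- c(1, 2, 5, 10, 20, 50)
  areas <- vapply(amounts, function(a) {
    ch <- simulate_chromatogram(pk, amounts = a, config = cfg, seed = 1L)
    p <- detect_peaks(ch, noise = 0)
    p$area[which.max(p$height)]
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})
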