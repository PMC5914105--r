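test_that("zero-amount peak with no noise or drift gives a flat zero trace", {
  cfg <- quiet_config()
  pk <- default_peak_specs()[4, ]
  ch <- simulate_chromatogram(pk, amounts = 0, config = cfg, seed = 1L)
  expect_true(all(ch$intensity == 0))
})

test_that("simulated Gaussian peak has the closed-form area", {
  cfg <- quiet_config()
  # height 100, sigma 0.05 -> area = 100 * 0.05 * sqrt(2*pi)
  area <- 100 * 0.05 * sqrt(2 * pi)
  pk <- data.frame(common_index = 1L, analyte = "x", rt = 10,
                   width_sigma = 0.05, response_factor = 1)
  ch <- simulate_chromatogram(pk, amounts = area, config = cfg, seed = 1L)
  expect_equal(max(ch$intensity), 100, tolerance = 1e-4)
  expect_equal(trapz(ch$time, ch$intensity), 12.533, tolerance = 1e-3)
})

test_that("traces are deterministic given the seed", {
  cfg <- sim_config(seed = 5L)
  pk <- default_peak_specs()
  a <- simulate_chromatogram(pk, amounts = rep(10, 10), config = cfg, seed = 9L)
  b <- simulate_chromatogram(pk, amounts = rep(10, 10), config = cfg, seed = 9L)
  c <- simulate_chromatogram(pk, amounts = rep(10, 10), config = cfg, seed = 10L)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("calibration series carries the line's true areas", {
  curve <- list(analyte = "uracil", slope = 41.219, intercept = 5.2065)
  ser <- generate_calibration_series(curve, levels = c(33.8, 10, 1),
                                     noise_sd = 0, seed = 1L,
                                     config = quiet_config())
  expect_equal(ser$truth$true_area[1], 1398.409, tolerance = 1e-6)
  expect_equal(ser$truth$true_area[2], 417.3965, tolerance = 1e-6)
  # trace integral matches the intended true area
  got <- trapz(ser$standards[[1]]$time, ser$standards[[1]]$intensity)
  expect_equal(got, 1398.409, tolerance = 1e-3)
  # zero level with zero intercept gives zero area
  ser0 <- generate_calibration_series(list(analyte = "uracil", slope = 2,
                                           intercept = 0),
                                      levels = c(0, 1), noise_sd = 0)
  expect_equal(ser0$truth$true_area[1], 0)
  expect_error(generate_calibration_series(curve, levels = c(-1, 2)),
               "non-negative")
  expect_error(generate_calibration_series(curve, levels = 5), "two")
})

test_that("noiseless series refits its generating line exactly", {
  curve <- list(analyte = "uracil", slope = 41.219, intercept = 5.2065)
  levels <- 33.8 / 2^(0:5)
  ser <- generate_calibration_series(curve, levels, noise_sd = 0, seed = 1L,
                                     config = quiet_config())
  areas <- vapply(ser$standards, function(ch) {
    pk <- detect_peaks(ch, noise = 0)
    pk$area[which.max(pk$area)]
  }, numeric(1))
  fit <- fit_calibration(levels, areas, "uracil")
  expect_equal(fit$slope, 41.219, tolerance = 5e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  # refit from the true areas themselves is exact to 6 significant figures
  fit2 <- fit_calibration(levels, ser$truth$true_area, "uracil")
  expect_equal(fit2$slope, 41.219, tolerance = 1e-7)
  expect_equal(fit2$intercept, 5.2065, tolerance = 1e-7)
})

test_that("study has the 3 x 10 design with class-specific structure", {
  st <- cached_study()
  expect_length(st$samples, 30L)
  expect_equal(as.integer(table(st$metadata$class)), rep(10L, 3))
  # Bailing-like samples have their missing peaks at zero content
  cc <- st$truth[st$truth$class == "capsule_C", ]
  expect_true(all(cc$content[cc$common_index %in% c(3, 5, 6)] == 0))
  expect_true(all(cc$content[!cc$common_index %in% c(3, 5, 6)] > 0))
})

test_that("capsule_C truth preserves the nucleoside content ordering per sample", {
  st <- cached_study()
  cc <- st$truth[st$truth$class == "capsule_C", ]
  for (sid in unique(cc$sample_id)) {
    s <- cc[cc$sample_id == sid, ]
    g <- function(a) s$content[s$analyte == a]
    expect_true(g("adenosine") > g("guanosine"))
    expect_true(g("guanosine") > g("uridine"))
    expect_true(g("uridine") > g("uracil"))
    expect_true(g("uracil") > g("adenine"))
  }
})

test_that("zero content CV collapses within-class variation", {
  cfg <- sim_config(samples_per_class = 3L, seed = 2L,
                    class_profiles = default_class_profiles(
                      content_cv = 0, analyte_cv = 0))
  st <- generate_study(cfg)
  a <- st$truth[st$truth$class == "capsule_A", ]
  per_sample <- split(a$content, a$sample_id)
  for (v in per_sample[-1]) expect_equal(v, per_sample[[1]])
})

test_that("study generation is deterministic and seed-sensitive", {
  cfg <- sim_config(samples_per_class = 2L, seed = 7L)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(serialize(s1$truth, NULL), serialize(s2$truth, NULL))
  expect_identical(s1$samples[[1]]$intensity, s2$samples[[1]]$intensity)
  cfg2 <- sim_config(samples_per_class = 2L, seed = 8L)
  expect_false(identical(generate_study(cfg2)$truth$content,
                         s1$truth$content))
})

test_that("integrated area is proportional to amount when noiseless", {
  cfg <- quiet_config()
  pk <- default_peak_specs()[7, ]
  amounts <- c(0.5, 1, 5, 20, 80)
  areas <- vapply(amounts, function(a) {
    ch <- simulate_chromatogram(pk, amounts = a, config = cfg, seed = 1L)
    trapz(ch$time, ch$intensity)
  }, numeric(1))
  ratio <- areas / (amounts * pk$response_factor)
  expect_true(all(abs(ratio - 1) < 1e-3))
  # proportionality between any two levels to within 0.1%
  expect_true(all(abs(ratio / ratio[1] - 1) < 1e-3))
})

test_that("true content vectors separate classes in cosine distance", {
  st <- cached_study()
  tv <- split(st$truth$content, st$truth$sample_id)
  cls <- st$metadata$class[match(names(tv), st$metadata$sample_id)]
  n <- length(tv)
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- 1 - cos_vec(tv[[i]], tv[[j]])
    if (cls[i] == cls[j]) within <- c(within, d) else between <- c(between, d)
  }
  expect_gt(min(between), max(within))
})

test_that("configuration validation rejects degenerate inputs", {
  expect_error(sim_config(dt = 0), "positive")
  expect_error(sim_config(t_end = 20), "cover")
  expect_error(sim_config(samples_per_class = 0), ">= 1")
  expect_error(generate_study(sim_config(class_profiles = list())),
               "non-empty")
  expect_error(class_profile("x", c(-1, 2)), "mean_contents")
})

test_that("sim config round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(list(noise_sd = 0.25, samples_per_class = 4L,
                        seed = 99L), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$noise_sd, 0.25)
  expect_equal(cfg$samples_per_class, 4L)
  expect_equal(cfg$seed, 99L)
  yaml::write_yaml(list(bogus_field = 1), path)
  expect_error(read_sim_config(path), "unknown")
})
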