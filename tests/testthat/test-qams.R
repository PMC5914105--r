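test_that("relative correction factors follow their defining ratio", {
  expect_equal(compute_rcf(5, 5, 7, 7), 1)
  expect_equal(compute_rcf(2, 4, 2, 8), 2)
  expect_error(compute_rcf(0, 1, 1, 1), "positive")
  expect_error(compute_rcf(1, 1, -2, 1), "positive")
})

test_that("correction factors are reciprocal between analyte and standard", {
  set.seed(4)
  for (i in 1:20) {
    c_i <- runif(1, 1, 100); c_s <- runif(1, 1, 100)
    a_i <- runif(1, 10, 5000); a_s <- runif(1, 10, 5000)
    expect_equal(compute_rcf(c_i, c_s, a_i, a_s) *
                   compute_rcf(c_s, c_i, a_s, a_i), 1)
  }
})

test_that("robustness summaries reproduce the bundled injection-volume table", {
  tab <- ref_table("table4")
  entries <- rcf_entries(tab)
  sm <- rcf_robustness(entries)
  expect_equal(round(sm$mean, 3), c(0.711, 1.245, 0.478, 1.389))
  expect_equal(sm$n, rep(7L, 4))
  # printed RSDs agree at the printed precision
  expect_true(all(abs(sm$rsd_percent - c(0.83, 1.05, 1.09, 1.15)) <= 0.01))
})

test_that("mean correction factors match the other bundled condition tables", {
  m5 <- rcf_robustness(rcf_entries(ref_table("table5")))
  expect_equal(round(m5$mean[m5$analyte == "uracil"], 3), 0.686)
  m6 <- rcf_robustness(rcf_entries(ref_table("table6")))
  expect_equal(round(m6$mean[m6$analyte == "guanosine"], 3), 1.304)
  m7 <- rcf_robustness(rcf_entries(ref_table("table7")))
  expect_equal(round(m7$mean[m7$analyte == "adenine"], 3), 0.446)
  expect_equal(round(m7$mean[m7$analyte == "guanosine"], 3), 1.302)
  # identical entries have zero spread
  same <- data.frame(analyte = "x", condition = 1:3, f = rep(1.25, 3))
  expect_equal(rcf_robustness(same)$rsd_percent, 0)
  one <- data.frame(analyte = "x", condition = 1, f = 1)
  expect_warning(expect_null(rcf_robustness(one)), "fewer than two")
})

test_that("single-marker quantification matches its algebra", {
  expect_equal(qams_quantify(100, 100, 10, 1) * 1000 / 50, 10)
  expect_equal(qams_quantify(50, 100, 10, 2) * 1000 / 50, 10)
  expect_error(qams_quantify(1, 0, 1, 1), "internal standard")
  expect_error(qams_quantify(1, 1, 1, -1), "positive")
})

test_that("QAMS equals ESM exactly when f comes from the same standards", {
  # proportional detector response: area = r * conc
  r <- c(uracil = 41.219, adenosine = 28.112)
  conc_std <- c(uracil = 33.8, adenosine = 93.6)
  area_std <- r * conc_std
  f <- unname(compute_rcf(conc_std["uracil"], conc_std["adenosine"],
                          area_std["uracil"], area_std["adenosine"]))
  curve_s <- list(analyte = "adenosine", slope = r[["adenosine"]],
                  intercept = 0)
  curve_i <- list(analyte = "uracil", slope = r[["uracil"]], intercept = 0)
  set.seed(8)
  for (i in 1:25) {
    conc <- runif(2, 0.5, 60)     # sample concentrations (uracil, adenosine)
    a_i <- r[["uracil"]] * conc[1]
    a_s <- r[["adenosine"]] * conc[2]
    c_s <- (a_s - curve_s$intercept) / curve_s$slope
    qams <- qams_quantify(a_i, a_s, c_s, f)
    esm <- esm_quantify(a_i, curve_i)
    expect_equal(qams, esm, tolerance = 1e-14)
  }
})

test_that("correction factors measured from simulated standards recover truth", {
  cfg <- sim_config(seed = 31L)
  rf <- default_peak_specs()
  true_f <- function(an) {
    rs <- rf$response_factor[rf$analyte == "adenosine"]
    ri <- rf$response_factor[rf$analyte == an]
    rs / ri
  }
  vols <- c(2, 4, 6, 8, 10, 12, 15)
  entries <- do.call(rbind, lapply(seq_along(vols), function(i)
    measure_rcf(config = cfg, seed = 31L + i, injection_volume = vols[i],
                condition = as.character(vols[i]))))
  sm <- rcf_robustness(entries)
  for (an in sm$analyte)
    expect_lt(abs(sm$mean[sm$analyte == an] / true_f(an) - 1), 0.02)
  # volume independence keeps the spread tight at the default noise
  expect_true(all(sm$rsd_percent <= 2))
})

test_that("QAMS and ESM contents agree on the bundled 30-sample comparison", {
  t8 <- ref_table("table8")
  for (an in c("uracil", "adenine", "guanosine")) {
    ag <- method_agreement(t8[[paste0(an, "_qams")]],
                           t8[[paste0(an, "_esm")]])
    expect_gte(ag$cosine, 0.999)
  }
  # a fixed correction factor makes the per-sample QAMS/ESM ratio nearly
  # constant; the printed columns bear this out to about 1%
  ratio <- t8$uracil_qams / t8$uracil_esm
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.02)
})

test_that("agreement handles identities and degenerate input", {
  v <- c(1, 2, 3)
  ag <- method_agreement(v, v)
  expect_equal(ag$cosine, 1)
  expect_equal(ag$correlation, 1)
  expect_error(method_agreement(1:3, 1:4), "equal length")
  expect_error(method_agreement(c(1, 2), c(0, 0)), "zero norm")
  expect_warning(ag0 <- method_agreement(c(0, 0), c(1, 2)), "zero-norm")
  expect_true(is.na(ag0$cosine))
})
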