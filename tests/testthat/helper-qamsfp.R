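# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# default synthetic study + detected/matched peaks, cached
cached_pipeline <- function() {
  if (is.null(.fixtures$pipeline))
    .fixtures$pipeline <- run_pipeline(sim_config(seed = 101L))
  .fixtures$pipeline
}

cached_study <- function() cached_pipeline()$study

# trapezoidal integral over a full trace (independent of integrate_peak)
trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

# quiet config: no noise, no drift, no jitter
quiet_config <- function(...) {
  sim_config(noise_sd = 0, baseline_amp = 0, rt_warp_sd = 0,
             rt_jitter_sd = 0, ...)
}

# cosine of two vectors (independent of the package's similarity())
cos_vec <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
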