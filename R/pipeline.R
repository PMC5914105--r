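#' Default peak-free window used for noise estimation
#'
#' Under the default peak layout the interval between the 6.8 min and
#' 13.5 min common peaks is free of configured peaks.
#' @return Numeric length-2 vector, minutes.
#' @export
default_noise_window <- function() c(8.5, 12.0)

#' Simulate a standard-mixture chromatogram and measure correction factors
#'
#' Simulates one injection of the five-nucleoside standard mixture (areas
#' scaled jointly by the injection volume relative to the 10 uL reference,
#' and by an optional per-condition response perturbation), detects and
#' matches the peaks, and computes each analyte's relative correction
#' factor against the internal standard.
#'
#' @param conc Named concentrations of the standards, ug/mL.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param injection_volume Injection volume, uL.
#' @param response_scale Multiplicative detector-response perturbation for
#'   this condition (instrument/column/flow/temperature effects).
#' @param internal_standard Analyte used as the single marker.
#' @param condition Label stored on the result.
#' @return Data frame of `RCFEntry` rows: analyte, condition, f.
#' @export
measure_rcf <- function(conc = standard_mixture_conc(),
                        config = sim_config(), seed = 1L,
                        injection_volume = 10, response_scale = 1,
                        internal_standard = "adenosine",
                        condition = as.character(injection_volume)) {
  specs <- config$peak_specs
  specs <- specs[specs$analyte %in% names(conc), , drop = FALSE]
  amounts <- conc[specs$analyte] * (injection_volume / 10) * response_scale
  chrom <- simulate_chromatogram(specs, amounts = unname(amounts),
                                 config = config, seed = seed,
                                 sample_id = paste0("std_", condition),
                                 metadata = list(role = "standard"))
  noise <- estimate_noise(chrom, default_noise_window())
  pk <- detect_peaks(chrom, noise = max(noise, 1e-9))
  matched <- match_common_peaks(list(std = pk),
                                reference_times = config$peak_specs$rt,
                                reference_analytes = config$peak_specs$analyte)
  matched <- matched[matched$analyte %in% names(conc), , drop = FALSE]
  s_row <- matched[matched$analyte == internal_standard, , drop = FALSE]
  if (!nrow(s_row)) stop("internal standard peak not found in the standard run")
  others <- setdiff(matched$analyte, internal_standard)
  f <- vapply(others, function(a) {
    r <- matched[matched$analyte == a, , drop = FALSE]
    compute_rcf(conc[[a]], conc[[internal_standard]], r$area, s_row$area)
  }, numeric(1))
  data.frame(analyte = others, condition = condition, f = unname(f),
             stringsAsFactors = FALSE)
}

#' Standard-mixture working concentrations
#'
#' The mixed working solution of the five nucleoside standards, ug/mL.
#' @return Named numeric vector.
#' @export
standard_mixture_conc <- function() {
  c(uracil = 33.8, uridine = 93.6, adenine = 30.1, guanosine = 120.8,
    adenosine = 93.6)
}

#' Run the complete analysis pipeline on a synthetic study
#'
#' Orchestrates simulate -> peak detection/matching -> calibration ->
#' fingerprint similarity -> clustering -> QAMS vs ESM quantification,
#' and (optionally) writes every result table plus a run manifest to
#' `out_dir`. The config seed fully determines the bundle.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param stages Character vector of stages to run after simulation; any
#'   of `"peaks"`, `"calibrate"`, `"fingerprint"`, `"cluster"`, `"qams"`.
#'   Later stages require the earlier ones.
#' @param injection_volumes Injection volumes (uL) for the correction
#'   factor robustness series.
#' @param min_snr Peak detection threshold.
#' @param qams_enabled With `FALSE` the quantification stage emits
#'   external-standard contents only (no correction factors, no agreement
#'   report).
#' @return A list with elements study, peaks, matched, curves, similarity,
#'   tree, groups, rcf, rcf_summary, contents, agreement, manifest
#'   (elements for disabled stages are `NULL`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         stages = c("peaks", "calibrate", "fingerprint",
                                    "cluster", "qams"),
                         injection_volumes = c(2, 4, 6, 8, 10, 12, 15),
                         min_snr = 10, qams_enabled = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list(manifest = list(
    package_version = as.character(utils::packageVersion("qamsfp")),
    seed = config$seed, samples_per_class = config$samples_per_class,
    noise_sd = config$noise_sd, stages = stages,
    extract_volume = config$extract_volume,
    sample_mass = config$sample_mass))

  res$study <- generate_study(config)
  samples <- res$study$samples
  specs <- config$peak_specs

  if ("peaks" %in% stages) {
    res$peaks <- lapply(samples, function(ch) {
      noise <- estimate_noise(ch, default_noise_window())
      detect_peaks(ch, noise = max(noise, 1e-9), min_snr = min_snr)
    })
    res$matched <- match_common_peaks(res$peaks,
                                      reference_times = specs$rt,
                                      reference_analytes = specs$analyte)
  }

  if ("calibrate" %in% stages) {
    ref2 <- ref_table("table2")
    res$curves <- list()
    for (i in seq_len(nrow(ref2))) {
      an <- ref2$analyte[i]
      top <- ref2$range_high[i]
      levels <- top / 2^(0:5)
      rf <- specs$response_factor[specs$analyte == an]
      series <- generate_calibration_series(
        list(analyte = an, slope = rf, intercept = 0),
        levels = levels, noise_sd = config$noise_sd,
        seed = config$seed + 7000L + i, config = config)
      meas <- lapply(series$standards, function(ch) {
        noise <- estimate_noise(ch, c(ch$time[1],
                                      ch$time[1] + 2))
        pk <- detect_peaks(ch, noise = max(noise, 1e-9), min_snr = 3)
        if (!nrow(pk)) return(c(area = 0, height = 0, noise = noise))
        j <- which.max(pk$area)
        c(area = pk$area[j], height = pk$height[j], noise = noise)
      })
      meas <- do.call(rbind, meas)
      res$curves[[an]] <- fit_calibration(
        levels, meas[, "area"], analyte = an,
        height = meas[, "height"], noise = stats::median(meas[, "noise"]))
    }
  }

  if ("fingerprint" %in% stages) {
    stopifnot(!is.null(res$matched))
    normalized <- lapply(names(samples), function(sid) {
      m <- res$matched[res$matched$sample_id == sid, , drop = FALSE]
      normalize_retention(samples[[sid]], m, reference_times = specs$rt)
    })
    names(normalized) <- names(samples)
    traces <- lapply(normalized, fingerprint_vector, mode = "trace")
    reference <- build_reference(traces)
    classes <- stats::setNames(res$study$metadata$class,
                               res$study$metadata$sample_id)
    res$similarity <- similarity_report(traces, reference,
                                        classes = classes)
    res$trace_vectors <- traces
  }

  if ("cluster" %in% stages) {
    stopifnot(!is.null(res$matched))
    pv <- lapply(names(samples), function(sid)
      fingerprint_vector(
        res$matched[res$matched$sample_id == sid, , drop = FALSE],
        mode = "peaks", n_common = nrow(specs)))
    names(pv) <- names(samples)
    res$peak_vectors <- pv
    d <- cosine_distance_matrix(pv)
    res$tree <- hca_between_groups(d)
    res$groups <- data.frame(
      sample_id = names(samples),
      class = res$study$metadata$class,
      group_k2 = unname(cut_groups(res$tree, 2L)[names(samples)]),
      group_k3 = unname(cut_groups(res$tree, 3L)[names(samples)]),
      stringsAsFactors = FALSE)
  }

  if ("qams" %in% stages) {
    stopifnot(!is.null(res$matched), !is.null(res$curves))
    if (qams_enabled) {
      res$rcf <- do.call(rbind, lapply(seq_along(injection_volumes),
        function(i) measure_rcf(
          config = config, seed = config$seed + 8000L + i,
          injection_volume = injection_volumes[i])))
      res$rcf_summary <- rcf_robustness(res$rcf)
      fmean <- stats::setNames(res$rcf_summary$mean, res$rcf_summary$analyte)
    }
    is_name <- "adenosine"
    contents <- list()
    for (sid in unique(res$matched$sample_id)) {
      m <- res$matched[res$matched$sample_id == sid, , drop = FALSE]
      s_row <- m[m$analyte == is_name, , drop = FALSE]
      if (!nrow(s_row)) next
      c_s <- (s_row$area - res$curves[[is_name]]$intercept) /
        res$curves[[is_name]]$slope
      for (an in intersect(names(res$curves), m$analyte)) {
        r <- m[m$analyte == an, , drop = FALSE]
        esm <- esm_quantify(r$area, res$curves[[an]],
                            config$extract_volume, config$sample_mass)
        rows <- data.frame(sample_id = sid, analyte = an, method = "ESM",
                           content = esm, stringsAsFactors = FALSE)
        if (!qams_enabled) {
          contents[[paste(sid, an)]] <- rows
          next
        }
        if (an != is_name) {
          qams <- qams_quantify(r$area, s_row$area, c_s, fmean[[an]],
                                config$extract_volume, config$sample_mass)
          rows <- rbind(rows, data.frame(sample_id = sid, analyte = an,
                                         method = "QAMS", content = qams,
                                         stringsAsFactors = FALSE))
        } else {
          # the internal standard is always ESM-quantified
          rows <- rbind(rows, data.frame(sample_id = sid, analyte = an,
                                         method = "QAMS", content = esm,
                                         stringsAsFactors = FALSE))
        }
        contents[[paste(sid, an)]] <- rows
      }
    }
    res$contents <- do.call(rbind, contents)
    rownames(res$contents) <- NULL
    if (qams_enabled) res$agreement <- do.call(rbind, lapply(
      setdiff(unique(res$contents$analyte), is_name), function(an) {
        q <- res$contents[res$contents$analyte == an &
                            res$contents$method == "QAMS", ]
        e <- res$contents[res$contents$analyte == an &
                            res$contents$method == "ESM", ]
        shared <- intersect(q$sample_id, e$sample_id)
        ag <- method_agreement(q$content[match(shared, q$sample_id)],
                               e$content[match(shared, e$sample_id)])
        data.frame(analyte = an, n = ag$n, cosine = ag$cosine,
                   correlation = ag$correlation, stringsAsFactors = FALSE)
      }))
  }

  if (!is.null(out_dir)) write_bundle(res, out_dir)
  res
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline result bundle as delimited text
#'
#' @param res Result list from [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(res$study$metadata, p("sample_metadata.tsv"))
  write_tsv(res$study$truth, p("ground_truth.tsv"))
  if (!is.null(res$matched)) write_tsv(res$matched, p("peak_table.tsv"))
  if (!is.null(res$curves)) {
    ct <- do.call(rbind, lapply(res$curves, function(cv)
      data.frame(analyte = cv$analyte, slope = cv$slope,
                 intercept = cv$intercept, r_squared = cv$r_squared,
                 range_low = cv$linear_range[1],
                 range_high = cv$linear_range[2],
                 lod = cv$lod, loq = cv$loq)))
    write_tsv(ct, p("calibration.tsv"))
  }
  if (!is.null(res$similarity)) write_tsv(res$similarity, p("similarity.tsv"))
  if (!is.null(res$tree)) {
    lt <- data.frame(step = seq_along(res$tree$height),
                     a = res$tree$merge[, 1], b = res$tree$merge[, 2],
                     height = res$tree$height)
    write_tsv(lt, p("linkage.tsv"))
    tree_newick(res$tree, p("dendrogram.nwk"))
    writeLines(tree_text(res$tree), p("dendrogram.txt"))
  }
  if (!is.null(res$groups)) write_tsv(res$groups, p("groups.tsv"))
  if (!is.null(res$rcf_summary)) {
    write_tsv(res$rcf, p("rcf_entries.tsv"))
    write_tsv(res$rcf_summary, p("rcf_summary.tsv"))
  }
  if (!is.null(res$contents)) write_tsv(res$contents, p("contents.tsv"))
  if (!is.null(res$agreement)) write_tsv(res$agreement, p("agreement.tsv"))
  yaml::write_yaml(res$manifest, p("manifest.yaml"))
  invisible(out_dir)
}
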