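#' Relative correction factor between an analyte and the internal standard
#'
#' `F_i/s = (C_i / C_s) x (A_s / A_i)`: the ratio of the internal
#' standard's response factor to the analyte's, measured from a standard
#' mixture of known concentrations. The factor of the internal standard
#' against itself is 1 by construction.
#'
#' @param c_i,c_s Concentrations of analyte and internal standard, ug/mL.
#' @param a_i,a_s Peak areas of analyte and internal standard.
#' @return The dimensionless relative correction factor.
#' @export
compute_rcf <- function(c_i, c_s, a_i, a_s) {
  vals <- c(c_i, c_s, a_i, a_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("concentrations and areas must be positive")
  (c_i / c_s) * (a_s / a_i)
}

#' Summarize relative correction factors across a robustness axis
#'
#' For each analyte, the mean and the sample-SD relative standard
#' deviation of the correction factors measured across the conditions of
#' one axis (injection volume, instrument x column, flow rate, or column
#' temperature).
#'
#' @param entries Data frame with columns `analyte`, `condition` and `f`.
#' @return A data frame: analyte, n, mean, rsd_percent, in the analyte
#'   order of first appearance. Analytes with fewer than 2 entries are
#'   skipped with a warning.
#' @export
rcf_robustness <- function(entries) {
  stopifnot(all(c("analyte", "f") %in% names(entries)))
  if (any(entries$f <= 0)) stop("correction factors must be positive")
  analytes <- unique(entries$analyte)
  rows <- list()
  for (a in analytes) {
    f <- entries$f[entries$analyte == a]
    if (length(f) < 2L) {
      warning("fewer than two entries for ", a, "; skipped")
      next
    }
    rows[[a]] <- data.frame(analyte = a, n = length(f), mean = mean(f),
                            rsd_percent = 100 * stats::sd(f) / mean(f),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-marker (QAMS) quantification
#'
#' Quantifies an analyte from the internal standard's calibrated
#' concentration and the area ratio, `C_i = F_i/s x (A_i / A_s) x C_s`,
#' then converts to content exactly as the external standard route does
#' (`m = C x V`, divided by sample mass).
#'
#' @param a_i Analyte peak area (>= 0).
#' @param a_s Internal standard peak area (> 0).
#' @param c_s Internal standard concentration, ug/mL (> 0), from its own
#'   calibration curve.
#' @param f Relative correction factor for this analyte (> 0), typically
#'   the grand mean across robustness conditions.
#' @param extract_volume Extract volume, mL.
#' @param sample_mass Sample mass, g.
#' @return Content in mg/g.
#' @export
qams_quantify <- function(a_i, a_s, c_s, f, extract_volume = 50,
                          sample_mass = 1.00) {
  if (any(a_s <= 0)) stop("internal standard peak missing (area <= 0)")
  if (any(c_s <= 0)) stop("internal standard concentration must be positive")
  if (any(f <= 0)) stop("relative correction factor must be positive")
  if (sample_mass <= 0) stop("sample_mass must be positive")
  conc <- f * (a_i / a_s) * c_s
  conc * extract_volume / 1000 / sample_mass
}

#' Vector-angle agreement between QAMS and ESM contents
#'
#' The cosine of the angle between the two content vectors across samples
#' (1 means proportional results); the Pearson correlation is reported
#' alongside.
#'
#' @param qams_vec,esm_vec Contents by sample for one analyte under the
#'   two methods; equal length >= 2, `esm_vec` not all zero.
#' @return A list: n, cosine, correlation.
#' @export
method_agreement <- function(qams_vec, esm_vec) {
  if (length(qams_vec) != length(esm_vec) || length(qams_vec) < 2L)
    stop("content vectors must have equal length >= 2")
  ne <- sqrt(sum(esm_vec^2)); nq <- sqrt(sum(qams_vec^2))
  if (ne == 0) stop("ESM content vector has zero norm")
  if (nq == 0) {
    warning("zero-norm QAMS content vector; agreement undefined")
    return(list(n = length(qams_vec), cosine = NA_real_,
                correlation = NA_real_))
  }
  list(n = length(qams_vec),
       cosine = sum(qams_vec * esm_vec) / (nq * ne),
       correlation = stats::cor(qams_vec, esm_vec))
}

#' Load a bundled reference table
#'
#' The package ships the published reference tables for the
#' five-nucleoside assay of fermented Cordyceps products: `table2`
#' (calibration curves), `table4` (correction factors by injection
#' volume), `table5` (by instrument and column), `table6` (by flow rate),
#' `table7` (by column temperature) and `table8` (the 30-sample QAMS vs
#' ESM content comparison, mg/g).
#'
#' @param name One of `"table2"`, `"table4"` ... `"table8"`.
#' @return A data frame.
#' @export
ref_table <- function(name = c("table2", "table4", "table5", "table6",
                               "table7", "table8")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "qamsfp",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Reshape a wide reference correction-factor table to entries
#'
#' Turns the bundled `table4`...`table7` layout (one column per analyte,
#' `f_<analyte>`) into the long `analyte`/`condition`/`f` format consumed
#' by [rcf_robustness()].
#'
#' @param tab A wide data frame with `f_*` columns.
#' @param condition_cols Columns identifying the condition; defaults to
#'   all non-`f_*` columns.
#' @return A long data frame: analyte, condition, f.
#' @export
rcf_entries <- function(tab, condition_cols = NULL) {
  fcols <- grep("^f_", names(tab), value = TRUE)
  if (!length(fcols)) stop("no f_* columns found")
  if (is.null(condition_cols)) condition_cols <- setdiff(names(tab), fcols)
  cond <- do.call(paste, c(tab[condition_cols], sep = "/"))
  do.call(rbind, lapply(fcols, function(cl)
    data.frame(analyte = sub("^f_", "", cl), condition = cond,
               f = tab[[cl]], stringsAsFactors = FALSE)))
}
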