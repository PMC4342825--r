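#' Estimate PCR amplification efficiency from a dilution series
#'
#' Fits the standard curve Cq ~ log10(relative concentration) by least
#' squares and converts the slope to an efficiency:
#' `E = 10^(-1/slope) - 1`, so a slope of -3.3219 corresponds to 100%
#' efficiency (perfect doubling per cycle).
#'
#' @param series `data.frame` with columns `concentration` (relative
#'   template concentration, > 0) and `cq`, e.g. from
#'   [simulate_dilution_series()].
#' @return list with `efficiency` (fraction), `slope`, `r_squared` and
#'   `n_points`.
#' @examples
#' ds <- simulate_dilution_series(0.95, n_points = 6, step = 10)
#' estimate_efficiency(ds)$efficiency  # 0.95
#' @export
estimate_efficiency <- function(series) {
  if (!all(c("concentration", "cq") %in% names(series)))
    stop("dilution series needs 'concentration' and 'cq' columns")
  series <- series[!is.na(series$cq) & !is.na(series$concentration), ]
  if (any(series$concentration <= 0))
    stop("dilution series concentrations must be > 0")
  if (length(unique(series$concentration)) < 3L)
    stop("need at least 3 distinct dilution points to fit a standard curve")
  fit <- stats::lm(cq ~ log10(concentration), data = series)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("standard-curve slope must be negative; check the dilution series")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless series fit exactly
  list(efficiency = 10^(-1 / slope) - 1, slope = slope,
       r_squared = r2, n_points = nrow(series))
}

#' Aggregate technical qPCR replicates
#'
#' Collapses technical replicates of each (sample, assay, run) cell to a
#' mean Cq and a sample standard deviation (n-1 denominator). Missing Cq
#' values (no amplification) are ignored; a cell whose replicates are all
#' missing stays in the table with `cq = NA`. Cells whose replicate SD
#' exceeds `sd_warn` cycles are flagged, a common qPCR QC practice.
#'
#' @param table long-format Cq `data.frame` (columns `sample_id`,
#'   `condition_id`, `bio_replicate`, `run_id`, `assay_id`, `tech_rep`,
#'   `cq`, `sample_kind`).
#' @param sd_warn flag threshold for the technical SD, in cycles.
#' @return aggregated `data.frame` with one row per cell and columns
#'   `cq` (mean), `cq_sd`, `n_used` (non-missing replicates) and `high_sd`.
#' @export
aggregate_technical_replicates <- function(table, sd_warn = 0.5) {
  need <- c("sample_id", "assay_id", "cq")
  if (!all(need %in% names(table)))
    stop("Cq table needs at least columns: ", paste(need, collapse = ", "))
  for (col in c("condition_id", "bio_replicate", "run_id", "sample_kind")) {
    if (is.null(table[[col]]))
      table[[col]] <- if (col == "sample_kind") "unknown" else NA
  }
  f <- interaction(table$sample_id, table$assay_id, table$run_id,
                   drop = TRUE, lex.order = TRUE)
  first <- !duplicated(f)
  out <- table[first, c("sample_id", "condition_id", "bio_replicate",
                        "run_id", "assay_id", "sample_kind")]
  keys <- as.character(f)[first]
  m <- tapply(table$cq, f, mean, na.rm = TRUE)
  s <- tapply(table$cq, f, stats::sd, na.rm = TRUE)
  n <- tapply(!is.na(table$cq), f, sum)
  out$cq <- as.numeric(m[keys])
  out$cq[is.nan(out$cq)] <- NA_real_
  out$cq_sd <- as.numeric(s[keys])
  out$n_used <- as.integer(n[keys])
  out$high_sd <- !is.na(out$cq_sd) & out$cq_sd > sd_warn
  rownames(out) <- NULL
  out
}

#' Align Cq values across qPCR runs with inter-run calibrators
#'
#' For each (run, assay) the offset of the run's calibrator Cq from the
#' across-run mean calibrator Cq is subtracted from every record of that
#' run and assay, putting all plates on a common Cq scale. With a single
#' run the table is returned unchanged.
#'
#' @param table long-format or aggregated Cq `data.frame` containing
#'   records with `sample_kind == "interrun_calibrator"` for every assay
#'   that appears in unknown-sample records of a multi-run table.
#' @return the table with calibrated `cq` values.
#' @export
interrun_calibrate <- function(table) {
  runs <- unique(table$run_id)
  if (length(runs) < 2L) return(table)
  cal <- table[table$sample_kind == "interrun_calibrator" & !is.na(table$cq), ]
  need_assays <- unique(table$assay_id[table$sample_kind == "unknown"])
  cal_mean <- tapply(cal$cq, list(run = cal$run_id, assay = cal$assay_id), mean)
  missing <- character()
  for (a in need_assays) {
    for (r in runs) {
      has <- a %in% colnames(cal_mean) && r %in% rownames(cal_mean) &&
        !is.na(cal_mean[r, a])
      if (!has) missing <- c(missing, sprintf("(%s, %s)", r, a))
    }
  }
  if (length(missing) > 0)
    stop("runs lacking an inter-run calibrator for assays: ",
         paste(missing, collapse = ", "))
  offsets <- sweep(cal_mean, 2L, colMeans(cal_mean), `-`)
  idx <- table$assay_id %in% colnames(offsets) & table$run_id %in% rownames(offsets)
  adj <- offsets[cbind(match(table$run_id[idx], rownames(offsets)),
                       match(table$assay_id[idx], colnames(offsets)))]
  adj[is.na(adj)] <- 0
  table$cq[idx] <- table$cq[idx] - adj
  table
}

#' Build an efficiency table
#'
#' @param assay_id assay identifiers.
#' @param efficiency amplification efficiency as a fraction (1.0 = 100%);
#'   must lie in (0, 2), with a warning outside the usual `[0.85, 1.15]`
#'   assay-validation window.
#' @return `data.frame` with columns `assay_id`, `efficiency` and the
#'   amplification factor `amp_factor = 1 + efficiency`.
#' @export
efficiency_table <- function(assay_id, efficiency) {
  if (length(assay_id) != length(efficiency))
    stop("'assay_id' and 'efficiency' must have the same length")
  if (any(is.na(efficiency)) || any(efficiency <= 0) || any(efficiency >= 2))
    stop("efficiencies must lie in (0, 2)")
  out_of_window <- efficiency < 0.85 | efficiency > 1.15
  if (any(out_of_window))
    warning("assay efficiency outside [0.85, 1.15] for: ",
            paste(assay_id[out_of_window], collapse = ", "))
  data.frame(assay_id = as.character(assay_id), efficiency = efficiency,
             amp_factor = 1 + efficiency, stringsAsFactors = FALSE)
}

#' Transform aggregated Cq values to efficiency-corrected quantities
#'
#' Relative quantity `Q = (1 + E)^(Cq_cal - Cq)` per gene and sample, with
#' per-gene amplification efficiency `E`. With the default calibration
#' (`"min"`, each gene's minimum Cq), the best-expressed sample of every
#' gene gets `Q = 1` and all quantities lie in (0, 1]. Technical replicate
#' SDs are propagated to the log2 scale as `cq_sd * log2(1 + E)`.
#'
#' @param table aggregated Cq `data.frame` from
#'   [aggregate_technical_replicates()]; only `sample_kind == "unknown"`
#'   records are used and the ValidPrime assay is excluded.
#' @param efficiency an [efficiency_table()] `data.frame` or a named
#'   numeric vector of per-assay efficiencies (fractions).
#' @param calibration `"min"` or a named numeric vector of per-gene
#'   reference Cq values.
#' @return object of class `quantity_matrix`: list with `quantity`
#'   (genes x samples), `log2_sd` (technical SD on the log2 scale),
#'   `calibration_cq`, `efficiency` and `sample_info`.
#' @export
cq_to_quantity <- function(table, efficiency, calibration = "min") {
  if (is.data.frame(efficiency)) {
    eff <- stats::setNames(efficiency$efficiency, efficiency$assay_id)
  } else eff <- efficiency
  tab <- table[table$sample_kind == "unknown" & table$assay_id != "VPA", ]
  if (nrow(tab) == 0L) stop("no unknown-sample records to transform")
  genes <- sort(unique(tab$assay_id))
  miss_eff <- setdiff(genes, names(eff))
  if (length(miss_eff) > 0)
    stop("missing amplification efficiency for assay(s): ",
         paste(miss_eff, collapse = ", "))
  samples <- unique(tab$sample_id)
  gi <- match(tab$assay_id, genes)
  si <- match(tab$sample_id, samples)
  cq <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  cq[cbind(gi, si)] <- tab$cq
  sd_mat <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  if (!is.null(tab$cq_sd)) sd_mat[cbind(gi, si)] <- tab$cq_sd

  if (identical(calibration, "min")) {
    cal <- apply(cq, 1L, min, na.rm = TRUE)
  } else {
    if (is.null(names(calibration)) || !all(genes %in% names(calibration)))
      stop("'calibration' must be \"min\" or a named per-gene Cq vector")
    cal <- calibration[genes]
  }
  a <- 1 + eff[genes]
  quantity <- a^(cal - cq)  # recycles a and cal down columns (genes in rows)
  log2_sd <- sd_mat * log2(a)

  sample_info <- unique(tab[, intersect(
    c("sample_id", "condition_id", "bio_replicate", "run_id"), names(tab))])
  sample_info <- sample_info[match(samples, sample_info$sample_id), ]
  rownames(sample_info) <- NULL
  structure(list(quantity = quantity, log2_sd = log2_sd,
                 calibration_cq = cal, efficiency = eff[genes],
                 sample_info = sample_info),
            class = "quantity_matrix")
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("Efficiency-corrected relative quantities: %d genes x %d samples\n",
              nrow(x$quantity), ncol(x$quantity)))
  cat(sprintf("  quantity range: [%.3g, %.3g], %d missing cells\n",
              suppressWarnings(min(x$quantity, na.rm = TRUE)),
              suppressWarnings(max(x$quantity, na.rm = TRUE)),
              sum(is.na(x$quantity))))
  invisible(x)
}

#' Screen samples for genomic-DNA contamination (ValidPrime)
#'
#' The ValidPrime assay (VPA) targets a non-transcribed intergenic region,
#' so its signal in a cDNA sample comes from contaminating gDNA only. Per
#' assay `a`, the gDNA control gives `dCq_a = Cq_a(gDNA) - Cq_VPA(gDNA)`;
#' the gDNA-derived fraction of the signal in sample `s` is then
#' `base^(Cq_a(s) - Cq_VPA(s) - dCq_a)`, capped at 1. Samples in which the
#' VPA did not amplify are reported with fraction 0 and status
#' `"undetected"`.
#'
#' @param table Cq `data.frame` (raw or aggregated) with unknown-sample
#'   records including the `"VPA"` assay.
#' @param gdna_control Cq records of the genomic-DNA control sample
#'   (`sample_kind == "gDNA_control"`), covering VPA and each assay to
#'   screen; defaults to the gDNA records found in `table`.
#' @param amplification_base assumed amplification factor of the assays
#'   (the VPA's own efficiency is typically unknown; default 2).
#' @param threshold flag fractions above this value (default 0.01, i.e.
#'   the conventional 1% screening level).
#' @return `data.frame` of class `contamination_report` with one row per
#'   (sample, assay): `gdna_fraction`, `exceeds_threshold`, `status`.
#' @export
assess_gdna_contamination <- function(table, gdna_control = NULL,
                                      amplification_base = 2,
                                      threshold = 0.01) {
  if (is.null(gdna_control))
    gdna_control <- table[table$sample_kind == "gDNA_control", ]
  if (nrow(gdna_control) == 0L || !"VPA" %in% gdna_control$assay_id)
    stop("gDNA control records including the VPA assay are required")
  g_mean <- tapply(gdna_control$cq, gdna_control$assay_id, mean, na.rm = TRUE)
  dcq <- g_mean - g_mean[["VPA"]]

  unk <- table[table$sample_kind == "unknown", ]
  vpa <- unk[unk$assay_id == "VPA", ]
  vpa_cq <- tapply(vpa$cq, vpa$sample_id, mean, na.rm = TRUE)
  tgt <- unk[unk$assay_id != "VPA", ]
  if (nrow(tgt) == 0L) stop("no target-assay records to screen")
  cq_cell <- tapply(tgt$cq, list(tgt$sample_id, tgt$assay_id), mean, na.rm = TRUE)

  grid <- expand.grid(sample_id = rownames(cq_cell),
                      assay_id = colnames(cq_cell),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$cq <- cq_cell[cbind(grid$sample_id, grid$assay_id)]
  grid$cq_vpa <- as.numeric(vpa_cq[grid$sample_id])
  grid$delta_cq <- as.numeric(dcq[grid$assay_id])
  undetected <- is.na(grid$cq_vpa) | is.nan(grid$cq_vpa)
  frac <- amplification_base^(grid$cq - grid$cq_vpa - grid$delta_cq)
  frac <- pmin(frac, 1)
  frac[undetected] <- 0
  frac[is.na(frac)] <- NA_real_
  grid$gdna_fraction <- frac
  grid$exceeds_threshold <- !is.na(frac) & frac > threshold
  grid$status <- ifelse(undetected, "undetected", "quantified")
  attr(grid, "threshold") <- threshold
  attr(grid, "amplification_base") <- amplification_base
  class(grid) <- c("contamination_report", "data.frame")
  grid
}

#' Box-plot statistics of raw Cq values per gene
#'
#' Per-gene distribution summary matching the usual box-plot conventions:
#' quartiles by linear interpolation between order statistics, whiskers at
#' the most extreme values within 1.5 IQR of the box, points beyond them
#' reported as outliers. With fewer than `min_n` values only the quartiles
#' are reported and the whiskers are left undefined.
#'
#' @param table Cq `data.frame`; only `sample_kind == "unknown"` records
#'   of gene assays (VPA excluded) are summarized.
#' @param min_n minimum number of values for whiskers/outliers (default 4).
#' @return list with `stats` (`data.frame`: `assay_id`, `n`, `mean`,
#'   `median`, `q1`, `q3`, `iqr`, `whisker_low`, `whisker_high`,
#'   `n_outliers`) and `outliers` (named list of outlying Cq values).
#' @export
summarize_cq_distribution <- function(table, min_n = 4L) {
  tab <- table[table$sample_kind == "unknown" & table$assay_id != "VPA" &
                 !is.na(table$cq), ]
  if (nrow(tab) == 0L) stop("no Cq values to summarize")
  genes <- sort(unique(tab$assay_id))
  rows <- vector("list", length(genes))
  outliers <- stats::setNames(vector("list", length(genes)), genes)
  for (i in seq_along(genes)) {
    x <- tab$cq[tab$assay_id == genes[i]]
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    if (length(x) >= min_n) {
      lo_fence <- qs[1] - 1.5 * iqr
      hi_fence <- qs[3] + 1.5 * iqr
      inside <- x[x >= lo_fence & x <= hi_fence]
      out <- sort(x[x < lo_fence | x > hi_fence])
      wl <- min(inside)
      wh <- max(inside)
    } else {
      out <- numeric()
      wl <- NA_real_
      wh <- NA_real_
    }
    outliers[[i]] <- out
    rows[[i]] <- data.frame(assay_id = genes[i], n = length(x),
                            mean = mean(x), median = qs[2], q1 = qs[1],
                            q3 = qs[3], iqr = iqr, whisker_low = wl,
                            whisker_high = wh, n_outliers = length(out),
                            stringsAsFactors = FALSE)
  }
  list(stats = do.call(rbind, rows), outliers = outliers)
}
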