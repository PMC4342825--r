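#' Normalized fold changes for a gene of interest
#'
#' Divides the gene-of-interest quantities by the normalization factor per
#' sample, expresses the result relative to the mean normalized value of
#' the calibrator condition (so the calibrator's mean fold change is 1),
#' and summarizes fold changes per condition as mean and SD across
#' biological replicates. Technical log2 SDs of the GOI and of the NF, if
#' supplied, are combined in quadrature and reported per sample.
#'
#' @param goi_q named positive quantity vector of the gene of interest.
#' @param nf named normalization-factor vector over the same samples.
#' @param conditions named character vector mapping sample id to condition.
#' @param calibrator condition name used as the fold-change reference.
#' @param goi_log2_sd,nf_log2_sd optional named technical SDs (log2 scale).
#' @return object of class `fold_change_result`: list with `per_sample`
#'   (`sample_id`, `condition_id`, `normalized`, `fc`, `log2_fc`,
#'   `tech_log2_sd`), `per_condition` (`condition_id`, `n`, `mean_fc`,
#'   `sd_fc`, `log2_mean_fc`) and `calibrator`.
#' @examples
#' fc <- normalized_fold_change(
#'   c(s1 = 1, s2 = 4), nf = c(s1 = 1, s2 = 2),
#'   conditions = c(s1 = "ctrl", s2 = "treat"), calibrator = "ctrl")
#' fc$per_sample$fc  # 1 2
#' @export
normalized_fold_change <- function(goi_q, nf, conditions, calibrator,
                                   goi_log2_sd = NULL, nf_log2_sd = NULL) {
  samples <- names(goi_q)
  if (is.null(samples) || !setequal(samples, names(nf)))
    stop("'goi_q' and 'nf' must be named over the same samples")
  nf <- nf[samples]
  conditions <- conditions[samples]
  if (anyNA(conditions)) stop("every sample needs a condition label")
  if (!calibrator %in% conditions)
    stop(sprintf("calibrator condition '%s' not present", calibrator))
  if (any(goi_q <= 0) || any(nf <= 0))
    stop("quantities and normalization factors must be strictly positive")
  normalized <- goi_q / nf
  cal_mean <- mean(normalized[conditions == calibrator])
  fc <- normalized / cal_mean
  tech <- rep(NA_real_, length(samples))
  if (!is.null(goi_log2_sd) || !is.null(nf_log2_sd)) {
    g <- if (is.null(goi_log2_sd)) 0 else goi_log2_sd[samples]
    h <- if (is.null(nf_log2_sd)) 0 else nf_log2_sd[samples]
    tech <- sqrt(g^2 + h^2)
  }
  per_sample <- data.frame(sample_id = samples,
                           condition_id = as.character(conditions),
                           normalized = as.numeric(normalized),
                           fc = as.numeric(fc),
                           log2_fc = as.numeric(log2(fc)),
                           tech_log2_sd = as.numeric(tech),
                           stringsAsFactors = FALSE)
  agg_mean <- tapply(fc, conditions, mean)
  agg_sd <- tapply(fc, conditions, stats::sd)
  agg_n <- tapply(fc, conditions, length)
  per_condition <- data.frame(condition_id = names(agg_mean),
                              n = as.integer(agg_n),
                              mean_fc = as.numeric(agg_mean),
                              sd_fc = as.numeric(agg_sd),
                              log2_mean_fc = as.numeric(log2(agg_mean)),
                              stringsAsFactors = FALSE)
  rownames(per_condition) <- NULL
  structure(list(per_sample = per_sample, per_condition = per_condition,
                 calibrator = calibrator),
            class = "fold_change_result")
}

#' Normalization bias between two normalization factors
#'
#' Per-sample log2 ratio of an alternative NF to the reference NF,
#' averaged within each condition. Positive values mean the alternative
#' NF over-estimates the normalization denominator relative to the
#' reference, i.e. under-estimates normalized expression of genes of
#' interest (the sign convention is recorded on the result).
#'
#' @param nf_ref,nf_alt named NF vectors over the same samples.
#' @param conditions optional named sample-to-condition map; without it
#'   each sample is its own condition.
#' @return named numeric vector of per-condition log2 bias, with
#'   attributes `per_sample` and `sign_convention`.
#' @export
bias_per_condition <- function(nf_ref, nf_alt, conditions = NULL) {
  samples <- names(nf_ref)
  if (is.null(samples) || !setequal(samples, names(nf_alt)))
    stop("'nf_ref' and 'nf_alt' must be named over the same samples")
  nf_alt <- nf_alt[samples]
  if (any(nf_ref <= 0) || any(nf_alt <= 0))
    stop("normalization factors must be strictly positive")
  if (is.null(conditions)) conditions <- stats::setNames(samples, samples)
  conditions <- conditions[samples]
  per_sample <- log2(nf_alt / nf_ref)
  bias <- tapply(per_sample, conditions, mean)
  bias <- stats::setNames(as.numeric(bias), names(bias))
  attr(bias, "per_sample") <- per_sample
  attr(bias, "sign_convention") <-
    "positive = alternative NF over-normalizes (under-estimates GOI expression) relative to the reference"
  bias
}

#' Classify normalization-bias values into fold-bias zones
#'
#' Labels each log2 bias by its absolute fold bias `2^|bias|`:
#' `yellow` below 1.5-fold, `green` 1.5-2, `blue` 2-3, `red` 3-8, and
#' `extreme` beyond 8-fold (left-closed bins; 8-fold itself is `red`).
#'
#' @param bias numeric log2 bias values.
#' @return character vector of zone labels (same length/names as `bias`).
#' @export
bias_zones <- function(bias) {
  fold <- 2^abs(bias)
  zone <- ifelse(fold < 1.5, "yellow",
                 ifelse(fold < 2, "green",
                        ifelse(fold < 3, "blue",
                               ifelse(fold <= 8, "red", "extreme"))))
  stats::setNames(zone, names(bias))
}

#' Quantile profile of normalization-bias values
#'
#' Sorted signed log2 biases paired with cumulative fractions i/n
#' (quantile-plot coordinates), plus the fractions of conditions with an
#' absolute fold bias below 1.5 and above 3.
#'
#' @param bias numeric log2 bias values (>= 1).
#' @param fraction_convention `"i/n"` (default) or `"(i-0.5)/n"` for the
#'   cumulative-fraction axis.
#' @return list with `profile` (`data.frame`: `log2_bias`, `fraction`),
#'   `fraction_below_1.5fold` and `fraction_above_3fold`.
#' @export
bias_quantile_profile <- function(bias, fraction_convention = c("i/n", "(i-0.5)/n")) {
  fraction_convention <- match.arg(fraction_convention)
  bias <- bias[!is.na(bias)]
  if (length(bias) == 0L) stop("need at least one bias value")
  sorted <- sort(as.numeric(bias))
  n <- length(sorted)
  frac <- if (fraction_convention == "i/n") seq_len(n) / n
          else (seq_len(n) - 0.5) / n
  fold <- 2^abs(sorted)
  list(profile = data.frame(log2_bias = sorted, fraction = frac),
       fraction_below_1.5fold = mean(fold < 1.5),
       fraction_above_3fold = mean(fold > 3))
}

#' Normalization-bias audit across alternative reference-gene sets
#'
#' Compares the normalization factor of a reference gene set against one
#' or more alternative sets: per-condition log2 bias, zone labels, zone
#' counts and the quantile profile for each alternative.
#'
#' @param q genes x samples quantity matrix or `quantity_matrix`.
#' @param ref_genes character vector, the reference NF gene set.
#' @param alt_sets named list of character vectors, alternative gene sets.
#' @param conditions optional named sample-to-condition map.
#' @return object of class `bias_report`: named list (one element per
#'   alternative set) of lists with `bias`, `zones`, `zone_counts` and
#'   `profile`; the reference set is stored as an attribute.
#' @export
bias_report <- function(q, ref_genes, alt_sets, conditions = NULL) {
  q <- as_quantity_mat(q)
  nf_ref <- normalization_factor(q, ref_genes)
  out <- lapply(alt_sets, function(genes) {
    b <- bias_per_condition(nf_ref, normalization_factor(q, genes), conditions)
    z <- bias_zones(b)
    list(bias = b, zones = z,
         zone_counts = table(factor(z, levels = c("yellow", "green", "blue",
                                                  "red", "extreme"))),
         profile = bias_quantile_profile(b))
  })
  attr(out, "ref_genes") <- ref_genes
  class(out) <- "bias_report"
  out
}
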