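#' Log2 fold-change matrix from RPKM tables
#'
#' For each dataset, expresses every non-control condition relative to the
#' dataset's control condition: `log2(RPKM_interest / RPKM_control)` per
#' gene. Cells where either RPKM is zero or missing become missing
#' ("data not available").
#'
#' @param tables named list of datasets; each element is a list with
#'   `rpkm` (conditions x genes matrix, RPKM >= 0), `control_condition`
#'   (row name of the control) and optionally `organism`.
#' @return list with `fc` (conditions-of-interest x genes log2 FC matrix)
#'   and `row_info` (`dataset_id`, `organism`, `condition`).
#' @export
fold_changes_from_rpkm <- function(tables) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a named list of datasets")
  all_genes <- sort(unique(unlist(lapply(tables, function(t) colnames(t$rpkm)))))
  rows <- list()
  info <- list()
  for (ds in names(tables)) {
    t <- tables[[ds]]
    rpkm <- as.matrix(t$rpkm)
    if (any(rpkm < 0, na.rm = TRUE))
      stop(sprintf("dataset '%s' has negative RPKM values", ds))
    ctrl <- t$control_condition
    if (is.null(ctrl) || !ctrl %in% rownames(rpkm))
      stop(sprintf("dataset '%s' lacks its control condition", ds))
    ctrl_vals <- rpkm[ctrl, ]
    interest <- setdiff(rownames(rpkm), ctrl)
    for (cond in interest) {
      num <- rpkm[cond, ]
      fc <- log2(num / ctrl_vals)
      fc[!is.finite(fc)] <- NA_real_  # zero or missing RPKM on either side
      row <- stats::setNames(rep(NA_real_, length(all_genes)), all_genes)
      row[names(fc)] <- fc
      rows[[length(rows) + 1L]] <- row
      info[[length(info) + 1L]] <- data.frame(
        dataset_id = ds, organism = t$organism %||% NA_character_,
        condition = cond, stringsAsFactors = FALSE)
    }
  }
  fc <- do.call(rbind, rows)
  row_info <- do.call(rbind, info)
  rownames(fc) <- paste(row_info$dataset_id, row_info$condition, sep = ":")
  list(fc = fc, row_info = row_info)
}

#' Pre-select candidate reference genes
#'
#' Applies the pre-selection filters for stable candidate genes: no
#' anti-sense transcription, no alternative-splicing events, expression
#' above the RPKM floor in every dataset and condition, and fold changes
#' close to one (|log2 FC| within `fc_tolerance`) everywhere. Each
#' rejected gene carries the first failing rule, checked in that order.
#'
#' @param fc conditions x genes log2 fold-change matrix (missing allowed).
#' @param rpkm_tables the RPKM dataset list used for `fc` (see
#'   [fold_changes_from_rpkm()]); may be `NULL` to skip the RPKM filter.
#' @param flags optional `data.frame` with columns `gene`, `antisense`,
#'   `alt_splicing` (logical indicators).
#' @param fc_tolerance band on |log2 FC| (default 0.25, i.e. FC within
#'   about 1.19-fold of one).
#' @param min_rpkm expression floor (default 15 RPKM).
#' @return `data.frame` with columns `gene`, `retained`, `reason`
#'   (`NA` for retained genes; otherwise `"antisense"`,
#'   `"alternative_splicing"`, `"low_expression"` or `"unstable_fc"`).
#' @export
preselect_candidates <- function(fc, rpkm_tables = NULL, flags = NULL,
                                 fc_tolerance = 0.25, min_rpkm = 15) {
  genes <- colnames(fc)
  if (is.null(genes)) stop("'fc' must have gene column names")
  reason <- stats::setNames(rep(NA_character_, length(genes)), genes)

  get_flag <- function(col) {
    v <- stats::setNames(rep(FALSE, length(genes)), genes)
    if (!is.null(flags) && col %in% names(flags)) {
      idx <- match(flags$gene, genes)
      v[idx[!is.na(idx)]] <- as.logical(flags[[col]][!is.na(idx)])
    }
    v
  }
  antisense <- get_flag("antisense")
  altsplice <- get_flag("alt_splicing")

  min_rpkm_of_gene <- stats::setNames(rep(Inf, length(genes)), genes)
  if (!is.null(rpkm_tables)) {
    for (t in rpkm_tables) {
      m <- as.matrix(t$rpkm)
      shared <- intersect(colnames(m), genes)
      if (length(shared) > 0) {
        mins <- apply(m[, shared, drop = FALSE], 2L, min, na.rm = TRUE)
        min_rpkm_of_gene[shared] <- pmin(min_rpkm_of_gene[shared], mins)
      }
    }
  }
  max_abs_fc <- apply(abs(fc), 2L, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })

  for (g in genes) {
    if (antisense[[g]]) reason[g] <- "antisense"
    else if (altsplice[[g]]) reason[g] <- "alternative_splicing"
    else if (is.finite(min_rpkm_of_gene[[g]]) && min_rpkm_of_gene[[g]] < min_rpkm)
      reason[g] <- "low_expression"
    else if (!is.na(max_abs_fc[[g]]) && max_abs_fc[[g]] > fc_tolerance)
      reason[g] <- "unstable_fc"
  }
  data.frame(gene = genes, retained = is.na(reason),
             reason = as.character(reason), stringsAsFactors = FALSE)
}

#' Per-gene fold-change summaries
#'
#' Median, interquartile range (linear-interpolation quantiles), mean and
#' a Shapiro-Wilk normality flag over each gene's non-missing log2
#' fold-change values. Genes with fewer than 4 values get quartile-free
#' summaries and are flagged as having too few values.
#'
#' @param fc conditions x genes log2 fold-change matrix.
#' @param alpha significance level of the normality test (default 0.05).
#' @return `data.frame` with columns `gene`, `n`, `mean`, `median`, `q1`,
#'   `q3`, `iqr`, `normal` (logical; `NA` when untestable) and `too_few`.
#' @export
gene_fc_summary <- function(fc, alpha = 0.05) {
  genes <- colnames(fc)
  if (is.null(genes)) stop("'fc' must have gene column names")
  rows <- lapply(genes, function(g) {
    x <- fc[, g]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n >= 4L) {
      qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      q1 <- qs[1]; med <- qs[2]; q3 <- qs[3]; iqr <- qs[3] - qs[1]
    } else if (n >= 1L) {
      med <- stats::median(x); q1 <- NA_real_; q3 <- NA_real_; iqr <- NA_real_
    } else {
      med <- NA_real_; q1 <- NA_real_; q3 <- NA_real_; iqr <- NA_real_
    }
    normal <- NA
    if (n >= 4L && stats::sd(x) > 0 && n <= 5000L)
      normal <- stats::shapiro.test(x)$p.value >= alpha
    data.frame(gene = g, n = n, mean = if (n > 0) mean(x) else NA_real_,
               median = med, q1 = q1, q3 = q3, iqr = iqr, normal = normal,
               too_few = n < 4L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ward clustering of genes into stability classes
#'
#' Standardizes the per-gene (median, IQR) pair to z-scores across genes,
#' clusters with the classical Ward minimum-variance criterion on squared
#' Euclidean distances, and cuts the tree into `k` classes. Centroids are
#' reported on the original (median, IQR) scale.
#'
#' @param summaries output of [gene_fc_summary()] (or any `data.frame`
#'   with columns `gene`, `median`, `iqr`).
#' @param k number of classes (default 5).
#' @return object of class `gene_classification`: list with `classes`
#'   (named integer vector), `centroids` (`data.frame`: `class`, `n`,
#'   `median`, `iqr`), `tree` (the `hclust` object, agglomeration history
#'   retained for audit), `k` and `degenerate`.
#' @export
classify_genes <- function(summaries, k = 5L) {
  need <- c("gene", "median", "iqr")
  if (!all(need %in% names(summaries)))
    stop("summaries need columns: ", paste(need, collapse = ", "))
  ok <- !is.na(summaries$median) & !is.na(summaries$iqr)
  if (!all(ok))
    stop("genes without median/IQR cannot be classified: ",
         paste(summaries$gene[!ok], collapse = ", "))
  x <- as.matrix(summaries[, c("median", "iqr")])
  rownames(x) <- summaries$gene
  if (k > nrow(x))
    stop(sprintf("k = %d exceeds the number of genes (%d)", k, nrow(x)))
  sds <- apply(x, 2L, stats::sd)
  degenerate <- any(sds == 0)
  z <- x
  for (j in 1:2) {
    z[, j] <- if (sds[j] > 0) (x[, j] - mean(x[, j])) / sds[j] else 0
  }
  tree <- stats::hclust(stats::dist(z)^2, method = "ward.D")
  classes <- stats::cutree(tree, k = k)
  cent <- do.call(rbind, lapply(sort(unique(classes)), function(cl) {
    idx <- classes == cl
    data.frame(class = cl, n = sum(idx), median = mean(x[idx, "median"]),
               iqr = mean(x[idx, "iqr"]), stringsAsFactors = FALSE)
  }))
  structure(list(classes = classes, centroids = cent, tree = tree, k = k,
                 degenerate = degenerate),
            class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  cat(sprintf("Ward clustering of %d genes into %d stability classes%s\n",
              length(x$classes), x$k,
              if (x$degenerate) " (degenerate input)" else ""))
  print(x$centroids, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Clip a fold-change matrix for heat-map display
#'
#' Saturates log2 fold changes at +/- `saturation` (the conventional
#' display scale saturates at |log2 FC| = 3.5, i.e. 12-fold and beyond
#' all map to the extreme colour), keeps 0 anchored to the neutral
#' (green) colour and preserves missing cells.
#'
#' @param fc log2 fold-change matrix.
#' @param saturation clipping magnitude in log2 units (default 3.5).
#' @return list with `matrix` (clipped values), `saturation`, `anchor`
#'   (value mapped to the neutral colour) and `scale` (colour-scale
#'   metadata).
#' @export
heatmap_matrix <- function(fc, saturation = 3.5) {
  if (saturation <= 0) stop("'saturation' must be > 0")
  clipped <- pmin(pmax(fc, -saturation), saturation)
  list(matrix = clipped, saturation = saturation, anchor = 0,
       scale = list(neutral_colour = "green", extreme_colour = "red",
                    neutral_value = 0,
                    extreme_values = c(-saturation, saturation)))
}
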