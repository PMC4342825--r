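#' Three-level fully nested variance decomposition
#'
#' Partitions variation in log2 relative expression into three nested
#' random levels — genes, conditions within genes, and biological
#' replicates within conditions — using the method-of-moments estimators
#' from the expected mean squares of the balanced fully nested design:
#' \deqn{E(MS_{rep}) = \sigma^2_{rep}}
#' \deqn{E(MS_{cond}) = \sigma^2_{rep} + n\,\sigma^2_{cond}}
#' \deqn{E(MS_{gene}) = \sigma^2_{rep} + n\,\sigma^2_{cond} + b\,n\,\sigma^2_{gene}}
#' with `b` conditions per gene and `n` replicates per condition.
#' Negative component estimates are truncated to zero before computing
#' percentages of total variance. The closed form requires a balanced
#' design; unbalanced input is rejected with a suggestion to subset.
#'
#' @param data long `data.frame` with columns `gene`, `condition`,
#'   `replicate` and the value column (log2 relative expression).
#' @param value name of the value column (default `"log2_value"`).
#' @return object of class `variance_decomposition`: list with `table`
#'   (`level`, `ss`, `df`, `ms`, `var_component`, `percent`), the design
#'   sizes, `balanced` and `status` (`"ok"` or `"degenerate"` when all
#'   values are identical).
#' @examples
#' d <- simulate_nested_dataset(sd_gene = 0, sd_condition = 1,
#'                              sd_replicate = 1, seed = 42)
#' nested_variance_components(d)
#' @export
nested_variance_components <- function(data, value = "log2_value") {
  need <- c("gene", "condition", "replicate", value)
  if (!all(need %in% names(data)))
    stop("input needs columns: ", paste(need, collapse = ", "))
  y <- data[[value]]
  if (anyNA(y)) stop("missing values are not allowed in the nested design")
  gene <- as.character(data$gene)
  cell <- paste(gene, data$condition, sep = "\r")

  a <- length(unique(gene))
  if (a < 2L) stop("need at least 2 genes")
  conds_per_gene <- tapply(data$condition, gene, function(x) length(unique(x)))
  if (any(conds_per_gene < 2L)) stop("need at least 2 conditions per gene")
  if (length(unique(conds_per_gene)) != 1L)
    stop("unbalanced design: genes have differing numbers of conditions; ",
         "subset to a balanced design first")
  b <- unname(conds_per_gene[1L])
  reps_per_cell <- table(cell)
  if (any(reps_per_cell < 2L))
    stop("need at least 2 replicates in every (gene, condition) cell")
  if (length(unique(as.integer(reps_per_cell))) != 1L)
    stop("unbalanced design: cells have differing replicate counts; ",
         "subset to a balanced design first")
  n <- as.integer(reps_per_cell[1L])

  grand <- mean(y)
  gene_means <- tapply(y, gene, mean)
  cell_means <- tapply(y, cell, mean)
  gene_of_cell <- sub("\r.*$", "", names(cell_means))

  ss_gene <- b * n * sum((gene_means - grand)^2)
  ss_cond <- n * sum((cell_means - gene_means[gene_of_cell])^2)
  ss_rep <- sum((y - cell_means[cell])^2)
  df <- c(gene = a - 1L, condition = a * (b - 1L), replicate = a * b * (n - 1L))
  ss <- c(gene = ss_gene, condition = ss_cond, replicate = ss_rep)
  ms <- ss / df

  sigma2_rep <- ms[["replicate"]]
  sigma2_cond <- (ms[["condition"]] - ms[["replicate"]]) / n
  sigma2_gene <- (ms[["gene"]] - ms[["condition"]]) / (b * n)
  comp <- pmax(c(gene = sigma2_gene, condition = sigma2_cond,
                 replicate = sigma2_rep), 0)
  total <- sum(comp)
  if (total > 0) {
    pct <- 100 * comp / total
    status <- "ok"
  } else {
    pct <- c(gene = 0, condition = 0, replicate = 0)
    status <- "degenerate"
  }
  tab <- data.frame(level = c("gene", "condition", "replicate"),
                    ss = as.numeric(ss), df = as.integer(df),
                    ms = as.numeric(ms), var_component = as.numeric(comp),
                    percent = as.numeric(pct), stringsAsFactors = FALSE)
  structure(list(table = tab, n_genes = a, n_conditions = b,
                 n_replicates = n, balanced = TRUE, status = status),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Three-level nested variance decomposition (%d genes x %d conditions x %d replicates)\n",
              x$n_genes, x$n_conditions, x$n_replicates))
  if (x$status == "degenerate") cat("  degenerate: all values identical\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Log2 relative expression table for the nested ANOVA
#'
#' Converts a quantity matrix into the long-format input of
#' [nested_variance_components()]: per gene, log2 quantity relative to the
#' mean log2 quantity of that gene in the control condition.
#'
#' @param q a `quantity_matrix` (needs `sample_info` with `condition_id`
#'   and `bio_replicate`).
#' @param control_condition condition used as the log2 reference.
#' @return long `data.frame` with columns `gene`, `condition`, `replicate`,
#'   `log2_value`.
#' @export
relative_expression_table <- function(q, control_condition) {
  if (!inherits(q, "quantity_matrix"))
    stop("'q' must be a quantity_matrix (sample annotation is required)")
  info <- q$sample_info
  if (!control_condition %in% info$condition_id)
    stop(sprintf("control condition '%s' not present", control_condition))
  lq <- log2(q$quantity)
  ctrl <- info$condition_id == control_condition
  ref <- rowMeans(lq[, ctrl, drop = FALSE])
  rel <- lq - ref
  data.frame(gene = rep(rownames(rel), times = ncol(rel)),
             condition = rep(info$condition_id, each = nrow(rel)),
             replicate = rep(info$bio_replicate, each = nrow(rel)),
             log2_value = as.numeric(rel),
             stringsAsFactors = FALSE)
}
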