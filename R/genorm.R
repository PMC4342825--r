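#' Pairwise variation between two genes
#'
#' Standard deviation, across samples, of the log2 ratio of two genes'
#' relative quantities. Two perfectly co-regulated (mutually proportional)
#' genes have V = 0.
#'
#' @param qa,qb positive quantity vectors over the same samples (>= 2).
#' @param var_denom `"n-1"` (sample SD, default) or `"n"`.
#' @return V (numeric scalar, >= 0); symmetric in its arguments.
#' @export
pairwise_variation <- function(qa, qb, var_denom = c("n-1", "n")) {
  var_denom <- match.arg(var_denom)
  if (length(qa) != length(qb)) stop("'qa' and 'qb' must cover the same samples")
  if (length(qa) < 2L) stop("need at least 2 samples")
  if (anyNA(qa) || anyNA(qb) || any(qa <= 0) || any(qb <= 0))
    stop("quantities must be strictly positive and complete")
  sd_with_denom(log2(qa / qb), var_denom)
}

#' Gene expression stability measure M
#'
#' For each gene, M is the arithmetic mean of its pairwise variations with
#' all other candidate genes; the most stable genes have the lowest M.
#'
#' @param q genes x samples matrix of positive quantities (>= 3 genes,
#'   >= 2 samples, no missing cells) or a `quantity_matrix`.
#' @param var_denom SD denominator convention, see [pairwise_variation()].
#' @return named numeric vector of M values.
#' @examples
#' q <- rbind(g1 = c(1, 1), g2 = c(1, 2), g3 = c(1, 4))
#' gene_stability_M(q)
#' @export
gene_stability_M <- function(q, var_denom = c("n-1", "n")) {
  var_denom <- match.arg(var_denom)
  q <- as_quantity_mat(q)
  if (nrow(q) < 3L) stop("stability M needs at least 3 candidate genes")
  if (ncol(q) < 2L) stop("stability M needs at least 2 samples")
  check_positive_complete(q)
  lr <- log2(q)
  n <- nrow(q)
  v <- matrix(0, n, n)
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      v[j, k] <- v[k, j] <- sd_with_denom(lr[j, ] - lr[k, ], var_denom)
    }
  }
  stats::setNames(rowSums(v) / (n - 1L), rownames(q))
}

#' Rank candidate reference genes by stepwise exclusion
#'
#' Iteratively computes M on the remaining genes and excludes the gene
#' with the highest M, down to the final two genes, which cannot be
#' ranked against each other and are reported as an unordered best pair.
#' Exact ties on the maximal M are broken towards the lexicographically
#' smallest gene id, and recorded.
#'
#' @inheritParams gene_stability_M
#' @return list with `ranking` (all genes, worst first; the last two are
#'   the best pair in lexicographic order), `exclusion_order`,
#'   `m_at_exclusion` (M of each excluded gene at its exclusion step, plus
#'   the shared M of the best pair), `best_pair`, `initial_M` (full-panel
#'   M values) and `ties` (steps at which a tie was broken).
#' @export
rank_genes <- function(q, var_denom = c("n-1", "n")) {
  var_denom <- match.arg(var_denom)
  q <- as_quantity_mat(q)
  initial_m <- gene_stability_M(q, var_denom)
  remaining <- rownames(q)
  exclusion <- character()
  m_excl <- numeric()
  ties <- character()
  while (length(remaining) > 2L) {
    m <- if (length(remaining) == nrow(q)) initial_m
         else gene_stability_M(q[remaining, , drop = FALSE], var_denom)
    worst <- max(m)
    cand <- sort(names(m)[abs(m - worst) < 1e-12])
    if (length(cand) > 1L)
      ties <- c(ties, sprintf("step %d: {%s} tied at M = %.6g",
                              length(exclusion) + 1L,
                              paste(cand, collapse = ", "), worst))
    pick <- cand[1L]
    exclusion <- c(exclusion, pick)
    m_excl <- c(m_excl, m[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  best_pair <- sort(remaining)
  pair_m <- sd_with_denom(log2(q[best_pair[1L], ] / q[best_pair[2L], ]),
                          var_denom)
  m_at_exclusion <- stats::setNames(c(m_excl, pair_m, pair_m),
                                    c(exclusion, best_pair))
  list(ranking = c(exclusion, best_pair),
       exclusion_order = exclusion,
       m_at_exclusion = m_at_exclusion,
       best_pair = best_pair,
       initial_M = initial_m,
       ties = ties)
}

#' Normalization factor: geometric mean of reference-gene quantities
#'
#' @param q genes x samples quantity matrix or `quantity_matrix`.
#' @param genes non-empty character vector of reference genes to average.
#' @return named numeric vector: per-sample geometric mean of the subset.
#' @export
normalization_factor <- function(q, genes) {
  q <- as_quantity_mat(q)
  if (length(genes) == 0L) stop("reference-gene subset must be non-empty")
  missing <- setdiff(genes, rownames(q))
  if (length(missing) > 0)
    stop("genes not in the quantity matrix: ", paste(missing, collapse = ", "))
  sub <- q[genes, , drop = FALSE]
  check_positive_complete(sub, "reference-gene quantities")
  exp(colMeans(log(sub)))
}

# Best-first gene order from a rank_genes() result (best pair first, in
# lexicographic order, then the remaining genes from best to worst).
best_first_order <- function(ranking) {
  if (is.list(ranking)) c(ranking$best_pair, rev(ranking$exclusion_order))
  else ranking
}

#' Pairwise-variation series V(n/n+1)
#'
#' With genes added best-first, V(n/n+1) is the standard deviation across
#' samples of log2(NF_n / NF_(n+1)), measuring the effect of including the
#' (n+1)-th reference gene in the normalization factor.
#'
#' @inheritParams normalization_factor
#' @param ranking a [rank_genes()] result, or a character vector of all
#'   genes ordered best-first.
#' @param var_denom SD denominator convention.
#' @return named numeric vector `V2/3 ... V(N-1)/N`; empty for < 3 genes.
#' @export
pairwise_variation_series <- function(q, ranking, var_denom = c("n-1", "n")) {
  var_denom <- match.arg(var_denom)
  q <- as_quantity_mat(q)
  order_bf <- best_first_order(ranking)
  if (!setequal(order_bf, rownames(q)))
    stop("'ranking' must cover exactly the genes of the quantity matrix")
  n_genes <- length(order_bf)
  if (n_genes < 3L) return(stats::setNames(numeric(0), character(0)))
  v <- numeric(n_genes - 2L)
  nf_n <- normalization_factor(q, order_bf[1:2])
  for (n in 2:(n_genes - 1L)) {
    nf_n1 <- normalization_factor(q, order_bf[seq_len(n + 1L)])
    v[n - 1L] <- sd_with_denom(log2(nf_n / nf_n1), var_denom)
    nf_n <- nf_n1
  }
  stats::setNames(v, sprintf("V%d/%d", 2:(n_genes - 1L), 3:n_genes))
}

#' Optimal number of reference genes from the V series
#'
#' The smallest n whose V(n/n+1) falls below the cutoff (0.15 by
#' convention): adding the (n+1)-th gene then no longer improves the
#' normalization significantly. If no V value is below the cutoff the full
#' panel size is returned with status `"no_n_below_cutoff"`.
#'
#' @param v_series numeric V(n/n+1) series for n = 2..N-1 (as produced by
#'   [pairwise_variation_series()]).
#' @param cutoff decision threshold on V (default 0.15).
#' @return list with `optimal_n`, `status` (`"ok"` or
#'   `"no_n_below_cutoff"`) and `cutoff`.
#' @examples
#' optimal_gene_count(c(0.20, 0.12, 0.14))  # 3 genes suffice
#' @export
optimal_gene_count <- function(v_series, cutoff = 0.15) {
  if (length(v_series) == 0L) stop("'v_series' must be non-empty")
  n_total <- length(v_series) + 2L
  below <- which(v_series < cutoff)
  if (length(below) == 0L) {
    list(optimal_n = n_total, status = "no_n_below_cutoff", cutoff = cutoff)
  } else {
    list(optimal_n = below[1L] + 1L, status = "ok", cutoff = cutoff)
  }
}

#' Full geNorm-style stability analysis
#'
#' Runs the complete stability workflow on a quantity matrix: per-gene M
#' values, stepwise exclusion ranking, normalization factors NF_n for
#' n = 2..N (genes added best-first), the pairwise-variation series
#' V(n/n+1), and the optimal reference-gene count under the V cutoff.
#' Genes whose full-panel M exceeds `m_threshold` (1.5 by convention) are
#' flagged as unsuitable references.
#'
#' @inheritParams gene_stability_M
#' @param v_cutoff cutoff on V(n/n+1) for the optimal gene count.
#' @param m_threshold flag threshold on the full-panel M value.
#' @return object of class `stability_result`: list with `initial_M`,
#'   `ranking`, `exclusion_order`, `m_at_exclusion`, `best_pair`,
#'   `best_first`, `nf` (samples x NF_n matrix), `v_series`, `optimal_n`,
#'   `status`, `flagged_genes`, `ties` and the cutoffs used.
#' @export
genorm <- function(q, v_cutoff = 0.15, m_threshold = 1.5,
                   var_denom = c("n-1", "n")) {
  var_denom <- match.arg(var_denom)
  q <- as_quantity_mat(q)
  rk <- rank_genes(q, var_denom)
  bf <- best_first_order(rk)
  n_genes <- length(bf)
  nf <- sapply(2:n_genes, function(n) normalization_factor(q, bf[seq_len(n)]))
  colnames(nf) <- sprintf("NF%d", 2:n_genes)
  rownames(nf) <- colnames(q)
  v <- pairwise_variation_series(q, rk, var_denom)
  opt <- optimal_gene_count(v, v_cutoff)
  flagged <- names(rk$initial_M)[rk$initial_M > m_threshold]
  structure(list(initial_M = rk$initial_M,
                 ranking = rk$ranking,
                 exclusion_order = rk$exclusion_order,
                 m_at_exclusion = rk$m_at_exclusion,
                 best_pair = rk$best_pair,
                 best_first = bf,
                 nf = nf,
                 v_series = v,
                 optimal_n = opt$optimal_n,
                 status = opt$status,
                 flagged_genes = flagged,
                 ties = rk$ties,
                 v_cutoff = v_cutoff,
                 m_threshold = m_threshold,
                 var_denom = var_denom),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Reference-gene stability analysis\n")
  cat(sprintf("  %d genes ranked (worst -> best): %s\n",
              length(x$ranking), paste(x$ranking, collapse = " > ")))
  cat(sprintf("  best pair (unordered): {%s}, M = %.4f\n",
              paste(x$best_pair, collapse = ", "),
              x$m_at_exclusion[[x$best_pair[1L]]]))
  cat(sprintf("  optimal number of reference genes: %d (V cutoff %.2f%s)\n",
              x$optimal_n, x$v_cutoff,
              if (x$status != "ok") ", no V below cutoff" else ""))
  if (length(x$flagged_genes) > 0)
    cat("  genes above M threshold ", x$m_threshold, ": ",
        paste(x$flagged_genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}
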