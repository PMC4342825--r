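#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values before averaging.
#' @return The geometric mean of `x`.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items;
#' 1 for identical partitions, ~0 for independent ones. Used to validate
#' recovery of planted stability classes in simulations.
#'
#' @param a,b label vectors of equal length.
#' @return Adjusted Rand index (numeric scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must label the same items")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (isTRUE(all.equal(max_index, expected))) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Standard deviation with a selectable denominator. geNorm-style statistics
# default to the sample convention (n-1); the population form (n) is kept as
# a switch because the original applet's convention is not documented.
sd_with_denom <- function(x, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  n <- length(x)
  if (n < 2) stop("need at least 2 values for a standard deviation")
  s <- stats::sd(x)
  if (denom == "n") s * sqrt((n - 1) / n) else s
}

# Accept either a quantity_matrix object or a plain genes x samples matrix.
as_quantity_mat <- function(q) {
  if (inherits(q, "quantity_matrix")) q <- q$quantity
  q <- as.matrix(q)
  if (is.null(rownames(q))) rownames(q) <- sprintf("gene%02d", seq_len(nrow(q)))
  if (is.null(colnames(q))) colnames(q) <- sprintf("sample%02d", seq_len(ncol(q)))
  storage.mode(q) <- "double"
  q
}

check_positive_complete <- function(q, what = "quantity matrix") {
  if (anyNA(q)) {
    bad <- which(is.na(q), arr.ind = TRUE)
    bad <- utils::head(apply(bad, 1L, function(i) {
      paste0(rownames(q)[i[1]], "/", colnames(q)[i[2]])
    }), 10L)
    stop(sprintf("%s has missing cells (%s%s); drop the offending genes or samples first",
                 what, paste(bad, collapse = ", "),
                 if (sum(is.na(q)) > 10) ", ..." else ""))
  }
  if (any(q <= 0)) stop(sprintf("%s must be strictly positive", what))
  invisible(q)
}
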