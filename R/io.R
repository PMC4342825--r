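# Tabular and JSON I/O. All tables are TSV with dot decimal separator and
# the literal token "NA" for missing cells; nested results go to JSON.

#' Read / write a long-format Cq table
#'
#' @param path file path (TSV with columns `sample_id`, `condition_id`,
#'   `bio_replicate`, `run_id`, `assay_id`, `tech_rep`, `cq`,
#'   `sample_kind`).
#' @return `read_cq_table`: the Cq `data.frame`.
#' @export
read_cq_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("sample_id", "assay_id", "cq")
  if (!all(need %in% names(tab)))
    stop("Cq table at '", path, "' lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  bad <- !is.na(tab$cq) & (tab$cq <= 0 | tab$cq > 45)
  if (any(bad))
    warning(sum(bad), " Cq value(s) outside (0, 45]")
  tab
}

#' @rdname read_cq_table
#' @param table Cq `data.frame` to write.
#' @export
write_cq_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an efficiency table
#'
#' Expects columns `assay_id` and either `efficiency` (fraction) or
#' `efficiency_percent`; validates through [efficiency_table()].
#'
#' @param path TSV file path.
#' @return validated efficiency `data.frame`.
#' @export
read_efficiency_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("efficiency_percent" %in% names(tab)) {
    eff <- tab$efficiency_percent / 100
  } else if ("efficiency" %in% names(tab)) {
    eff <- tab$efficiency
  } else stop("efficiency table needs 'efficiency' or 'efficiency_percent'")
  efficiency_table(tab$assay_id, eff)
}

#' Write / read a genes x samples matrix as TSV
#'
#' @param m matrix (or `quantity_matrix`, whose `quantity` slot is used).
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "quantity_matrix")) m <- m$quantity
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an R object as pretty JSON
#'
#' @param x object (lists, data frames, vectors).
#' @param path file path.
#' @export
write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
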