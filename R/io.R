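#' Read and write allele tables
#'
#' Tab-separated text with header columns `cell_id`, `intBC`, `site`,
#' `lineage_mark`, `umi_count`, `read_count`.
#'
#' @param file path.
#' @export
read_allele_table <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("cell_id", "intBC", "site", "lineage_mark", "umi_count",
            "read_count")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("allele table missing columns: ", paste(miss, collapse = ", "))
  tab[need]
}

#' @rdname read_allele_table
#' @param table allele table data.frame.
#' @export
write_allele_table <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read and write character matrices
#'
#' TSV with cells as rows and characters as columns; states coded `UE`,
#' `M1`..`M8`, `ND`.
#'
#' @param file path.
#' @export
read_character_matrix <- function(file) {
  df <- utils::read.delim(file, row.names = 1, check.names = FALSE,
                          colClasses = "character")
  M <- apply(as.matrix(df), c(1, 2), identity)
  out <- matrix(code_to_state(M), nrow(M), ncol(M), dimnames = dimnames(M))
  out
}

#' @rdname read_character_matrix
#' @param matrix integer character matrix.
#' @export
write_character_matrix <- function(matrix, file) {
  M <- matrix(state_to_code(matrix), nrow(matrix), ncol(matrix),
              dimnames = dimnames(matrix))
  utils::write.table(M, file, sep = "\t", quote = FALSE, col.names = NA)
  invisible(file)
}

#' Write cell class labels as CSV
#' @param labels data.frame `cell_id`, `label` (from [classify_cells()]).
#' @param file path.
#' @export
write_cell_labels <- function(labels, file) {
  utils::write.csv(labels, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
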