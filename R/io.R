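# TSV readers/writers for the pipeline's on-disk formats. TSV (not CSV)
# so gene symbols with commas never need escaping; NA encodes missing.

#' Write / read a wide abundance matrix as TSV
#'
#' Rows are samples, columns proteins; the first column (`sample_id`)
#' holds sample ids and missing cells are written as `NA`. The round
#' trip is lossless including the missingness pattern.
#'
#' @param matrix Numeric samples x proteins matrix.
#' @param path Output path.
#' @return `write_protein_matrix` the path invisibly;
#'   `read_protein_matrix` the matrix.
#' @export
write_protein_matrix <- function(matrix, path) {
  assert_matrix(matrix, "matrix")
  df <- data.frame(sample_id = rownames(matrix), matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protein_matrix
#' @export
read_protein_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") abort("first column must be sample_id")
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in matrix file")
  if (anyDuplicated(names(df)[-1])) {
    dup <- names(df)[-1][duplicated(names(df)[-1])][1]
    abort(sprintf("duplicate protein column: %s", dup))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(df[, -1, drop = FALSE]), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf("non-numeric cell at row %d, column %s",
                    bad[1, 1], names(df)[-1][bad[1, 2]]))
    }
    storage.mode(m) <- "double"
  }
  rownames(m) <- df$sample_id
  m
}

#' Write a tibble as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table as a tibble
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE))
}
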