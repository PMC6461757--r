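#' Read a two-column seed taxonomy TSV
#'
#' Expects columns genome id and semicolon-delimited lineage string (no
#' header by default).
#'
#' @param path File path.
#' @param header Whether the file carries a header row.
#' @return Named character vector genome -> lineage.
#' @export
read_seed_taxonomy <- function(path, header = FALSE) {
  tab <- read.table(path, sep = "\t", header = header,
                    stringsAsFactors = FALSE, quote = "")
  setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read a genome x marker copy-count TSV
#'
#' @param path File path; first column = genome ids, header = marker ids.
#' @return Integer matrix with genome rownames and marker colnames.
#' @export
read_marker_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                    check.names = FALSE)
  as.matrix(tab)
}

#' Read a clade x sample count TSV with its sample metadata
#'
#' @param counts_path TSV of counts, first column clade ids, header samples.
#' @param metadata_path TSV with a `sample` column keying the count columns.
#' @return An `abundance_dataset` list (`counts`, `metadata`).
#' @export
read_abundance_dataset <- function(counts_path, metadata_path) {
  counts <- as.matrix(read.table(counts_path, sep = "\t", header = TRUE,
                                 row.names = 1L, check.names = FALSE))
  meta <- read.table(metadata_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(meta)) stop("metadata needs a 'sample' column")
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  if (any(is.na(meta$sample)))
    stop("metadata does not cover every count sample")
  structure(list(counts = counts, metadata = meta),
            class = "abundance_dataset")
}

#' Write a matrix as TSV with a leading id column
#'
#' @param x Matrix or data frame.
#' @param path Output path.
#' @param id_name Name of the leading id column (rownames of `x`).
#' @export
write_tsv_matrix <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
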