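#' Read and write the pipeline's TSV dialects
#'
#' Counts and Cq tables are TSVs with features in rows (first column
#' `feature_id`) and samples in columns; metadata tables are long TSVs with
#' one row per sample.
#'
#' @param path file path.
#' @name neuromir-io
NULL

#' @describeIn neuromir-io read a feature-by-sample matrix TSV.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' @describeIn neuromir-io write a matrix as TSV with a `feature_id` lead
#'   column.
#' @param x matrix to write.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn neuromir-io read a counts TSV plus sample-metadata TSV into
#'   a [count_matrix()].
#' @param meta_path sample metadata TSV (columns `sample_id`, `group`, ...).
#' @export
read_counts <- function(path, meta_path) {
  count_matrix(read_matrix_tsv(path),
               utils::read.delim(meta_path, stringsAsFactors = FALSE))
}

#' @describeIn neuromir-io read a counts TSV plus metadata TSV (columns
#'   `sample_id`, `arm`, `condition`, `replicate`) into an
#'   [expression_matrix()].
#' @export
read_expression <- function(path, meta_path) {
  expression_matrix(read_matrix_tsv(path),
                    utils::read.delim(meta_path, stringsAsFactors = FALSE))
}

#' @describeIn neuromir-io read a Cq TSV plus metadata TSV (columns
#'   `sample_id`, `region`, `age_weeks_pc`, `age_group`) into a
#'   [cq_matrix()].
#' @export
read_cq <- function(path, meta_path) {
  cq_matrix(read_matrix_tsv(path),
            utils::read.delim(meta_path, stringsAsFactors = FALSE))
}

#' @describeIn neuromir-io write a data.frame as a plain TSV.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
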