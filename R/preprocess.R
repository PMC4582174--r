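#' Small-RNA read batch
#'
#' @param read_id character vector of read identifiers.
#' @param sequence character vector of read sequences (non-empty).
#' @param quality character vector of Phred+33 quality strings, same length
#'   per record as the sequence.
#' @return object of class `read_batch`: data.frame with those columns.
#' @export
read_batch <- function(read_id, sequence, quality = strrep("I", nchar(sequence))) {
  if (length(sequence) &&
      (anyNA(sequence) || any(!nzchar(sequence))))
    stop("read sequences must be non-empty")
  if (length(quality) != length(sequence) ||
      (length(sequence) && any(nchar(quality) != nchar(sequence))))
    stop("quality strings must match sequence lengths")
  out <- data.frame(read_id = as.character(read_id), sequence = sequence,
                    quality = quality, stringsAsFactors = FALSE)
  class(out) <- c("read_batch", "data.frame")
  out
}

#' Read a FASTQ file into a read batch
#'
#' @param path FASTQ file (4-line records, Phred+33).
#' @return a [read_batch()].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  read_batch(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read batch to FASTQ
#'
#' @param reads a [read_batch()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Trim 3' sequencing adapters from reads
#'
#' Removes the adapter and everything after it. The read prefix preceding
#' the leftmost exact occurrence of the full adapter is returned; if the
#' full adapter does not occur, the longest adapter prefix of length at
#' least `min_overlap` that occurs as a read suffix is removed (a read
#' ending mid-adapter). Reads without either match are returned unchanged.
#' Matching is exact (no mismatches).
#'
#' @param read_sequence character vector of read sequences.
#' @param adapter adapter sequence (DNA alphabet).
#' @param min_overlap minimum adapter-prefix length accepted at the read
#'   end; default 8.
#' @return character vector of trimmed sequences.
#' @export
trim_adapter <- function(read_sequence, adapter, min_overlap = 8L) {
  if (length(adapter) != 1 || is.na(adapter) || !nzchar(adapter))
    stop("adapter must be a single non-empty string")
  if (anyNA(read_sequence) || any(!nzchar(read_sequence)))
    stop("read sequences must be non-empty")
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1 || nchar(adapter) < min_overlap)
    stop("need adapter length >= min_overlap >= 1")

  out <- read_sequence
  # full adapter, leftmost occurrence
  pos <- regexpr(adapter, out, fixed = TRUE)
  hit <- pos > 0
  out[hit] <- substr(out[hit], 1L, pos[hit] - 1L)
  # partial adapter at read end: longest prefix of the adapter that is a
  # read suffix, length >= min_overlap
  todo <- which(!hit)
  if (length(todo)) {
    for (k in seq(nchar(adapter) - 1L, min_overlap)) {
      if (!length(todo)) break
      pre <- substr(adapter, 1L, k)
      sub <- todo[endsWith(out[todo], pre)]
      if (length(sub)) {
        out[sub] <- substr(out[sub], 1L, nchar(out[sub]) - k)
        todo <- setdiff(todo, sub)
      }
    }
  }
  out
}

#' Drop reads shorter than a minimum length
#'
#' Reads shorter than 15 nt cannot be assigned to a mature miRNA reliably
#' and are removed after adapter trimming; the boundary length is kept.
#'
#' @param reads a [read_batch()].
#' @param min_length minimum surviving length, default 15.
#' @return a [read_batch()] with only reads of length >= `min_length`,
#'   input order preserved.
#' @export
filter_length <- function(reads, min_length = 15L) {
  min_length <- as.integer(min_length)
  if (min_length < 1) stop("min_length must be >= 1")
  keep <- nchar(reads$sequence) >= min_length
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_batch", "data.frame")
  out
}

#' Collapse identical reads to sequence counts
#'
#' @param reads a [read_batch()] (already trimmed and length-filtered).
#' @return object of class `collapsed_reads`: data.frame with columns
#'   `sequence` and `count`, one row per distinct sequence, ordered by
#'   decreasing count then sequence. Counts sum to `nrow(reads)`.
#' @export
collapse_reads <- function(reads) {
  tab <- table(reads$sequence)
  out <- data.frame(sequence = as.character(names(tab)),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (!nrow(out)) out <- data.frame(sequence = character(0),
                                    count = integer(0))
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("collapsed_reads", "data.frame")
  out
}

#' Assign collapsed reads to reference features by exact match
#'
#' A collapsed sequence contributes its count to a feature if and only if
#' it equals that feature's mature sequence exactly (full length, after
#' U -> T canonicalization). Because identical reference sequences are
#' merged into one feature, each read maps to at most one feature.
#' Non-matching reads are tallied as unassigned.
#'
#' @param collapsed a [collapse_reads()] result.
#' @param reference a [mature_reference()].
#' @return list with `counts` (named integer vector over all feature_ids),
#'   `unassigned` (integer) and `total` (assigned + unassigned).
#' @export
count_sample <- function(collapsed, reference) {
  if (!inherits(reference, "mature_reference") || nrow(reference) == 0)
    stop("reference must be a non-empty mature_reference")
  counts <- stats::setNames(integer(nrow(reference)), reference$feature_id)
  unassigned <- 0L
  if (nrow(collapsed)) {
    seqs <- canonicalize_sequence(collapsed$sequence)
    idx <- match(seqs, reference$sequence)
    hit <- !is.na(idx)
    if (any(hit)) {
      agg <- tapply(collapsed$count[hit], idx[hit], sum)
      counts[as.integer(names(agg))] <- as.integer(agg)
      names(counts) <- reference$feature_id
    }
    unassigned <- sum(collapsed$count[!hit])
  }
  list(counts = counts, unassigned = as.integer(unassigned),
       total = as.integer(sum(counts) + unassigned))
}

#' Run the full small-RNA counting pipeline over FASTQ samples
#'
#' For each sample: adapter trimming, length filtering, collapsing of
#' identical reads, and exact-match assignment to the mature reference.
#'
#' @param fastq_files named character vector of FASTQ paths; names are
#'   sample ids.
#' @param reference a [mature_reference()].
#' @param sample_meta data.frame with `sample_id` and `group` for each
#'   sample; defaults to a single group "sample".
#' @param adapter adapter sequence for [trim_adapter()].
#' @param min_overlap,min_length see [trim_adapter()] and [filter_length()].
#' @return list with `counts` (a [count_matrix()]) and `stats` (data.frame
#'   of per-sample surviving, assigned and unassigned read counts).
#' @export
count_samples <- function(fastq_files, reference, sample_meta = NULL,
                          adapter, min_overlap = 8L, min_length = 15L) {
  if (is.null(names(fastq_files)) || any(!nzchar(names(fastq_files))))
    stop("fastq_files must be named by sample id")
  cols <- lapply(fastq_files, function(fp) {
    reads <- read_fastq(fp)
    reads$sequence <- trim_adapter(reads$sequence, adapter, min_overlap)
    reads$quality <- substr(reads$quality, 1L, nchar(reads$sequence))
    reads <- filter_length(reads, min_length)
    count_sample(collapse_reads(reads), reference)
  })
  values <- vapply(cols, `[[`, integer(nrow(reference)), "counts")
  if (is.null(dim(values)))
    values <- matrix(values, nrow = nrow(reference),
                     dimnames = list(reference$feature_id, names(fastq_files)))
  stats_df <- data.frame(
    sample_id = names(fastq_files),
    surviving = vapply(cols, `[[`, integer(1), "total"),
    assigned = colSums(values),
    unassigned = vapply(cols, `[[`, integer(1), "unassigned"),
    row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = names(fastq_files),
                              group = "sample", stringsAsFactors = FALSE)
  list(counts = count_matrix(values, sample_meta), stats = stats_df)
}
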