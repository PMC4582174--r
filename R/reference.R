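#' Build a mature-miRNA reference with family annotations
#'
#' Constructs the reference used for exact-match read assignment. Mature
#' miRNA sequences are canonicalized from RNA to DNA alphabet (U -> T) and
#' entries with identical sequences are merged into a single feature: the
#' merged feature keeps all contributing mature names (sorted
#' lexicographically) and takes the lexicographically first name as its
#' `feature_id`. Each mature name must map to exactly one miRNA family
#' (seed-defined grouping, e.g. miR-10a and miR-10b both belong to the
#' miR-10 family).
#'
#' @param names character vector of mature miRNA names (unique).
#' @param families character vector of family labels, parallel to `names`;
#'   non-empty for every entry.
#' @param sequences character vector of mature sequences (RNA or DNA
#'   alphabet, 15-30 nt), parallel to `names`.
#' @return object of class `mature_reference`: data.frame with columns
#'   `feature_id`, `names` (list column), `family`, `sequence`.
#' @export
mature_reference <- function(names, families, sequences) {
  if (length(names) == 0) stop("empty reference")
  if (length(families) != length(names) || length(sequences) != length(names))
    stop("names, families and sequences must have equal length")
  if (anyDuplicated(names))
    stop("duplicate mature names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (any(is.na(families) | families == ""))
    stop("every mature miRNA needs a non-empty family label")
  sequences <- canonicalize_sequence(sequences)
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop("non-ACGU/ACGT characters in sequences of: ",
         paste(names[bad], collapse = ", "))
  len <- nchar(sequences)
  if (any(len < 15 | len > 30))
    stop("mature sequences must be 15-30 nt; offending: ",
         paste(names[len < 15 | len > 30], collapse = ", "))

  merged <- lapply(split(seq_along(sequences), sequences), function(idx) {
    nm <- sort(names[idx])
    fam <- unique(families[idx])
    if (length(fam) > 1)
      stop("identical sequence annotated with conflicting families: ",
           paste(nm, collapse = ", "))
    list(feature_id = nm[[1]], names = nm, family = fam,
         sequence = sequences[idx[[1]]])
  })
  ref <- data.frame(
    feature_id = vapply(merged, `[[`, "", "feature_id"),
    family = vapply(merged, `[[`, "", "family"),
    sequence = vapply(merged, `[[`, "", "sequence"),
    stringsAsFactors = FALSE
  )
  ref$names <- lapply(merged, `[[`, "names")
  ref <- ref[order(ref$feature_id), c("feature_id", "names", "family",
                                      "sequence")]
  rownames(ref) <- NULL
  class(ref) <- c("mature_reference", "data.frame")
  ref
}

#' Read a mature-miRNA reference from FASTA plus a family table
#'
#' @param mature_fasta path to a FASTA of mature miRNA sequences (miRBase
#'   style, RNA alphabet accepted); record names are the mature names.
#' @param family_table path to a TSV with columns `mature_name` and
#'   `family`, mapping every mature name to its family.
#' @return a [mature_reference()].
#' @export
build_reference <- function(mature_fasta, family_table) {
  seqs <- Biostrings::readBStringSet(mature_fasta)
  nm <- sub("\\s.*$", "", names(seqs))  # keep first FASTA header token
  fam_tab <- utils::read.delim(family_table, stringsAsFactors = FALSE)
  for (col in c("mature_name", "family"))
    if (!col %in% names(fam_tab))
      stop("family table lacks column '", col, "'")
  if (anyDuplicated(fam_tab$mature_name))
    stop("duplicate mature_name rows in family table")
  missing <- setdiff(nm, fam_tab$mature_name)
  if (length(missing))
    stop("mature names missing from family table: ",
         paste(missing, collapse = ", "))
  mature_reference(nm,
                   fam_tab$family[match(nm, fam_tab$mature_name)],
                   as.character(seqs))
}

#' @export
print.mature_reference <- function(x, ...) {
  cat(sprintf("mature_reference: %d features, %d families\n",
              nrow(x), length(unique(x$family))))
  invisible(x)
}

#' Canonicalize miRNA sequences to the DNA alphabet
#'
#' Uppercases and converts U to T so that RNA-alphabet reference sequences
#' and DNA-alphabet sequencing reads can be compared by exact string
#' equality.
#'
#' @param x character vector of sequences.
#' @return character vector in the {A,C,G,T,...} alphabet.
#' @export
canonicalize_sequence <- function(x) {
  chartr("uU", "TT", toupper(x))
}

# Internal: family lookup usable by family_fractions(); accepts either a
# mature_reference or a named character vector family-by-feature.
.family_map <- function(reference, feature_ids) {
  if (inherits(reference, "mature_reference")) {
    fam <- reference$family[match(feature_ids, reference$feature_id)]
  } else if (is.character(reference) && !is.null(names(reference))) {
    fam <- unname(reference[feature_ids])
  } else {
    stop("reference must be a mature_reference or a named character vector")
  }
  if (anyNA(fam))
    stop("features without a family: ",
         paste(feature_ids[is.na(fam)], collapse = ", "))
  fam
}
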