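#' Count matrix with sample metadata
#'
#' Light container pairing a non-negative integer feature-by-sample matrix
#' with per-sample metadata. Used for mature-miRNA counts from small-RNA
#' sequencing, where samples belong to cell groups (e.g. hESC, FB_NE, MB_NE,
#' HB_NE, MB_FP, HB_FP, ME, HLF) with 2-4 replicates each.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   no negative cells. Row and column names required.
#' @param sample_meta data.frame with at least columns `sample_id` and
#'   `group`; `sample_id` must match `colnames(values)` one-to-one.
#' @return object of class `count_matrix`: list with elements `values` and
#'   `sample_meta`.
#' @export
count_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix needs row (feature) and column (sample) names")
  if (anyNA(values) || any(values < 0))
    stop("count matrix cells must be non-negative and non-missing")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group"))
    if (!col %in% names(sample_meta))
      stop("sample_meta lacks required column '", col, "'")
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicated sample_id in sample_meta")
  if (!setequal(sample_meta$sample_id, colnames(values)))
    stop("sample_meta$sample_id does not match colnames(values)")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (any(is.na(sample_meta$group) | sample_meta$group == ""))
    stop("every sample needs a group")
  structure(list(values = values, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$sample_meta$group)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Expression matrix for paired overexpression/control mRNA counts
#'
#' Same structure as [count_matrix()] but the metadata describes the
#' doxycycline-inducible overexpression design: each sample has an `arm`
#' (which miRNA construct, e.g. miR10a or miR10b), a `condition`
#' (`dox` = overexpression induced, `no_dox` = control) and a replicate
#' index. The study design uses three replicates per arm-by-condition group.
#'
#' @param values gene-by-sample non-negative count matrix with dimnames.
#' @param sample_meta data.frame with columns `sample_id`, `arm`,
#'   `condition`, `replicate`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row (gene) and column (sample) names")
  if (anyNA(values) || any(values < 0))
    stop("expression matrix cells must be non-negative and non-missing")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  for (col in c("sample_id", "arm", "condition", "replicate"))
    if (!col %in% names(sample_meta))
      stop("sample_meta lacks required column '", col, "'")
  if (!all(sample_meta$condition %in% c("dox", "no_dox")))
    stop("condition must be 'dox' or 'no_dox'")
  if (!setequal(sample_meta$sample_id, colnames(values)))
    stop("sample_meta$sample_id does not match colnames(values)")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$sample_meta$arm, x$sample_meta$condition)
  print(tab)
  invisible(x)
}

#' Cq matrix from a targeted qPCR miRNA panel
#'
#' Holds raw quantification-cycle (Cq) values, one row per panel miRNA and
#' one column per tissue sample. Missing values mark assays that did not
#' amplify. Metadata records the dissected rostro-caudal region
#' (FB, vMB, dMB, vHB, dHB, pHB, SC) and the foetal age (weeks
#' post-conception plus a coarse age-group label).
#'
#' @param values numeric matrix of Cq values (NA allowed), dimnames required;
#'   present values must lie in (0, 50) cycles.
#' @param sample_meta data.frame with columns `sample_id`, `region`,
#'   `age_weeks_pc`, `age_group`.
#' @param regions allowed region vocabulary.
#' @return object of class `cq_matrix`.
#' @export
cq_matrix <- function(values, sample_meta,
                      regions = c("FB", "vMB", "dMB", "vHB", "dHB", "pHB",
                                  "SC")) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("Cq matrix needs row (miRNA) and column (sample) names")
  present <- values[!is.na(values)]
  if (any(present <= 0 | present >= 50))
    stop("Cq values must lie in (0, 50) cycles")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  for (col in c("sample_id", "region", "age_weeks_pc", "age_group"))
    if (!col %in% names(sample_meta))
      stop("sample_meta lacks required column '", col, "'")
  if (!all(sample_meta$region %in% regions))
    stop("unknown region(s): ",
         paste(setdiff(sample_meta$region, regions), collapse = ", "))
  if (!setequal(sample_meta$sample_id, colnames(values)))
    stop("sample_meta$sample_id does not match colnames(values)")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("cq_matrix: %d miRNAs x %d samples (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat("regions:", paste(unique(x$sample_meta$region), collapse = ", "), "\n")
  invisible(x)
}

# Internal: pull the values matrix out of any of the light containers,
# or pass a plain matrix through.
.values <- function(x) {
  if (inherits(x, c("count_matrix", "expression_matrix", "cq_matrix",
                    "normalized_matrix", "dcq_matrix")))
    x$values
  else as.matrix(x)
}

# Internal: sample metadata or NULL.
.meta <- function(x) {
  if (is.list(x) && !is.null(x$sample_meta)) x$sample_meta else NULL
}
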