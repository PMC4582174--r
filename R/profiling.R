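#' Normalize a count matrix to equal column totals
#'
#' Scales every sample so all columns sum to the same total; within-sample
#' proportions are unchanged. This is the total-count normalization used
#' before enrichment selection and family pooling.
#'
#' @param counts a [count_matrix()], or a plain feature-by-sample matrix.
#' @param target_total positive number, or `"median"` (default) to use the
#'   median of the raw column sums.
#' @return object of class `normalized_matrix`: list with `values` (every
#'   column summing to `target_total`), `target_total`, and the source
#'   `sample_meta` (if any).
#' @export
normalize_total_counts <- function(counts, target_total = "median") {
  values <- .values(counts)
  colsums <- colSums(values)
  if (any(colsums <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(values)[colsums <= 0], collapse = ", "))
  if (identical(target_total, "median")) {
    target_total <- stats::median(colsums)
  } else if (!is.numeric(target_total) || length(target_total) != 1 ||
             target_total <= 0) {
    stop("target_total must be a positive number or \"median\"")
  }
  scaled <- sweep(values, 2, target_total / colsums, `*`)
  structure(list(values = scaled, target_total = target_total,
                 sample_meta = .meta(counts)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d features x %d samples, total %g/sample\n",
              nrow(x$values), ncol(x$values), x$target_total))
  invisible(x)
}

#' Per-group mean expression
#'
#' Arithmetic mean of normalized counts over the replicates of each sample
#' group.
#'
#' @param norm a [normalize_total_counts()] result (or any matrix-bearing
#'   container).
#' @param groups character vector of group labels per sample; defaults to
#'   the container's `sample_meta$group`.
#' @return feature-by-group matrix of means.
#' @export
group_means <- function(norm, groups = NULL) {
  values <- .values(norm)
  if (is.null(groups)) {
    meta <- .meta(norm)
    if (is.null(meta)) stop("no sample metadata; supply groups explicitly")
    groups <- meta$group
  }
  if (length(groups) != ncol(values))
    stop("groups must have one label per sample")
  glev <- unique(groups)
  out <- vapply(glev, function(g)
    rowMeans(values[, groups == g, drop = FALSE]),
    numeric(nrow(values)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(values),
                  dimnames = list(rownames(values), glev))
  out
}

#' Select miRNAs enriched in neural progenitors relative to a reference group
#'
#' Flags miRNAs whose mean normalized expression in at least one tested
#' neuroepithelial group is at least `fold_threshold` times the reference
#' (hESC) mean ("and/or" semantics over the tested groups). Fold changes
#' use a pseudocount so that reference zeros give finite ratios. Mean
#' expression in non-ectodermal comparison groups (e.g. ME, HLF), when
#' present in `means`, is carried along; an optional ceiling on those
#' groups can additionally require low non-ectodermal expression.
#'
#' @param means feature-by-group mean matrix from [group_means()].
#' @param reference_group reference column name, default `"hESC"`.
#' @param tested_groups groups tested for enrichment; default the three
#'   neuroepithelial groups `c("FB_NE", "MB_NE", "HB_NE")`.
#' @param fold_threshold selection threshold on the fold change, default 4
#'   (fourfold-or-higher rule); must be > 0.
#' @param pseudocount added to numerator and denominator means, default 1
#'   normalized-count unit.
#' @param nonneural_groups optional group names whose means are reported
#'   alongside the call.
#' @param nonneural_ceiling optional: if set, selection additionally
#'   requires all `nonneural_groups` means to be below this ceiling
#'   (default `NULL`, off).
#' @return data.frame, one row per feature, with per-group means, per-tested
#'   group `fc_*` columns, `max_fold_change`, and logical `selected`;
#'   sorted by decreasing `max_fold_change`.
#' @export
select_enriched <- function(means, reference_group = "hESC",
                            tested_groups = c("FB_NE", "MB_NE", "HB_NE"),
                            fold_threshold = 4, pseudocount = 1,
                            nonneural_groups = intersect(c("ME", "HLF"),
                                                         colnames(means)),
                            nonneural_ceiling = NULL) {
  if (fold_threshold <= 0) stop("fold_threshold must be > 0")
  missing <- setdiff(c(reference_group, tested_groups), colnames(means))
  if (length(missing))
    stop("group(s) absent from means: ", paste(missing, collapse = ", "))
  if (pseudocount <= 0 && any(means[, reference_group] <= 0))
    stop("pseudocount must be > 0 when reference means contain zeros")

  ref <- means[, reference_group] + pseudocount
  fc <- sweep(means[, tested_groups, drop = FALSE] + pseudocount, 1, ref, `/`)
  colnames(fc) <- paste0("fc_", tested_groups)
  max_fc <- apply(fc, 1, max)
  selected <- max_fc >= fold_threshold
  if (!is.null(nonneural_ceiling) && length(nonneural_groups))
    selected <- selected &
      apply(means[, nonneural_groups, drop = FALSE] < nonneural_ceiling, 1,
            all)
  out <- data.frame(feature_id = rownames(means),
                    means[, unique(c(reference_group, tested_groups,
                                     nonneural_groups)), drop = FALSE],
                    fc, max_fold_change = max_fc, selected = selected,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(-out$max_fold_change, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNA-family fractions of the total miRNA pool
#'
#' Groups features into miRNA families and reports each family's share of
#' the total pool of normalized counts, per sample group (on group means)
#' or per sample. Fractions within each group sum to 1.
#'
#' @param norm a [normalize_total_counts()] result.
#' @param reference a [mature_reference()], or a named character vector
#'   mapping feature_id to family.
#' @param by `"group"` (default; fractions computed on group-mean profiles)
#'   or `"sample"`.
#' @param groups group labels per sample when `by = "group"`; defaults to
#'   the container metadata.
#' @return family-by-group (or family-by-sample) matrix of fractions.
#' @export
family_fractions <- function(norm, reference, by = c("group", "sample"),
                             groups = NULL) {
  by <- match.arg(by)
  values <- if (by == "group") group_means(norm, groups) else .values(norm)
  fam <- .family_map(reference, rownames(values))
  pooled <- rowsum(values, fam)
  sweep(pooled, 2, colSums(pooled), `/`)
}

#' Unbiased hierarchical clustering of samples
#'
#' Deterministic agglomerative clustering of samples on their expression
#' profiles, as used to ask whether replicates of the same neural subtype
#' group together. Defaults: log2(x + 1) transform, Pearson-correlation
#' distance (1 - r), average linkage.
#'
#' @param x a normalized count matrix, dCq matrix or plain feature-by-sample
#'   matrix; columns are clustered.
#' @param transform `"log2"` (log2(x + 1), default) or `"none"`.
#' @param distance `"pearson"` (1 - correlation, default) or `"euclidean"`.
#' @param linkage agglomeration method for [stats::hclust()], default
#'   `"average"`.
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (the merge tree), `order` (leaf order of
#'   sample names) and, when `k` is given, `labels` (named cluster
#'   assignments from [stats::cutree()]).
#' @export
cluster_samples <- function(x, transform = c("log2", "none"),
                            distance = c("pearson", "euclidean"),
                            linkage = "average", k = NULL) {
  transform <- match.arg(transform)
  distance <- match.arg(distance)
  values <- .values(x)
  if (ncol(values) < 2) stop("need at least 2 samples to cluster")
  if (transform == "log2") values <- log2(values + 1)
  if (anyNA(values)) stop("missing values after transform")
  if (distance == "pearson") {
    sds <- apply(values, 2, stats::sd)
    if (any(sds == 0))
      stop("constant sample(s) make correlation distance undefined: ",
           paste(colnames(values)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(values))
  } else {
    d <- stats::dist(t(values))
  }
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc, order = colnames(values)[hc$order])
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}
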