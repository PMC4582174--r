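#' Normalize panel Cq values to dCq expression values
#'
#' Converts raw quantification cycles to a per-sample-normalized expression
#' scale. With the default policy the normalizer for sample s is the mean
#' Cq over the "common set" — the panel miRNAs detected (non-missing) in
#' every sample — and dCq(m, s) = normalizer(s) - Cq(m, s). Higher dCq
#' therefore means higher expression, and per-sample additive Cq offsets
#' (global efficiency shifts) cancel. The alternative `"global-mean"`
#' policy subtracts Cq from the grand mean over all samples and common-set
#' miRNAs (one shared normalizer), which no longer cancels per-sample
#' offsets. Missing Cq values stay missing.
#'
#' @param cq a [cq_matrix()].
#' @param policy `"detected-in-all"` (default, per-sample mean over the
#'   common set) or `"global-mean"`.
#' @return object of class `dcq_matrix`: list with `values` (dCq matrix),
#'   `normalizer` (description string), `common_set` (miRNA names) and the
#'   sample metadata.
#' @export
normalize_dcq <- function(cq, policy = c("detected-in-all", "global-mean")) {
  policy <- match.arg(policy)
  values <- .values(cq)
  common <- rownames(values)[rowSums(is.na(values)) == 0]
  if (!length(common))
    stop("no miRNA detected in every sample; dCq normalizer undefined")
  norm <- if (policy == "detected-in-all")
    colMeans(values[common, , drop = FALSE])
  else
    rep(mean(values[common, , drop = FALSE]), ncol(values))
  dcq <- sweep(-values, 2, norm, `+`)
  structure(list(values = dcq,
                 normalizer = sprintf(
                   "%s: mean Cq over %d miRNAs detected in all samples",
                   policy, length(common)),
                 common_set = common, sample_meta = .meta(cq)),
            class = "dcq_matrix")
}

#' @export
print.dcq_matrix <- function(x, ...) {
  cat(sprintf("dcq_matrix: %d miRNAs x %d samples\nnormalizer %s\n",
              nrow(x$values), ncol(x$values), x$normalizer))
  invisible(x)
}

#' Select the highest-variance panel miRNAs
#'
#' Ranks panel miRNAs by the standard deviation of their dCq values across
#' samples (missing values ignored) and returns the top k, as used to pick
#' the most regionally/temporally informative assays for clustering.
#'
#' @param dcq a [normalize_dcq()] result.
#' @param k number of miRNAs to return, default 49.
#' @return character vector of k miRNA names, SD descending, ties broken
#'   lexicographically.
#' @export
top_sd_features <- function(dcq, k = 49L) {
  k <- as.integer(k)
  if (k <= 0) stop("k must be a positive integer")
  values <- .values(dcq)
  n_obs <- rowSums(!is.na(values))
  sds <- apply(values, 1, stats::sd, na.rm = TRUE)
  sds[n_obs < 2] <- NA_real_
  if (k > sum(!is.na(sds)))
    stop("k exceeds the number of miRNAs with >= 2 non-missing values")
  ord <- order(-sds, rownames(values), na.last = TRUE)
  rownames(values)[ord][seq_len(k)]
}

#' Per-miRNA one-way ANOVA across sample groups
#'
#' Classical fixed-effects one-way ANOVA of dCq values across groups
#' (typically foetal age groups), run independently for each panel miRNA.
#' miRNAs without at least two groups of at least two non-missing samples
#' are dropped with a warning. When all group means are equal the F ratio
#' is reported as 0 with p = 1.
#'
#' @param dcq a [normalize_dcq()] result.
#' @param groups group label per sample; defaults to the metadata's
#'   `age_group` column.
#' @return data.frame with columns `feature_id`, `f_statistic`, `p_value`.
#' @export
age_group_anova <- function(dcq, groups = NULL) {
  values <- .values(dcq)
  if (is.null(groups)) {
    meta <- .meta(dcq)
    if (is.null(meta) || is.null(meta$age_group))
      stop("no age_group metadata; supply groups explicitly")
    groups <- meta$age_group
  }
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  res <- lapply(rownames(values), function(m) {
    y <- values[m, ]
    ok <- !is.na(y)
    g <- factor(groups[ok])
    y <- y[ok]
    sizes <- table(g)
    if (sum(sizes >= 2) < 2) return(NULL)
    keep <- g %in% names(sizes)[sizes >= 2]
    g <- droplevels(g[keep]); y <- y[keep]
    gm <- tapply(y, g, mean)
    if (max(gm) - min(gm) == 0)
      return(data.frame(feature_id = m, f_statistic = 0, p_value = 1))
    fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
    data.frame(feature_id = m,
               f_statistic = unname(fit$statistic),
               p_value = fit$p.value)
  })
  dropped <- rownames(values)[vapply(res, is.null, logical(1))]
  if (length(dropped))
    warning("dropped (insufficient replication): ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Centred per-group mean dCq profiles
#'
#' For each miRNA: the mean dCq per group, centred by subtracting the mean
#' of the group means, so each miRNA's profile sums to zero across groups
#' and shows its relative pattern over regions or ages.
#'
#' @param dcq a [normalize_dcq()] result.
#' @param groups group labels per sample (e.g. age groups or regions);
#'   defaults to the metadata's `age_group`.
#' @return miRNA-by-group matrix of centred mean dCq; rows sum to 0.
#' @export
centred_profiles <- function(dcq, groups = NULL) {
  values <- .values(dcq)
  if (is.null(groups)) {
    meta <- .meta(dcq)
    if (is.null(meta) || is.null(meta$age_group))
      stop("no age_group metadata; supply groups explicitly")
    groups <- meta$age_group
  }
  if (length(groups) != ncol(values) || anyNA(groups))
    stop("grouping must be defined for all samples")
  glev <- unique(groups)
  gm <- vapply(glev, function(g)
    rowMeans(values[, groups == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(values)))
  if (is.null(dim(gm)))
    gm <- matrix(gm, nrow = nrow(values),
                 dimnames = list(rownames(values), glev))
  gm - rowMeans(gm)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Standard qPCR relative quantification against a housekeeping gene
#' (e.g. ACTB). Technical-replicate Ct values are averaged per condition
#' first; then dCt = Ct_target - Ct_housekeeping, ddCt = dCt_condition -
#' dCt_reference, and the relative quantity RQ = 2^(-ddCt). The reference
#' condition has ddCt = 0 and RQ = 1 by construction. For assays normalized
#' to several reference miRNAs instead of one housekeeping gene, pass the
#' mean Ct of the normalizer assays as `ct_housekeeping`.
#'
#' @param ct_table data.frame with columns `condition`, `replicate`,
#'   `ct_target`, `ct_housekeeping` (one row per technical replicate).
#' @param reference_condition condition used as calibrator.
#' @return data.frame, one row per condition: `delta_ct`, `delta_delta_ct`,
#'   `relative_quantity`, and `sd_delta_ct` (dispersion of per-replicate
#'   dCt values; NA with a single replicate).
#' @export
ddct <- function(ct_table, reference_condition) {
  for (col in c("condition", "replicate", "ct_target", "ct_housekeeping"))
    if (!col %in% names(ct_table))
      stop("ct_table lacks column '", col, "'")
  if (anyNA(ct_table$ct_housekeeping))
    stop("missing housekeeping Ct values")
  if (!reference_condition %in% ct_table$condition)
    stop("reference condition '", reference_condition, "' absent")
  conds <- unique(ct_table$condition)
  per <- lapply(conds, function(co) {
    rows <- ct_table[ct_table$condition == co, ]
    dct_rep <- rows$ct_target - rows$ct_housekeeping
    data.frame(condition = co,
               delta_ct = mean(rows$ct_target) - mean(rows$ct_housekeeping),
               sd_delta_ct = if (nrow(rows) > 1) stats::sd(dct_rep) else NA_real_)
  })
  out <- do.call(rbind, per)
  ref_dct <- out$delta_ct[out$condition == reference_condition]
  out$delta_delta_ct <- out$delta_ct - ref_dct
  out$relative_quantity <- 2^(-out$delta_delta_ct)
  out[, c("condition", "delta_ct", "delta_delta_ct", "relative_quantity",
          "sd_delta_ct")]
}

#' Presence/absence calls from Cq values
#'
#' An assay is called detected when its Cq is present and at most
#' `max_cq` cycles; missing Cq values are not detected.
#'
#' @param cq a [cq_matrix()].
#' @param max_cq detection threshold in cycles, default 37; must lie in
#'   (0, 50).
#' @return logical miRNA-by-sample matrix of detected calls.
#' @export
detection_call <- function(cq, max_cq = 37) {
  if (max_cq <= 0 || max_cq >= 50) stop("max_cq must lie in (0, 50)")
  values <- .values(cq)
  det <- !is.na(values) & values <= max_cq
  det
}
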