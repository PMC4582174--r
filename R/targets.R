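#' Scale mRNA counts to equal library totals
#'
#' Total-count scaling of the gene expression matrix, the same contract as
#' [normalize_total_counts()] applied to mRNA-seq data before fold-change
#' computation.
#'
#' @inheritParams normalize_total_counts
#' @param expr an [expression_matrix()] (or plain matrix).
#' @return a `normalized_matrix` (see [normalize_total_counts()]).
#' @export
scale_normalize <- function(expr, target_total = "median") {
  normalize_total_counts(expr, target_total)
}

#' Expressed-gene background from control samples
#'
#' Genes with mean raw read count strictly above `min_reads` in the control
#' (no doxycycline) samples form the expressed universe used for target
#' statistics: a gene with mean exactly `min_reads` is excluded.
#'
#' @param expr an [expression_matrix()] of raw counts.
#' @param min_reads strict lower bound on the mean control count, default 10.
#' @param arm optional arm label to restrict which control samples are used;
#'   default all `no_dox` samples.
#' @return character vector of expressed gene ids.
#' @export
expressed_background <- function(expr, min_reads = 10, arm = NULL) {
  meta <- .meta(expr)
  if (is.null(meta) || is.null(meta$condition))
    stop("expr must carry condition metadata")
  keep <- meta$condition == "no_dox"
  if (!is.null(arm)) keep <- keep & meta$arm == arm
  if (!any(keep)) stop("no control (no_dox) samples found")
  ctrl <- .values(expr)[, keep, drop = FALSE]
  rownames(ctrl)[rowMeans(ctrl) > min_reads]
}

#' Per-gene fold changes after miRNA overexpression
#'
#' For one overexpression arm: the ratio of mean scaled expression under
#' doxycycline induction to the no-doxycycline control mean, computed on
#' replicate means with a pseudocount so all fold changes are positive and
#' finite.
#'
#' @param scaled a [scale_normalize()] result carrying arm/condition
#'   metadata.
#' @param arm arm label to analyse (e.g. `"miR10a"`).
#' @param pseudocount added to both condition means, default 1 scaled-count
#'   unit; must be > 0 if any control mean is zero.
#' @return data.frame with columns `gene_id`, `mean_control`,
#'   `mean_treated`, `fold_change`, `log2_fc`.
#' @export
fold_changes <- function(scaled, arm, pseudocount = 1) {
  meta <- .meta(scaled)
  if (is.null(meta) || is.null(meta$condition) || is.null(meta$arm))
    stop("scaled matrix must carry arm/condition metadata")
  values <- .values(scaled)
  dox <- meta$arm == arm & meta$condition == "dox"
  ctl <- meta$arm == arm & meta$condition == "no_dox"
  if (!any(dox) || !any(ctl))
    stop("arm '", arm, "' needs both dox and no_dox samples")
  m_t <- rowMeans(values[, dox, drop = FALSE])
  m_c <- rowMeans(values[, ctl, drop = FALSE])
  if (pseudocount <= 0 && any(m_c == 0))
    stop("pseudocount must be > 0 when control means contain zeros")
  fc <- (m_t + pseudocount) / (m_c + pseudocount)
  data.frame(gene_id = rownames(values), mean_control = m_c,
             mean_treated = m_t, fold_change = fc, log2_fc = log2(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative fraction curve of fold changes
#'
#' Sorted values with their cumulative fractions (the empirical CDF
#' evaluated at the data points), as plotted in cumulative fraction graphs
#' of log2 fold changes.
#'
#' @param values numeric vector (non-empty).
#' @return data.frame with columns `value` (sorted ascending) and
#'   `fraction` (ending at 1).
#' @export
cumulative_fraction <- function(values) {
  if (!length(values) || anyNA(values))
    stop("values must be non-empty and non-missing")
  v <- sort(values)
  data.frame(value = v, fraction = seq_along(v) / length(v))
}

#' Test for a CDF shift of predicted targets versus background
#'
#' Two-sample Kolmogorov-Smirnov test comparing the log2 fold-change
#' distribution of predicted target genes against the non-target expressed
#' background ("all other genes"). A left shift (targets' median log2 FC
#' below the background's) indicates that the miRNA represses its
#' predicted targets. The exact small-sample distribution of D is used when
#' both sets have at most 25 genes; otherwise the asymptotic Kolmogorov
#' approximation.
#'
#' @param fc a [fold_changes()] table.
#' @param targets character vector of predicted target gene ids.
#' @param background character vector of background gene ids; must be
#'   disjoint from `targets`.
#' @return list with `D`, `p_value`, `direction` (`"left"` or `"right"`),
#'   `n_targets`, `n_background`, and `cdf_targets` / `cdf_background`
#'   curves from [cumulative_fraction()].
#' @export
cdf_shift_test <- function(fc, targets, background) {
  if (length(intersect(targets, background)))
    stop("targets and background overlap")
  if (!length(targets) || !length(background))
    stop("both gene sets must be non-empty")
  missing <- setdiff(c(targets, background), fc$gene_id)
  if (length(missing))
    stop("gene(s) absent from fold-change table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  lfc <- stats::setNames(fc$log2_fc, fc$gene_id)
  x <- unname(lfc[targets])
  y <- unname(lfc[background])
  exact <- length(x) <= 25 && length(y) <= 25
  ks <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(ks$statistic),
       p_value = ks$p.value,
       direction = if (stats::median(x) < stats::median(y)) "left" else "right",
       n_targets = length(x),
       n_background = length(y),
       cdf_targets = cumulative_fraction(x),
       cdf_background = cumulative_fraction(y))
}

#' High-confidence targets downregulated in both overexpression arms
#'
#' A gene is called a high-confidence target when it is a predicted target,
#' lies in the expressed background, and has fold change below
#' `down_threshold` in both overexpression arms.
#'
#' @param fc_a,fc_b [fold_changes()] tables for the two arms.
#' @param targets character vector of predicted target gene ids.
#' @param down_threshold fold-change cutoff defining "downregulated",
#'   default 1 (any decrease).
#' @param expressed optional character vector restricting to expressed
#'   genes; default the genes present in both fold-change tables.
#' @return character vector of gene ids sorted by mean log2 fold change
#'   ascending (strongest repression first).
#' @export
high_confidence_targets <- function(fc_a, fc_b, targets, down_threshold = 1,
                                    expressed = NULL) {
  universe <- intersect(fc_a$gene_id, fc_b$gene_id)
  if (!is.null(expressed)) universe <- intersect(universe, expressed)
  cand <- intersect(targets, universe)
  if (!length(cand)) return(character(0))
  fca <- stats::setNames(fc_a$fold_change, fc_a$gene_id)[cand]
  fcb <- stats::setNames(fc_b$fold_change, fc_b$gene_id)[cand]
  hit <- fca < down_threshold & fcb < down_threshold
  genes <- cand[hit]
  mean_lfc <- (log2(fca[hit]) + log2(fcb[hit])) / 2
  genes[order(mean_lfc, genes)]
}

#' Read a predicted-target table
#'
#' Two-column TSV distilled from TargetScan-style downloads: `gene_id` and
#' `mirna_family` (an optional `site_type` column is retained when
#' present). Duplicate (gene, family) pairs are collapsed.
#'
#' @param path TSV path.
#' @return data.frame with unique (gene_id, mirna_family) rows.
#' @export
read_target_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("gene_id", "mirna_family"))
    if (!col %in% names(tab))
      stop("target table lacks column '", col, "'")
  tab[!duplicated(tab[, c("gene_id", "mirna_family")]), , drop = FALSE]
}

#' Full miRNA target inference from an overexpression experiment
#'
#' Runs the whole inference chain on a paired overexpression/control
#' expression matrix: total-count scaling, expressed-background
#' construction from the control samples, per-arm fold changes, per-arm
#' CDF-shift (Kolmogorov-Smirnov) tests of predicted targets against all
#' other expressed genes, and intersection of the per-arm downregulated
#' target lists into the high-confidence set.
#'
#' @param expr an [expression_matrix()] of raw counts with two arms.
#' @param target_table data.frame from [read_target_table()], or a
#'   character vector of predicted target gene ids.
#' @param family miRNA family selecting rows of `target_table` (ignored
#'   when `target_table` is already a gene vector).
#' @param arms the two arm labels; default the arms found in the metadata.
#' @param min_reads expressed-background rule, see [expressed_background()].
#' @param pseudocount see [fold_changes()].
#' @param down_threshold see [high_confidence_targets()].
#' @return object of class `target_call`: list with per-arm `fold_changes`
#'   and `tests`, the `expressed` universe, `targets_expressed`,
#'   `down_per_arm` lists and the `high_confidence` gene vector.
#' @export
infer_targets <- function(expr, target_table, family = NULL, arms = NULL,
                          min_reads = 10, pseudocount = 1,
                          down_threshold = 1) {
  meta <- .meta(expr)
  if (is.null(arms)) arms <- unique(meta$arm)
  if (length(arms) != 2) stop("need exactly two overexpression arms")
  targets <- if (is.character(target_table)) {
    target_table
  } else {
    if (is.null(family)) stop("family required with a target table")
    unique(target_table$gene_id[target_table$mirna_family == family])
  }
  expressed <- expressed_background(expr, min_reads = min_reads)
  scaled <- scale_normalize(expr)
  tset <- intersect(targets, expressed)
  bg <- setdiff(expressed, targets)
  fc <- lapply(arms, function(a) fold_changes(scaled, a, pseudocount))
  names(fc) <- arms
  tests <- lapply(fc, cdf_shift_test, targets = tset, background = bg)
  down <- lapply(fc, function(tab) {
    f <- stats::setNames(tab$fold_change, tab$gene_id)[tset]
    tset[f < down_threshold]
  })
  hc <- high_confidence_targets(fc[[1]], fc[[2]], tset, down_threshold,
                                expressed = expressed)
  structure(list(arms = arms, fold_changes = fc, tests = tests,
                 expressed = expressed, targets_expressed = tset,
                 down_per_arm = down, high_confidence = hc,
                 down_threshold = down_threshold),
            class = "target_call")
}

#' @export
print.target_call <- function(x, ...) {
  cat("miRNA target inference by fold-change CDF shift\n")
  cat(sprintf("expressed genes: %d; predicted targets expressed: %d\n",
              length(x$expressed), length(x$targets_expressed)))
  for (a in x$arms) {
    t <- x$tests[[a]]
    cat(sprintf(
      "  %s: KS D = %.3f, p = %.3g, shift %s; %d/%d targets down (FC < %g)\n",
      a, t$D, t$p_value, t$direction, length(x$down_per_arm[[a]]),
      length(x$targets_expressed), x$down_threshold))
  }
  cat(sprintf("high-confidence targets (down in both arms): %d\n",
              length(x$high_confidence)))
  invisible(x)
}

#' Plot cumulative fold-change distributions of targets versus background
#'
#' Base-graphics cumulative fraction plot per arm: predicted targets versus
#' all other expressed genes, on the log2 fold-change axis.
#'
#' @param x a `target_call` from [infer_targets()].
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.target_call <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$arms)))
  on.exit(graphics::par(old))
  for (a in x$arms) {
    t <- x$tests[[a]]
    plot(t$cdf_background$value, t$cdf_background$fraction, type = "s",
         xlab = "log2 fold change", ylab = "cumulative fraction",
         main = a, ...)
    graphics::lines(t$cdf_targets$value, t$cdf_targets$fraction, type = "s",
                    col = "red", lty = 2)
    graphics::legend("topleft", c("background", "targets"),
                     col = c("black", "red"), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
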