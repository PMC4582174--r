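#' Simulate grouped miRNA count matrices with known ground truth
#'
#' Generates a feature-by-sample count matrix emulating small-RNA profiles
#' of embryonic stem cells and regionalized neural progenitors. Baseline
#' feature abundances are log-normal; per group, two kinds of structure can
#' be seeded exactly on the proportion scale:
#'
#' * `enriched`: a feature set whose proportions in the listed groups are a
#'   fixed fold change above their reference-group (hESC) proportions;
#' * `families`: miRNA families pinned to target shares of the total miRNA
#'   pool in specific groups (e.g. the miR-10 family at 35% of the pool in
#'   hindbrain neuroepithelial cells).
#'
#' Remaining features are rescaled proportionally so each group's
#' proportions sum to 1. Counts are drawn negative-binomially around
#' `proportion * reads_per_sample` with the given dispersion; dispersion 0
#' gives deterministic counts (largest-remainder rounding to the exact
#' total), the noise-free limit.
#'
#' @param n_features number of miRNA features, default 200.
#' @param groups named integer vector: replicates per group; default the
#'   eight-group design (hESC, mesendoderm ME, lung fibroblast HLF,
#'   FB/MB/HB neuroepithelium, MB/HB floor plate) with 2-4 replicates.
#' @param reads_per_sample total reads per sample, default 20000.
#' @param dispersion negative-binomial dispersion (variance = mu + disp *
#'   mu^2), default 0.1; 0 means noise-free.
#' @param families named list; each element
#'   `list(members = feature ids, proportions = named numeric)` pins that
#'   family's pool share per group (groups not named keep baseline shares).
#' @param enriched `NULL` or `list(features, fc, groups)`: features whose
#'   proportions in `groups` equal `fc` times their reference proportions.
#' @param reference_group group defining the enrichment baseline, default
#'   `"hESC"`.
#' @param baseline_sdlog log-normal sd of baseline feature weights,
#'   default 1.
#' @param seed RNG seed.
#' @return list with `counts` (a [count_matrix()]) and `truth`: the
#'   feature-by-group `proportions` actually used, a `family` vector per
#'   feature (unassigned features form singleton families), the `enriched`
#'   feature ids and their realized fold changes vs the reference.
#' @export
simulate_mirna_counts <- function(n_features = 200,
                                  groups = c(hESC = 3, ME = 2, HLF = 2,
                                             FB_NE = 3, MB_NE = 3, HB_NE = 3,
                                             MB_FP = 2, HB_FP = 4),
                                  reads_per_sample = 20000,
                                  dispersion = 0.1,
                                  families = NULL,
                                  enriched = NULL,
                                  reference_group = "hESC",
                                  baseline_sdlog = 1,
                                  seed = NULL) {
  if (any(groups < 2)) stop("every group needs >= 2 replicates")
  if (!reference_group %in% names(groups))
    stop("reference_group absent from groups")
  if (!is.null(seed)) set.seed(seed)
  feat <- sprintf("miR-sim-%03d", seq_len(n_features))

  w <- stats::rlnorm(n_features, meanlog = 0, sdlog = baseline_sdlog)
  p_ref <- stats::setNames(w / sum(w), feat)

  pin <- function(p, members, target) {
    # fix sum(p[members]) = target, rescale the rest to 1 - target
    if (target < 0 || target >= 1) stop("infeasible proportion target")
    inside <- sum(p[members])
    if (inside <= 0) stop("pinned members have zero baseline weight")
    p[members] <- target * p[members] / inside
    rest <- setdiff(names(p), members)
    p[rest] <- (1 - target) * p[rest] / sum(p[rest])
    p
  }

  props <- sapply(names(groups), function(g) {
    p <- p_ref
    if (!is.null(enriched) && g %in% enriched$groups) {
      e <- enriched$features
      mass <- sum(enriched$fc * p_ref[e])
      if (mass >= 1) stop("infeasible enrichment: fold changes exceed pool")
      p[e] <- enriched$fc * p_ref[e]
      rest <- setdiff(feat, e)
      p[rest] <- (1 - mass) * p_ref[rest] / sum(p_ref[rest])
    }
    if (!is.null(families)) {
      for (fam in names(families)) {
        tgt <- families[[fam]]$proportions
        if (g %in% names(tgt))
          p <- pin(p, families[[fam]]$members, tgt[[g]])
      }
    }
    p
  })
  rownames(props) <- feat

  meta <- data.frame(
    sample_id = unlist(lapply(names(groups), function(g)
      paste0(g, "_", seq_len(groups[[g]])))),
    group = rep(names(groups), groups),
    replicate = unlist(lapply(groups, seq_len)),
    row.names = NULL, stringsAsFactors = FALSE)

  draw <- function(p) {
    mu <- p * reads_per_sample
    if (dispersion == 0) .round_to_total(mu, reads_per_sample)
    else as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
  }
  values <- vapply(seq_len(nrow(meta)),
                   function(i) draw(props[, meta$group[i]]),
                   integer(n_features))
  dimnames(values) <- list(feat, meta$sample_id)

  family <- stats::setNames(feat, feat)  # singleton families by default
  if (!is.null(families))
    for (fam in names(families)) family[families[[fam]]$members] <- fam

  truth <- list(proportions = props, family = family,
                enriched = if (is.null(enriched)) character(0)
                           else enriched$features,
                realized_fc = if (is.null(enriched)) NULL else
                  props[enriched$features, , drop = FALSE] /
                  props[enriched$features, reference_group],
                reference_group = reference_group)
  list(counts = count_matrix(values, meta), truth = truth)
}

# Largest-remainder rounding of non-negative expectations to an integer
# vector with an exact total.
.round_to_total <- function(mu, total) {
  base <- floor(mu)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    extra <- order(mu - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate adapter-contaminated small-RNA reads
#'
#' Draws reads multinomially from known feature abundances; each read is
#' the mature sequence followed by the 3' adapter, truncated at the read
#' length — exactly the structure the trimming/counting pipeline is meant
#' to invert. Ground-truth tallies are returned.
#'
#' @param reference a [mature_reference()].
#' @param abundances named numeric vector over `reference$feature_id`,
#'   summing to 1.
#' @param adapter adapter sequence appended 3' of each insert.
#' @param n_reads number of reads.
#' @param read_length instrument read length (reads are truncated here),
#'   default 50.
#' @param seed RNG seed.
#' @return list with `reads` (a [read_batch()]) and `tallies` (named
#'   integer vector of true per-feature read counts, summing to `n_reads`).
#' @export
simulate_reads <- function(reference, abundances, adapter, n_reads,
                           read_length = 50L, seed = NULL) {
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  if (!all(names(abundances) %in% reference$feature_id))
    stop("abundances must be named by reference feature_id")
  if (!is.null(seed)) set.seed(seed)
  tallies <- stats::setNames(
    as.integer(stats::rmultinom(1, n_reads, abundances)), names(abundances))
  seqs <- reference$sequence[match(names(abundances), reference$feature_id)]
  full <- substr(paste0(seqs, strrep(adapter,
                                     ceiling(read_length / nchar(adapter)) + 1)),
                 1L, read_length)
  sequence <- sample(rep(full, tallies))
  reads <- read_batch(read_id = sprintf("read_%06d", seq_len(n_reads)),
                      sequence = sequence)
  list(reads = reads, tallies = tallies)
}

#' Simulate a targeted qPCR Cq matrix over brain regions and foetal ages
#'
#' Emulates a custom miRNA panel run on sub-dissected neural-tube regions
#' across age groups: per-assay Cq values around a shared baseline, with
#' additive expression effects (an effect of e cycles lowers Cq by e, i.e.
#' raises expression 2^e-fold), Gaussian cycle noise, and optional
#' region-restricted assays emitted as missing (or as a high Cq) outside
#' their detected regions.
#'
#' @param panel character vector of panel miRNA names; default a synthetic
#'   59-assay panel.
#' @param regions rostro-caudal regions, default the seven-region
#'   vocabulary FB, vMB, dMB, vHB, dHB, pHB, SC.
#' @param age_groups named numeric vector mapping age-group label to
#'   representative age (weeks post-conception); default
#'   `c(early = 5, mid = 7.5, late = 10)`.
#' @param samples_per_cell foetal samples per region-by-age cell, default 1.
#' @param baseline_cq baseline Cq in cycles, default 27.
#' @param effects optional data.frame with columns `mirna`, `effect` and
#'   any of `region`, `age_group` (NA or absent = applies to all); effects
#'   are summed where several rows match.
#' @param absent optional data.frame with columns `mirna`, `region`: those
#'   assay-region pairs are not detected.
#' @param absent_as `"missing"` (default, NA) or `"high_cq"` (Cq 39, above
#'   the default detection threshold).
#' @param noise_sd Gaussian Cq noise in cycles, default 0.5.
#' @param seed RNG seed.
#' @return list with `cq` (a [cq_matrix()]) and `truth` (`effects`,
#'   `absent`).
#' @export
simulate_cq <- function(panel = sprintf("hsa-miR-sim-%02d", 1:59),
                        regions = c("FB", "vMB", "dMB", "vHB", "dHB", "pHB",
                                    "SC"),
                        age_groups = c(early = 5, mid = 7.5, late = 10),
                        samples_per_cell = 1,
                        baseline_cq = 27,
                        effects = NULL, absent = NULL,
                        absent_as = c("missing", "high_cq"),
                        noise_sd = 0.5, seed = NULL) {
  absent_as <- match.arg(absent_as)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(rep = seq_len(samples_per_cell),
                      region = regions, age_group = names(age_groups),
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_%d", grid$region, grid$age_group, grid$rep),
    region = grid$region,
    age_weeks_pc = unname(age_groups[grid$age_group]),
    age_group = grid$age_group, stringsAsFactors = FALSE)

  values <- matrix(baseline_cq, nrow = length(panel), ncol = nrow(meta),
                   dimnames = list(panel, meta$sample_id))
  if (!is.null(effects)) {
    if (!all(effects$mirna %in% panel))
      stop("effects reference miRNAs outside the panel")
    for (i in seq_len(nrow(effects))) {
      cols <- rep(TRUE, nrow(meta))
      if ("region" %in% names(effects) && !is.na(effects$region[i]))
        cols <- cols & meta$region == effects$region[i]
      if ("age_group" %in% names(effects) && !is.na(effects$age_group[i]))
        cols <- cols & meta$age_group == effects$age_group[i]
      values[effects$mirna[i], cols] <-
        values[effects$mirna[i], cols] - effects$effect[i]
    }
  }
  if (noise_sd > 0)
    values <- values + matrix(stats::rnorm(length(values), 0, noise_sd),
                              nrow = nrow(values))
  values <- pmin(pmax(values, 1), 49)
  if (!is.null(absent)) {
    for (i in seq_len(nrow(absent))) {
      cols <- meta$region == absent$region[i]
      values[absent$mirna[i], cols] <-
        if (absent_as == "missing") NA_real_ else 39
    }
  }
  list(cq = cq_matrix(values, meta, regions = regions),
       truth = list(effects = effects, absent = absent))
}

#' Simulate a paired overexpression/control mRNA count experiment
#'
#' Emulates the doxycycline-inducible miRNA overexpression design: two
#' construct arms, each with induced (dox) and control (no_dox) conditions
#' and three replicates. Baseline gene means are log-normal; in the dox
#' condition of each arm, true-target means are multiplied by 2^shift
#' (shift <= 0 models repression) while decoys — predicted targets with no
#' true effect — and background genes are unshifted. Counts are
#' negative-binomial; dispersion 0 gives the deterministic noise-free
#' limit.
#'
#' @param n_genes total genes, default 12000.
#' @param n_targets true targets, default 90.
#' @param n_decoys decoy predicted targets (no effect), default 90.
#' @param shift_a,shift_b log2 repression of true targets in each arm,
#'   default -0.6; must be <= 0.
#' @param dispersion NB dispersion, default 0.05.
#' @param replicates per arm-by-condition group, default 3.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline mean counts (natural-log scale), defaults 4 and 1.5 — a
#'   realistic expressed/unexpressed split around a 10-read floor.
#' @param arms arm labels, default `c("miR10a", "miR10b")`.
#' @param seed RNG seed.
#' @return list with `expr` (an [expression_matrix()] of raw counts) and
#'   `truth` (`targets`, `decoys`, `predicted` = their union, per-arm
#'   `shifts`, `baseline_mu`).
#' @export
simulate_mrna_overexpression <- function(n_genes = 12000, n_targets = 90,
                                         n_decoys = 90, shift_a = -0.6,
                                         shift_b = -0.6, dispersion = 0.05,
                                         replicates = 3,
                                         baseline_meanlog = 4,
                                         baseline_sdlog = 1.5,
                                         arms = c("miR10a", "miR10b"),
                                         seed = NULL) {
  if (shift_a > 0 || shift_b > 0) stop("repression shifts must be <= 0")
  if (n_targets + n_decoys > n_genes) stop("too many targets/decoys")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  mu <- stats::setNames(stats::rlnorm(n_genes, baseline_meanlog,
                                      baseline_sdlog), genes)
  picked <- sample(genes, n_targets + n_decoys)
  targets <- sort(picked[seq_len(n_targets)])
  decoys <- sort(picked[n_targets + seq_len(n_decoys)])
  shifts <- stats::setNames(c(shift_a, shift_b), arms)

  meta <- expand.grid(replicate = seq_len(replicates),
                      condition = c("dox", "no_dox"), arm = arms,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_%d", meta$arm, meta$condition,
                            meta$replicate)
  meta <- meta[, c("sample_id", "arm", "condition", "replicate")]

  values <- vapply(seq_len(nrow(meta)), function(i) {
    m <- mu
    if (meta$condition[i] == "dox")
      m[targets] <- m[targets] * 2^shifts[[meta$arm[i]]]
    if (dispersion == 0) as.integer(round(m))
    else as.integer(stats::rnbinom(n_genes, mu = m, size = 1 / dispersion))
  }, integer(n_genes))
  dimnames(values) <- list(genes, meta$sample_id)

  list(expr = expression_matrix(values, meta),
       truth = list(targets = targets, decoys = decoys,
                    predicted = sort(c(targets, decoys)),
                    shifts = shifts, baseline_mu = mu))
}
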