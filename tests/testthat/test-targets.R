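test_that("expressed_background applies the strict >10 mean-count rule", {
  v <- rbind(at_bound = c(10, 10, 10), above = c(10, 10, 11.5),
             zero = c(0, 0, 0), high = c(100, 90, 110))
  v <- cbind(v, dox = c(1e4, 1e4, 1e4, 1e4))
  colnames(v) <- c("c1", "c2", "c3", "d1")
  meta <- data.frame(sample_id = colnames(v), arm = "miR10a",
                     condition = c("no_dox", "no_dox", "no_dox", "dox"),
                     replicate = c(1:3, 1))
  expr <- expression_matrix(v, meta)
  bg <- expressed_background(expr)
  expect_identical(sort(bg), c("above", "high"))
  # mean exactly 10 is excluded, mean 10.5 included
  expect_false("at_bound" %in% bg)
  # random matrix equals the elementwise threshold oracle
  set.seed(51)
  r <- matrix(rpois(600, 12), 200, 3,
              dimnames = list(sprintf("g%03d", 1:200), c("c1", "c2", "c3")))
  r <- cbind(r, d1 = rpois(200, 12))
  expr2 <- expression_matrix(r, meta)
  expect_identical(expressed_background(expr2),
                   rownames(r)[rowMeans(r[, 1:3]) > 10])
})

test_that("fold_changes uses replicate means of scaled counts with pseudocount", {
  v <- rbind(g1 = c(50, 50, 25, 25), g2 = c(30, 30, 30, 30))
  colnames(v) <- c("c1", "c2", "d1", "d2")
  meta <- data.frame(sample_id = colnames(v), arm = "miR10a",
                     condition = c("no_dox", "no_dox", "dox", "dox"),
                     replicate = c(1, 2, 1, 2))
  expr <- structure(list(values = v, sample_meta = meta),
                    class = "expression_matrix")
  fc <- fold_changes(expr, "miR10a", pseudocount = 0)
  expect_equal(fc$fold_change[fc$gene_id == "g1"], 0.5)
  expect_equal(fc$log2_fc[fc$gene_id == "g1"], -1)
  expect_equal(fc$fold_change[fc$gene_id == "g2"], 1)
  expect_error(fold_changes(expr, "miR10b"), "miR10b")
  # identical conditions give FC 1 everywhere
  v1 <- v; v1[, 3:4] <- v1[, 1:2]
  expr1 <- structure(list(values = v1, sample_meta = meta),
                     class = "expression_matrix")
  expect_equal(fold_changes(expr1, "miR10a")$fold_change, c(1, 1))
  # zero control mean without pseudocount is rejected
  v0 <- v; v0["g2", 1:2] <- 0
  expr0 <- structure(list(values = v0, sample_meta = meta),
                     class = "expression_matrix")
  expect_error(fold_changes(expr0, "miR10a", pseudocount = 0), "pseudocount")
})

test_that("seeded repression is recovered by the fold-change estimator", {
  # targets are a small fraction of the library so total-count scaling
  # does not visibly compress the seeded shift
  sim <- simulate_mrna_overexpression(n_genes = 4000, n_targets = 60,
                                      n_decoys = 0, shift_a = -1,
                                      shift_b = -1, dispersion = 0.05,
                                      baseline_meanlog = log(500),
                                      baseline_sdlog = 0.2, seed = 52)
  scaled <- scale_normalize(sim$expr)
  fc <- fold_changes(scaled, "miR10a")
  lfc <- fc$log2_fc[fc$gene_id %in% sim$truth$targets]
  expect_equal(mean(lfc), -1, tolerance = 0.1)
})

test_that("cumulative_fraction matches the sort-and-rank oracle", {
  cf <- cumulative_fraction(c(1, -1, 0))
  expect_equal(cf$value, c(-1, 0, 1))
  expect_equal(cf$fraction, c(1, 2, 3) / 3)
  cf1 <- cumulative_fraction(2.5)
  expect_equal(cf1$value, 2.5)
  expect_equal(cf1$fraction, 1)
  set.seed(53)
  x <- rnorm(100)
  cf2 <- cumulative_fraction(x)
  expect_equal(cf2$value, sort(x))
  expect_equal(cf2$fraction, rank(sort(x), ties.method = "max") / 100)
  expect_error(cumulative_fraction(numeric(0)), "non-empty")
})

make_fc_table <- function(lfc) {
  data.frame(gene_id = names(lfc), mean_control = 100, mean_treated = 100,
             fold_change = 2^lfc, log2_fc = unname(lfc),
             stringsAsFactors = FALSE)
}

test_that("cdf_shift_test equals the brute-force ECDF-gap oracle", {
  set.seed(54)
  # tiny 3 vs 3 case with the exhaustive oracle
  lfc <- stats::setNames(c(-1.2, -0.4, 0.1, 0.3, -0.2, 0.8),
                         sprintf("g%d", 1:6))
  res <- cdf_shift_test(make_fc_table(lfc), sprintf("g%d", 1:3),
                        sprintf("g%d", 4:6))
  expect_equal(res$D, ks_d_oracle(lfc[1:3], lfc[4:6]))
  # random instances up to 200 genes
  for (i in 1:20) {
    nt <- sample(3:80, 1); nb <- sample(3:120, 1)
    vals <- stats::setNames(rnorm(nt + nb), sprintf("r%03d", seq_len(nt + nb)))
    res_i <- cdf_shift_test(make_fc_table(vals),
                            names(vals)[1:nt], names(vals)[-(1:nt)])
    expect_equal(res_i$D, ks_d_oracle(vals[1:nt], vals[-(1:nt)]))
  }
  # identical empirical distributions give D = 0
  same <- stats::setNames(rep(c(-0.5, 0, 0.5), 2), sprintf("s%d", 1:6))
  res0 <- cdf_shift_test(make_fc_table(same), sprintf("s%d", 1:3),
                         sprintf("s%d", 4:6))
  expect_equal(res0$D, 0)
  expect_error(cdf_shift_test(make_fc_table(same), sprintf("s%d", 1:3),
                              sprintf("s%d", 3:6)), "overlap")
})

test_that("cdf_shift_test is invariant under common monotone transforms", {
  set.seed(55)
  vals <- stats::setNames(rnorm(150, sd = 0.5), sprintf("g%03d", 1:150))
  t_ids <- names(vals)[1:40]; b_ids <- names(vals)[-(1:40)]
  res_raw <- cdf_shift_test(make_fc_table(vals), t_ids, b_ids)
  mono <- exp(3 * vals) - 1  # strictly increasing transform
  res_mono <- cdf_shift_test(make_fc_table(mono / log(2)) , t_ids, b_ids)
  # D depends only on ranks
  expect_equal(res_mono$D, res_raw$D)
  expect_equal(res_mono$p_value, res_raw$p_value)
})

test_that("left-shifted targets are detected with direction", {
  set.seed(56)
  vals <- stats::setNames(c(rnorm(100, -0.5, 0.5), rnorm(1000, 0, 0.5)),
                          sprintf("g%04d", 1:1100))
  res <- cdf_shift_test(make_fc_table(vals), names(vals)[1:100],
                        names(vals)[-(1:100)])
  expect_lt(res$p_value, 1e-4)
  expect_identical(res$direction, "left")
  expect_identical(res$n_targets + res$n_background, 1100L)
})

test_that("high_confidence_targets requires downregulation in both arms", {
  fc_a <- make_fc_table(c(gA = log2(0.7), gB = log2(0.7), gC = log2(1.2)))
  fc_b <- make_fc_table(c(gA = log2(0.8), gB = log2(1.1), gC = log2(0.5)))
  hc <- high_confidence_targets(fc_a, fc_b, c("gA", "gB", "gC"))
  expect_identical(hc, "gA")
  expect_identical(high_confidence_targets(fc_a, fc_b, character(0)),
                   character(0))
  # non-target genes are never called
  expect_identical(high_confidence_targets(fc_a, fc_b, "gZ"), character(0))
  # monotone in the threshold: lowering it never adds genes
  set.seed(57)
  lfc_a <- stats::setNames(rnorm(100, 0, 0.6), sprintf("g%03d", 1:100))
  lfc_b <- stats::setNames(rnorm(100, 0, 0.6), names(lfc_a))
  ta <- make_fc_table(lfc_a); tb <- make_fc_table(lfc_b)
  thr <- c(1.2, 1.0, 0.8, 0.6)
  sets <- lapply(thr, function(d)
    high_confidence_targets(ta, tb, names(lfc_a), down_threshold = d))
  for (i in 2:length(sets))
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # sorted by mean log2 FC ascending
  mean_lfc <- (lfc_a + lfc_b)[sets[[2]]] / 2
  expect_false(is.unsorted(mean_lfc))
})

test_that("infer_targets ties the whole chain together consistently", {
  sim <- small_mrna_sim(seed = 58)
  res <- infer_targets(sim$expr, sim$truth$predicted)
  expect_s3_class(res, "target_call")
  # the high-confidence set is contained in each per-arm down list
  for (a in res$arms)
    expect_true(all(res$high_confidence %in% res$down_per_arm[[a]]))
  # targets + background partition the expressed universe
  t1 <- res$tests[[1]]
  expect_identical(t1$n_targets + t1$n_background, length(res$expressed))
  expect_true(all(t1$D >= 0 && t1$D <= 1))
  # true targets shifted down: both arms must show a left shift
  for (a in res$arms)
    expect_identical(res$tests[[a]]$direction, "left")
  # family selection from a target table gives the same result
  tab <- data.frame(gene_id = sim$truth$predicted, mirna_family = "miR-10")
  res2 <- infer_targets(sim$expr, tab, family = "miR-10")
  expect_identical(res2$high_confidence, res$high_confidence)
  expect_output(print(res), "high-confidence")
})

test_that("target tables read from TSV drop duplicate pairs", {
  fp <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tmirna_family", "LIN28A\tmiR-10", "LIN28A\tmiR-10",
               "WNT1\tmiR-10", "HOXB3\tmiR-92"), fp)
  tab <- read_target_table(fp)
  expect_identical(nrow(tab), 3L)
  expect_identical(sort(tab$gene_id[tab$mirna_family == "miR-10"]),
                   c("LIN28A", "WNT1"))
})
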