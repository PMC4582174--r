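make_cq <- function(values) {
  meta <- data.frame(sample_id = colnames(values),
                     region = rep(c("FB", "pHB"),
                                  length.out = ncol(values)),
                     age_weeks_pc = 7,
                     age_group = rep(c("early", "late"),
                                     length.out = ncol(values)))
  cq_matrix(values, meta)
}

test_that("normalize_dcq centres each sample on the common detected set", {
  v <- matrix(25, 4, 3, dimnames = list(sprintf("m%d", 1:4),
                                        sprintf("s%d", 1:3)))
  d <- normalize_dcq(make_cq(v))
  expect_true(all(d$values == 0))
  # per-sample additive Cq shifts cancel
  set.seed(41)
  v2 <- matrix(runif(12, 20, 30), 4, 3,
               dimnames = dimnames(v))
  d2 <- normalize_dcq(make_cq(v2))
  v3 <- v2; v3[, 2] <- v3[, 2] + 3
  d3 <- normalize_dcq(make_cq(v3))
  expect_equal(d3$values, d2$values)
  # random panel: per-sample mean of dCq over the common set is zero
  v4 <- matrix(runif(59 * 12, 18, 36), 59, 12,
               dimnames = list(sprintf("m%02d", 1:59), sprintf("s%02d", 1:12)))
  v4[3, 5] <- NA  # one dropout; m03 leaves the common set
  d4 <- normalize_dcq(make_cq(v4))
  common <- setdiff(rownames(v4), "m03")
  expect_equal(unname(colMeans(d4$values[common, ])), rep(0, 12))
  expect_true(is.na(d4$values[3, 5]))
  # direct recomputation oracle
  expect_equal(d4$values[1, 2],
               mean(v4[common, 2]) - v4[1, 2])
  # all-missing rows everywhere -> empty common set errors
  v5 <- v4; v5[, 1] <- NA
  expect_error(normalize_dcq(make_cq(v5)), "normalizer undefined")
})

test_that("top_sd_features ranks by SD with lexicographic ties", {
  v <- rbind(const = rep(5, 6),
             wide = c(0, 10, 0, 10, 0, 10),
             mid_b = c(1, 2, 3, 4, 5, 6),
             mid_a = c(6, 5, 4, 3, 2, 1))
  colnames(v) <- sprintf("s%d", 1:6)
  d <- structure(list(values = v), class = "dcq_matrix")
  expect_identical(top_sd_features(d, 1), "wide")
  # mid_a and mid_b tie: lexicographic order breaks it
  expect_identical(top_sd_features(d, 3), c("wide", "mid_a", "mid_b"))
  # a constant feature is only reachable at k = all
  expect_identical(top_sd_features(d, 4)[4], "const")
  expect_error(top_sd_features(d, 0), "positive")
  # random matrix equals a brute-force sd sort
  set.seed(42)
  r <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%d", 1:8)))
  dr <- structure(list(values = r), class = "dcq_matrix")
  sds <- apply(r, 1, sd)
  expect_identical(top_sd_features(dr, 10),
                   rownames(r)[order(-sds, rownames(r))][1:10])
})

test_that("age_group_anova matches the sum-of-squares oracle", {
  g <- rep(c("e", "m", "l"), each = 4)
  # degenerate equal groups: F = 0, p = 1
  v <- matrix(3, 1, 12, dimnames = list("flat", sprintf("s%d", 1:12)))
  out <- age_group_anova(structure(list(values = v), class = "dcq_matrix"),
                         groups = g)
  expect_equal(out$f_statistic, 0)
  expect_equal(out$p_value, 1)
  # clear separation is highly significant
  set.seed(43)
  v2 <- matrix(c(rnorm(4, 0, .01), rnorm(4, 5, .01), rnorm(4, 0, .01)),
               1, 12, dimnames = list("sep", sprintf("s%d", 1:12)))
  out2 <- age_group_anova(structure(list(values = v2), class = "dcq_matrix"),
                          groups = g)
  expect_lt(out2$p_value, 1e-3)
  # random data: F equals hand-computed between/within mean squares
  y <- rnorm(12)
  v3 <- matrix(y, 1, 12, dimnames = list("r", sprintf("s%d", 1:12)))
  out3 <- age_group_anova(structure(list(values = v3), class = "dcq_matrix"),
                          groups = g)
  gm <- tapply(y, g, mean)
  ssb <- sum(4 * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(out3$f_statistic, f_oracle)
  expect_equal(out3$p_value, pf(f_oracle, 2, 9, lower.tail = FALSE))
  expect_error(age_group_anova(structure(list(values = v3),
                                         class = "dcq_matrix"),
                               groups = rep("one", 12)), "2 groups")
  # features without enough replication are dropped with a warning
  v4 <- rbind(v3, lone = c(rnorm(1), rep(NA, 11)))
  expect_warning(
    age_group_anova(structure(list(values = v4), class = "dcq_matrix"),
                    groups = g), "lone")
})

test_that("centred_profiles centre group means to zero-sum rows", {
  v <- matrix(c(2, 2, 4, 4, 6, 6), 1, 6,
              dimnames = list("m", sprintf("s%d", 1:6)))
  d <- structure(list(values = v), class = "dcq_matrix")
  prof <- centred_profiles(d, groups = rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(prof["m", ]), c(-2, 0, 2))
  # single group centres to zero
  expect_equal(unname(centred_profiles(d, groups = rep("a", 6))[1, ]), 0)
  # random data: rows sum to zero and match a loop recomputation
  set.seed(44)
  r <- matrix(rnorm(10 * 9), 10, 9,
              dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:9)))
  g <- rep(c("x", "y", "z"), 3)
  pr <- centred_profiles(structure(list(values = r), class = "dcq_matrix"),
                         groups = g)
  expect_equal(unname(rowSums(pr)), rep(0, 10), tolerance = 1e-9)
  for (f in rownames(r)) {
    gm <- tapply(r[f, ], g, mean)[colnames(pr)]
    expect_equal(unname(pr[f, ]), as.numeric(gm - mean(gm)))
  }
})

test_that("ddct reproduces the textbook relative-quantification example", {
  tab <- data.frame(condition = c("treated", "reference"),
                    replicate = 1,
                    ct_target = c(18, 20), ct_housekeeping = c(15, 15))
  out <- ddct(tab, "reference")
  expect_equal(out$delta_delta_ct[out$condition == "treated"], -2)
  expect_equal(out$relative_quantity[out$condition == "treated"], 4)
  expect_equal(out$relative_quantity[out$condition == "reference"], 1)
  expect_equal(out$delta_delta_ct[out$condition == "reference"], 0)
  # technical replicates are averaged before dCt; RQ matches the formula
  set.seed(45)
  tab2 <- data.frame(condition = rep(c("a", "b", "ref"), each = 3),
                     replicate = rep(1:3, 3),
                     ct_target = runif(9, 15, 30),
                     ct_housekeeping = runif(9, 14, 16))
  out2 <- ddct(tab2, "ref")
  dct <- tapply(tab2$ct_target, tab2$condition, mean) -
    tapply(tab2$ct_housekeeping, tab2$condition, mean)
  expect_equal(out2$relative_quantity,
               as.numeric(2^-(dct - dct["ref"])[out2$condition]))
  tab3 <- tab; tab3$ct_housekeeping[1] <- NA
  expect_error(ddct(tab3, "reference"), "housekeeping")
  expect_error(ddct(tab, "absent"), "absent")
})

test_that("detection_call thresholds Cq and treats missing as undetected", {
  v <- matrix(c(45, 30, NA, 37), 2, 2,
              dimnames = list(c("m1", "m2"), c("s1", "s2")))
  det <- detection_call(make_cq(v), max_cq = 37)
  expect_identical(unname(det), matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  expect_error(detection_call(make_cq(v), max_cq = 55), "max_cq")
  # random matrix equals the elementwise comparison oracle
  set.seed(46)
  r <- matrix(runif(40, 20, 45), 4, 10,
              dimnames = list(sprintf("m%d", 1:4), sprintf("s%02d", 1:10)))
  r[sample(40, 6)] <- NA
  expect_identical(detection_call(make_cq(r), 37),
                   !is.na(r) & r <= 37)
})

test_that("region-restricted assays reproduce the seeded detection pattern", {
  sim <- simulate_cq(
    effects = data.frame(mirna = c("hsa-miR-sim-01", "hsa-miR-sim-02"),
                         effect = 4),
    absent = data.frame(mirna = rep(c("hsa-miR-sim-01", "hsa-miR-sim-02"),
                                    each = 5),
                        region = rep(c("FB", "vMB", "dMB", "vHB", "dHB"), 2)),
    noise_sd = 0.3, seed = 47)
  det <- detection_call(sim$cq)
  meta <- sim$cq$sample_meta
  for (m in c("hsa-miR-sim-01", "hsa-miR-sim-02")) {
    expect_true(all(det[m, meta$region %in% c("pHB", "SC")]))
    expect_false(any(det[m, !meta$region %in% c("pHB", "SC")]))
  }
  # everything else is detected everywhere at this noise level
  expect_true(all(det[-(1:2), ]))
})
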