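test_that("log-ratio assembly inverts reverse experiments and validates labels", {
  tab <- data.frame(protein_id = c("P1", "P2"),
                    ratio_F1 = c(2, NA), ratio_R1 = c(0.5, 4))
  des <- data.frame(experiment = c("F1", "R1"),
                    orientation = c("forward", "reverse"))
  m <- assemble_log_ratios(tab, des)
  expect_equal(m["P1", ], c(F1 = 1, R1 = 1))
  expect_true(is.na(m["P2", "F1"]))
  expect_equal(m["P2", "R1"], -2)
  des$orientation[1] <- "sideways"
  expect_error(assemble_log_ratios(tab, des), "orientation")
})

test_that("evidence filters enforce forward+reverse and min-replicate rules", {
  des <- data.frame(experiment = c("F1", "F2", "R1", "R2"),
                    orientation = c("forward", "forward", "reverse", "reverse"))
  m <- matrix(c(1, 1, NA, NA,    # only forward: dropped
                1, NA, 1, NA,    # 1 forward + 1 reverse: kept
                NA, NA, 1, 1),   # only reverse: dropped
              nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), des$experiment))
  kept <- suppressMessages(filter_min_evidence(m, "forward_and_reverse", design = des))
  expect_equal(rownames(kept), "b")
  expect_equal(attr(kept, "n_removed"), 2)

  kept2 <- suppressMessages(filter_min_evidence(m, "min_k_replicates", k = 2))
  expect_equal(rownames(kept2), c("a", "b", "c"))  # boundary: exactly 2 kept
  empty <- matrix(numeric(0), nrow = 0, ncol = 4)
  expect_equal(nrow(filter_min_evidence(empty, "min_k_replicates")), 0)
})

test_that("quantile normalization equalizes distributions within groups only", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6), c = c(10, 20, 30))
  out <- quantile_normalize(m, groups = c("g1", "g1", "g2"))
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "c"]), c(10, 20, 30))  # singleton group untouched

  # identical columns are a fixed point
  m2 <- cbind(x = c(1, 5, 9), y = c(1, 5, 9))
  expect_equal(quantile_normalize(m2, c("g", "g")), m2)

  # missing cells stay missing; observed multiset shared across complete columns
  m3 <- cbind(u = c(1, 2, 3, 4), v = c(2, NA, 6, 8), w = c(0, 4, 8, 12))
  out3 <- quantile_normalize(m3, rep("g", 3))
  expect_true(is.na(out3[2, "v"]))
  expect_equal(sort(out3[, "u"]), sort(out3[, "w"]))
  # rank order within each column preserved
  expect_equal(order(out3[, "u"]), order(m3[, "u"]))
})

test_that("imputation follows the mean-of-replicates / minimum rules", {
  g <- rep(c("cross", "ctrl"), each = 5)
  m <- rbind(p1 = c(10, 12, NA, 11, NA, 20, 21, 19, 22, 20),
             p2 = c(9, 9, 9, 9, 9,    NA, NA, NA, NA, NA),
             p3 = c(NA, NA, NA, 8, 7,  15, 15, 15, 15, 15),
             p4 = c(5, 6, 7, 8, 9,    10, 11, 12, 13, 14))
  colnames(m) <- paste0(g, 1:5)
  out <- impute_intensities(m, g, rule = "sicap_protein",
                            min_impute_groups = "ctrl")
  # <=2 of 5 missing: mean of observed replicates
  expect_equal(unname(out["p1", c(3, 5)]), c(11, 11))
  # all 5 control replicates missing: per-column observed minimum
  expect_equal(unname(out["p2", 6:10]), unname(apply(m[, 6:10], 2, min, na.rm = TRUE)))
  # 3 of 5 missing: left missing for the evidence filter to handle
  expect_true(all(is.na(out["p3", 1:3])))
  # complete row unchanged
  expect_equal(out["p4", ], m["p4", ])

  # spacemap rule: an all-missing fraction gets column minima, partial stays
  g2 <- rep(c("cross", "rel"), each = 3)
  m2 <- rbind(q1 = c(10, 11, 12, NA, NA, NA),
              q2 = c(10, NA, 12, 5, 6, 7))
  colnames(m2) <- paste0(g2, 1:3)
  out2 <- impute_intensities(m2, g2, rule = "spacemap_peptide")
  expect_equal(unname(out2["q1", 4:6]), c(5, 6, 7))
  expect_true(is.na(out2["q2", 2]))

  m3 <- rbind(c(NA, 1), c(NA, 2))
  expect_error(impute_intensities(m3, c("a", "b"), "spacemap_peptide"),
               "entirely missing")
})

test_that("EB hyperparameter estimation matches moments and recovers truth", {
  # all variances identical: no excess dispersion, d0 infinite
  h <- fit_eb_hyperparams(rep(2, 10), d = 3)
  expect_identical(h$d0, Inf)
  expect_equal(h$s0sq, 2)

  expect_error(fit_eb_hyperparams(2, d = 3), ">= 2 features")

  # recovery from a known scaled inverse chi-square law
  set.seed(11)
  sigma2 <- 4 * 1 / rchisq(2000, df = 4)
  s2 <- sigma2 * rchisq(2000, df = 2) / 2
  h2 <- fit_eb_hyperparams(s2, d = 2)
  expect_gt(h2$d0, 3.2)
  expect_lt(h2$d0, 4.8)
  expect_equal(h2$s0sq, 1, tolerance = 0.1)
  # independent cross-check against limma's F-distribution fit
  fd <- limma::fitFDist(s2, df1 = 2)
  expect_equal(h2$d0, fd$df2, tolerance = 1e-6)
  expect_equal(h2$s0sq, fd$scale, tolerance = 1e-6)
})

test_that("moderated t-test reproduces the closed-form worked example", {
  m <- matrix(c(1.0, 1.2, 0.8), nrow = 1, dimnames = list("f1", NULL))
  res <- moderated_t_test(m, "one_sample_ratio", hyper = list(d0 = 4, s0sq = 1))
  expect_equal(res$log2FC, 1)
  expect_equal(res$s2, 0.04)
  expect_equal(res$s2_post, 0.68)
  expect_equal(res$t_mod, 1 / sqrt(0.68 / 3), tolerance = 1e-12)
  expect_equal(res$df_total, 6)
  expect_equal(res$p, 2 * pt(-abs(res$t_mod), df = 6))
})

test_that("moderation limits behave: d0 = 0 is the ordinary t, d0 = Inf is normal", {
  set.seed(2)
  m <- matrix(rnorm(50 * 4), nrow = 50)
  res0 <- moderated_t_test(m, "one_sample_ratio", hyper = list(d0 = 0, s0sq = 1))
  tt <- apply(m, 1, function(x) t.test(x)$statistic)
  expect_equal(res0$t_mod, unname(tt), tolerance = 1e-10)

  resI <- moderated_t_test(m, "one_sample_ratio", hyper = list(d0 = Inf, s0sq = 1))
  expect_true(all(is.infinite(resI$df_total)))
  expect_equal(resI$p, 2 * pnorm(-abs(resI$t_mod)))

  # all-zero observations: t = 0, p = 1
  z <- moderated_t_test(matrix(0, 1, 3), "one_sample_ratio",
                        hyper = list(d0 = 4, s0sq = 1))
  expect_equal(z$t_mod, 0)
  expect_equal(z$p, 1)
})

test_that("moderated t-test agrees with limma as an independent oracle", {
  set.seed(7)
  n <- 200
  m <- matrix(rnorm(n * 6, sd = rep(sqrt(4 * 0.3 / rchisq(n, 4)), 6)), nrow = n)
  m[sample(length(m), 40)] <- NA
  keep <- rowSums(!is.na(m)) >= 2
  m <- m[keep, , drop = FALSE]
  rownames(m) <- sprintf("f%03d", seq_len(nrow(m)))
  res <- moderated_t_test(m, "one_sample_ratio")
  fit <- limma::eBayes(limma::lmFit(m, matrix(1, ncol(m), 1)))
  expect_equal(attr(res, "hyper")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "hyper")$s0sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("moderation shrinks every posterior variance between s2 and s0sq", {
  set.seed(8)
  m <- matrix(rnorm(100 * 5), nrow = 100)
  res <- moderated_t_test(m, "one_sample_ratio", hyper = list(d0 = 3, s0sq = 0.8))
  lo <- pmin(res$s2, 0.8); hi <- pmax(res$s2, 0.8)
  expect_true(all(res$s2_post >= lo - 1e-12 & res$s2_post <= hi + 1e-12))
})

test_that("two-group mode handles unbalanced and untestable features", {
  m <- rbind(f1 = c(5, 6, 7, 1, 2, 3),
             f2 = c(5, NA, NA, 1, 2, 3),   # n1 = 1: still testable with prior
             f3 = c(5, 6, 7, NA, NA, NA))  # one group empty: untested
  g <- rep(c("cross", "rel"), each = 3)
  res <- moderated_t_test(m, "two_group", groups = g,
                          hyper = list(d0 = 4, s0sq = 1))
  expect_equal(res$log2FC[1], 4)
  expect_false(is.na(res$p[2]))
  expect_true(is.na(res$p[3]))
  # ordinary two-sample t recovered at d0 = 0
  res0 <- moderated_t_test(m[1, , drop = FALSE], "two_group", groups = g,
                           hyper = list(d0 = 0, s0sq = 1))
  tt <- t.test(m[1, 1:3], m[1, 4:6], var.equal = TRUE)
  expect_equal(res0$t_mod, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res0$p, tt$p.value, tolerance = 1e-10)
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.5, 5)), rep(0.5, 5))
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone in p, adj_p >= p, invariant to input order
  set.seed(3)
  p <- runif(50)
  a <- adjust_bh(p)
  expect_true(all(a >= p))
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(adjust_bh(p[perm]), a[perm])
  # NA handling: NAs excluded from ranking, returned as NA
  p2 <- c(0.01, NA, 0.02)
  expect_equal(adjust_bh(p2), c(0.02, NA, 0.02))
})

test_that("tier calls use strict printed thresholds", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2FC = c(1.5, 1.5, 1.0, 2.0),
                    p = c(0.001, 0.02, 0.001, NA))
  res$adj_p <- c(0.005, 0.05, 0.005, NA)
  out <- classify_tiers(res)
  expect_equal(as.character(out$tier),
               c("highly_significant", "significant", "not_significant",
                 "not_significant"))
  expect_equal(unname(c(attr(out, "tier_counts"))), c(1, 1, 2))
})

test_that("Fisher 2x2 matches the hypergeometric enumeration oracle", {
  # exhaustive enumeration at fixed margins (4,4 rows; 4,4 columns)
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  probs <- dhyper(0:4, 4, 4, 4)
  p_oracle <- sum(probs[probs <= dhyper(3, 4, 4, 4) + 1e-12])
  expect_equal(fisher_2x2(tab), p_oracle)
  expect_equal(fisher_2x2(tab), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_2x2(matrix(5, 2, 2)), 1)
  expect_warning(p <- fisher_2x2(matrix(c(0, 0, 1, 1), 2, byrow = TRUE)),
                 "degenerate")
  expect_equal(p, 1)
  # random tables against stats::fisher.test enumeration
  set.seed(4)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    x <- t2[1, 1]; m <- sum(t2[1, ]); n <- sum(t2[2, ]); k <- sum(t2[, 1])
    pr <- dhyper(max(0, k - n):min(k, m), m, n, k)
    expect_equal(fisher_2x2(t2),
                 sum(pr[pr <= dhyper(x, m, n, k) * (1 + 1e-7)]),
                 tolerance = 1e-9)
  }
})
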