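# Differential-enrichment engine: ratio assembly, group-wise quantile
# normalization, rule-based imputation, empirical-Bayes moderated t-test,
# BH adjustment, tiered significance calls and Fisher's exact test.

#' Assemble per-experiment log2 enrichment ratios from SILAC data
#'
#' Forward experiments (heavy = crosslinked) contribute
#' `log2(ratio H/L)`; reverse experiments (label swap) contribute
#' `-log2(ratio H/L)`, so every column is log2(crosslinked /
#' non-crosslinked). Missing ratios stay missing.
#'
#' @param table A `protein_quant` data frame with `ratio_<experiment>`
#'   columns.
#' @param design Data frame with columns `experiment` and `orientation`
#'   (`"forward"` or `"reverse"`).
#' @return Numeric matrix, rows = proteins (rownames = protein ids),
#'   one column per designed experiment.
#' @export
assemble_log_ratios <- function(table, design) {
  if (!all(design$orientation %in% c("forward", "reverse"))) {
    stop("assemble_log_ratios: unknown orientation label; use 'forward'/'reverse'")
  }
  labs <- gsub("[^A-Za-z0-9]+", "_", design$experiment)
  cols <- paste0("ratio_", labs)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    stop(sprintf("assemble_log_ratios: ratio column(s) not in table: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- sapply(seq_along(cols), function(k) {
    sgn <- if (design$orientation[k] == "forward") 1 else -1
    sgn * log2(table[[cols[k]]])
  })
  m <- matrix(m, nrow = nrow(table),
              dimnames = list(table$protein_id, design$experiment))
  m
}

#' Drop features with insufficient replicate evidence
#'
#' `forward_and_reverse` keeps rows observed in at least one forward
#' and at least one reverse experiment (>= 2 assays in total);
#' `min_k_replicates` keeps rows with at least `k` observed values.
#'
#' @param m Numeric matrix (features x experiments), NAs = unobserved.
#' @param rule `"forward_and_reverse"` or `"min_k_replicates"`.
#' @param design Required for `forward_and_reverse`: the design data
#'   frame whose `orientation` matches columns of `m`.
#' @param k Minimum observed values for `min_k_replicates`.
#' @return The filtered matrix; removal count in attribute
#'   `n_removed` and reported via `message()`.
#' @export
filter_min_evidence <- function(m, rule = c("forward_and_reverse", "min_k_replicates"),
                                design = NULL, k = 2L) {
  rule <- match.arg(rule)
  if (nrow(m) == 0) return(m)
  obs <- !is.na(m)
  keep <- if (rule == "forward_and_reverse") {
    stopifnot(!is.null(design), ncol(m) == nrow(design))
    fwd <- design$orientation == "forward"
    rowSums(obs[, fwd, drop = FALSE]) >= 1 &
      rowSums(obs[, !fwd, drop = FALSE]) >= 1
  } else {
    rowSums(obs) >= k
  }
  out <- m[keep, , drop = FALSE]
  message(sprintf("filter_min_evidence (%s): removed %d of %d features",
                  rule, sum(!keep), nrow(m)))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Group-wise quantile normalization
#'
#' Applies quantile normalization separately within each condition
#' group (e.g. crosslinked columns together, control columns
#' together), via [limma::normalizeQuantiles()]. Within a group every
#' column is mapped onto the per-rank mean of the sorted columns;
#' missing cells remain missing and within-column rank order is
#' preserved. Groups with a single column, or columns with fewer than
#' two observed values, are left unchanged (with a warning for the
#' latter).
#'
#' @param m Numeric matrix of intensities (features x samples).
#' @param groups Vector of group labels, one per column.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(m, groups) {
  stopifnot(ncol(m) == length(groups))
  out <- m
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- m[, idx, drop = FALSE]
    few <- colSums(!is.na(sub)) < 2
    if (any(few)) {
      warning(sprintf("quantile_normalize: %d column(s) in group '%s' with <2 observed values left unchanged",
                      sum(few), g))
    }
    if (sum(!few) >= 2) {
      sub[, !few] <- limma::normalizeQuantiles(sub[, !few, drop = FALSE])
    }
    out[, idx] <- sub
  }
  out
}

#' Rule-based imputation of missing intensities
#'
#' `sicap_protein` (per row, within each condition group): if at most
#' `max_impute` replicates are missing they are imputed with the mean
#' of the observed replicates; if *all* replicates of a group listed in
#' `min_impute_groups` (by default the control group) are missing,
#' each missing cell gets its column's observed minimum; intermediate
#' missingness is left as is (such rows are expected to fall to the
#' evidence filter). `spacemap_peptide` (per row): a fraction whose
#' replicates are all missing is imputed with per-column observed
#' minima; partial missingness is left as is.
#'
#' @param m Intensity matrix (post-normalization).
#' @param groups Group label per column.
#' @param rule `"sicap_protein"` or `"spacemap_peptide"`.
#' @param max_impute Maximum missing replicates replaced by the
#'   row-group mean under `sicap_protein` (default 2, mirroring a
#'   2-of-5 allowance).
#' @param min_impute_groups Groups eligible for all-missing minimum
#'   imputation under `sicap_protein`; default the last group label
#'   (the non-crosslinked control). Under `spacemap_peptide` both
#'   fractions are always eligible.
#' @return Matrix with imputed values.
#' @export
impute_intensities <- function(m, groups,
                               rule = c("sicap_protein", "spacemap_peptide"),
                               max_impute = 2L,
                               min_impute_groups = NULL) {
  rule <- match.arg(rule)
  stopifnot(ncol(m) == length(groups))
  col_min <- apply(m, 2, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  if (anyNA(col_min)) {
    stop("impute_intensities: a column is entirely missing; no minimum defined")
  }
  if (is.null(min_impute_groups)) {
    min_impute_groups <- if (rule == "sicap_protein")
      utils::tail(unique(groups), 1) else unique(groups)
  }
  out <- m
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- out[, idx, drop = FALSE]
    n_miss <- rowSums(is.na(sub))
    if (rule == "sicap_protein") {
      fix <- which(n_miss > 0 & n_miss <= max_impute & n_miss < length(idx))
      for (i in fix) {
        sub[i, is.na(sub[i, ])] <- mean(sub[i, ], na.rm = TRUE)
      }
    }
    all_missing <- which(n_miss == length(idx))
    if (g %in% min_impute_groups && length(all_missing) > 0) {
      for (j in seq_along(idx)) sub[all_missing, j] <- col_min[idx[j]]
    }
    out[, idx] <- sub
  }
  out
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Closed-form moment matching on log sample variances: under a scaled
#' inverse chi-square prior with `d0` degrees of freedom and scale
#' `s0sq`, `log(s^2)` has mean and variance expressible through
#' digamma/trigamma functions. The excess dispersion of `log(s^2)`
#' beyond the sampling term `trigamma(d/2)` determines `d0` through a
#' trigamma inverse (Newton iteration, tolerance 1e-8, at most 50
#' steps); zero or negative excess gives `d0 = Inf` with `s0sq` the
#' mean sample variance.
#'
#' @param s2 Sample variances (one per feature); non-positive or
#'   missing entries are dropped.
#' @param d Residual degrees of freedom, scalar or per-feature.
#' @return List of class `eb_hyperparams` with elements `d0`, `s0sq`,
#'   `n_used`.
#' @export
fit_eb_hyperparams <- function(s2, d) {
  d <- rep_len(d, length(s2))
  ok <- !is.na(s2) & s2 > 0 & !is.na(d) & d > 0
  if (sum(ok) < 2) {
    stop("fit_eb_hyperparams: need >= 2 features with positive variance and df; supply fixed hyperparameters instead")
  }
  s2 <- s2[ok]; d <- d[ok]
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond sampling noise: point-mass prior whose
    # scale is the plain mean of the sample variances
    d0 <- Inf
    s0sq <- mean(s2)
  }
  structure(list(d0 = d0, s0sq = s0sq, n_used = n), class = "eb_hyperparams")
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone,
# nearly linear); tolerance 1e-8, max 50 iterations.
.trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated t-test
#'
#' Per feature, the posterior variance
#' `s2_post = (d0 * s0sq + d * s2) / (d0 + d)` shrinks the sample
#' variance toward the prior; the moderated t statistic is the
#' estimate divided by `sqrt(s2_post * v)` with `v = 1/n` (one-sample
#' on log-ratios, null mean 0) or `v = 1/n1 + 1/n2` (two-group on
#' log-intensities). P-values come from the t distribution on
#' `d0 + d` degrees of freedom (standard normal when `d0 = Inf`).
#' `d0 = 0` recovers the ordinary t-test.
#'
#' @param m Numeric matrix: log2 ratios (one-sample) or log2
#'   intensities (two-group), features in rows.
#' @param mode `"one_sample_ratio"` or `"two_group"`.
#' @param groups For `two_group`: a two-level factor/vector over
#'   columns; log2FC is group 1 minus group 2 (first level =
#'   numerator condition).
#' @param hyper An `eb_hyperparams` list (`d0`, `s0sq`), or `NULL` to
#'   estimate from the data via [fit_eb_hyperparams()].
#' @return Data frame of class `enrichment_result`: `feature_id`,
#'   `n_obs` (total; for two-group also `n1`, `n2`), `log2FC`, `s2`,
#'   `t_mod`, `df_total`, `p`. Features with insufficient observations
#'   are reported untested (`p = NA`).
#' @export
moderated_t_test <- function(m, mode = c("one_sample_ratio", "two_group"),
                             groups = NULL, hyper = NULL) {
  mode <- match.arg(mode)
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%06d", seq_len(nrow(m)))

  if (mode == "one_sample_ratio") {
    n <- rowSums(!is.na(m))
    est <- rowMeans(m, na.rm = TRUE)
    s2 <- apply(m, 1, stats::var, na.rm = TRUE)
    d <- pmax(n - 1, 0)
    v <- 1 / n
    testable <- n >= 2
    n1 <- n2 <- NULL
  } else {
    stopifnot(!is.null(groups), length(groups) == ncol(m))
    lev <- unique(groups)
    stopifnot(length(lev) == 2)
    m1 <- m[, groups == lev[1], drop = FALSE]
    m2 <- m[, groups == lev[2], drop = FALSE]
    n1 <- rowSums(!is.na(m1)); n2 <- rowSums(!is.na(m2))
    n <- n1 + n2
    est <- rowMeans(m1, na.rm = TRUE) - rowMeans(m2, na.rm = TRUE)
    ss <- function(x) {
      mu <- rowMeans(x, na.rm = TRUE)
      rowSums((x - mu)^2, na.rm = TRUE)
    }
    d <- pmax(n - 2, 0)
    s2 <- ifelse(d > 0, (ss(m1) + ss(m2)) / pmax(d, 1), NA_real_)
    v <- 1 / n1 + 1 / n2
    testable <- n1 >= 1 & n2 >= 1 & n >= 3
  }
  s2[is.na(s2) & testable] <- 0  # zero residual df or constant rows stay testable

  if (is.null(hyper)) {
    hyper <- fit_eb_hyperparams(s2[testable & d > 0], d[testable & d > 0])
  }
  d0 <- hyper$d0; s0sq <- hyper$s0sq

  if (is.infinite(d0)) {
    s2_post <- rep(s0sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * s0sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  t_mod <- est / sqrt(s2_post * v)
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t_mod)),
              2 * stats::pt(-abs(t_mod), df = df_total))
  t_mod[!testable] <- NA_real_
  p[!testable] <- NA_real_
  p[testable & !is.na(t_mod) & t_mod == 0] <- 1

  out <- data.frame(feature_id = rownames(m), n_obs = n,
                    log2FC = est, s2 = s2, s2_post = s2_post,
                    t_mod = t_mod, df_total = df_total, p = p,
                    stringsAsFactors = FALSE)
  if (mode == "two_group") { out$n1 <- n1; out$n2 <- n2 }
  attr(out, "hyper") <- hyper
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; `NA` p-values are
#' excluded from the ranking and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("adjust_bh: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-tier significance calls
#'
#' Strict thresholds: `log2FC > fc_threshold` with
#' `adj_p < tier1_alpha` is `highly_significant`; `log2FC >
#' fc_threshold` with `adj_p < tier2_alpha` (but not tier 1) is
#' `significant`; everything else `not_significant`. Defaults mirror
#' the log2FC > 1 with adjusted p < 0.01 / < 0.1 convention.
#'
#' @param results An `enrichment_result` data frame with `log2FC` and
#'   `p` columns (`adj_p` is computed if absent).
#' @param fc_threshold,tier1_alpha,tier2_alpha Thresholds (strict
#'   inequalities).
#' @return `results` with columns `adj_p` and `tier` added; tier
#'   counts in attribute `tier_counts`.
#' @export
classify_tiers <- function(results, fc_threshold = 1,
                           tier1_alpha = 0.01, tier2_alpha = 0.1) {
  if (!"adj_p" %in% names(results)) results$adj_p <- adjust_bh(results$p)
  tier <- rep("not_significant", nrow(results))
  ok <- !is.na(results$log2FC) & !is.na(results$adj_p)
  hit2 <- ok & results$log2FC > fc_threshold & results$adj_p < tier2_alpha
  hit1 <- ok & results$log2FC > fc_threshold & results$adj_p < tier1_alpha
  tier[hit2] <- "significant"
  tier[hit1] <- "highly_significant"
  results$tier <- factor(tier, levels = c("highly_significant", "significant",
                                          "not_significant"))
  attr(results, "tier_counts") <- table(results$tier)
  results
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than that of the
#' observed table. A zero row or column margin yields `p = 1` with a
#' warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("fisher_2x2: degenerate margin; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}
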