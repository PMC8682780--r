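# Keyword-driven categorization of enriched proteins and dataset-level
# comparisons. Keyword matching is case-insensitive substring matching
# against the union of a protein's GO terms and UniProt-style keywords.

#' Default keyword configuration for protein categorization
#'
#' Editable keyword sets driving [categorize_proteins()]:
#' `chromatin_binding` defines known DNA/chromatin binders (and the
#' potential-true-positive call), `nuclear` defines the "present in
#' nucleus" class, `pfp_processes` lists the biological processes
#' treated as potential false positives when no chromatin-related term
#' is present (translation, metabolic process, cell adhesion, protein
#' folding, protein transport), and `rbp` flags RNA-binding proteins.
#' These defaults are deliberately compact; real analyses should
#' extend them (e.g. from a curated GO slim).
#'
#' @return Named list of character vectors.
#' @export
default_keyword_config <- function() {
  list(
    chromatin_binding = c("chromatin binding", "dna binding", "dna-binding",
                          "chromatin", "nucleosome", "histone",
                          "transcription factor", "dna repair",
                          "dna replication", "chromosome"),
    nuclear = c("nucleus", "nuclear", "nucleolus", "nucleoplasm"),
    pfp_processes = c("translation", "metabolic process", "cell adhesion",
                      "protein folding", "protein transport"),
    rbp = c("rna binding", "rna-binding", "mrna binding", "rrna binding",
            "trna binding")
  )
}

.terms_of <- function(go_terms, keywords) {
  tolower(paste(go_terms, keywords, sep = ";"))
}

.hits_any <- function(terms, keyset) {
  if (length(keyset) == 0) return(rep(FALSE, length(terms)))
  Reduce(`|`, lapply(tolower(keyset), function(k) grepl(k, terms, fixed = TRUE)))
}

#' Categorize proteins by GO/keyword annotation
#'
#' Deterministic, mutually exclusive three-way category with
#' precedence known_binder > nuclear > unexpected: a protein is a
#' `known_binder` if any DNA/chromatin-binding keyword hits, else
#' `nuclear` if any nucleus keyword hits, else `unexpected`.
#' Independently, `ptp_pfp` is `PTP` when chromatin-related keywords
#' hit, `PFP` when only the configured non-chromatin processes hit,
#' and `NA` otherwise; `is_rbp` comes from the RBP keyword set and is
#' independent of the three-way category.
#'
#' @param annotations Data frame with `protein_id`, `go_terms`,
#'   `keywords` (semicolon-separated term strings; empty allowed).
#' @param keyword_config See [default_keyword_config()].
#' @return Data frame of class `category_annotation`: `protein_id`,
#'   `category3`, `ptp_pfp`, `is_rbp`.
#' @export
categorize_proteins <- function(annotations,
                                keyword_config = default_keyword_config()) {
  terms <- .terms_of(annotations$go_terms, annotations$keywords)
  chrom <- .hits_any(terms, keyword_config$chromatin_binding)
  nuc <- .hits_any(terms, keyword_config$nuclear)
  pfp <- .hits_any(terms, keyword_config$pfp_processes)
  rbp <- .hits_any(terms, keyword_config$rbp)

  category3 <- ifelse(chrom, "known_binder", ifelse(nuc, "nuclear", "unexpected"))
  ptp_pfp <- ifelse(chrom, "PTP", ifelse(pfp, "PFP", NA_character_))
  out <- data.frame(protein_id = annotations$protein_id,
                    category3 = factor(category3, levels = c("known_binder",
                                                             "nuclear",
                                                             "unexpected")),
                    ptp_pfp = ptp_pfp,
                    is_rbp = rbp,
                    stringsAsFactors = FALSE)
  class(out) <- c("category_annotation", "data.frame")
  out
}

#' Category summary by protein count and relative iBAQ
#'
#' Relative iBAQ is each protein's share of the summed iBAQ over the
#' summarized set, an abundance estimate; category fractions are
#' reported both by count and by relative iBAQ (each summing to 1).
#'
#' @param ibaq Named numeric vector of iBAQ values (names = protein
#'   ids); proteins with missing iBAQ are dropped from the iBAQ
#'   fractions.
#' @param categories A `category_annotation` data frame covering the
#'   proteins; its `category3` defines the grouping (pass a different
#'   factor via `by` to group otherwise, e.g. by `ptp_pfp`).
#' @param by Column of `categories` to group by.
#' @return Data frame with `category`, `n`, `count_fraction`,
#'   `ibaq_fraction`.
#' @export
relative_ibaq_summary <- function(ibaq, categories, by = "category3") {
  if (all(is.na(ibaq))) stop("relative_ibaq_summary: all iBAQ values missing")
  df <- data.frame(protein_id = names(ibaq), ibaq = as.numeric(ibaq),
                   stringsAsFactors = FALSE)
  df <- merge(df, categories[, c("protein_id", by)], by = "protein_id")
  df$category <- as.character(df[[by]])
  df <- df[!is.na(df$category), , drop = FALSE]
  total <- sum(df$ibaq, na.rm = TRUE)
  agg <- do.call(rbind, lapply(split(df, df$category), function(g) {
    data.frame(category = g$category[1], n = nrow(g),
               count_fraction = nrow(g) / nrow(df),
               ibaq_fraction = sum(g$ibaq, na.rm = TRUE) / total,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Chromatin-to-total-proteome abundance ratio classes
#'
#' For proteins quantified in both tables, computes the ratio of
#' chromatin-fraction iBAQ to total-proteome iBAQ and bins the log
#' ratio into `k` classes of near-equal size (class `k` = highest
#' ratio, i.e. most chromatin-avid). Ties are broken by stable
#' protein-id order; class sizes differ by at most 1.
#'
#' @param space_ibaq,total_ibaq Named numeric vectors of positive iBAQ
#'   values.
#' @param k Number of classes (default 4: quartiles).
#' @return Data frame with `protein_id`, `ratio`, `class`.
#' @export
ratio_classes <- function(space_ibaq, total_ibaq, k = 4L) {
  shared <- intersect(names(space_ibaq), names(total_ibaq))
  shared <- shared[!is.na(space_ibaq[shared]) & !is.na(total_ibaq[shared]) &
                     space_ibaq[shared] > 0 & total_ibaq[shared] > 0]
  dropped <- length(union(names(space_ibaq), names(total_ibaq))) - length(shared)
  if (dropped > 0) {
    message(sprintf("ratio_classes: %d protein(s) absent or unquantified in one table excluded",
                    dropped))
  }
  if (length(shared) < k) {
    stop(sprintf("ratio_classes: need at least k = %d proteins present in both tables", k))
  }
  ratio <- space_ibaq[shared] / total_ibaq[shared]
  ord <- order(log(ratio), shared)  # stable tie-break on protein id
  n <- length(shared)
  cls <- integer(n)
  cls[ord] <- as.integer(ceiling(seq_len(n) / (n / k)))
  cls[cls > k] <- k
  out <- data.frame(protein_id = shared, ratio = as.numeric(ratio),
                    class = cls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Map p-values to significance stars
#'
#' `***` for p < 0.001, `**` for p <= 0.01, `*` for p <= 0.05, empty
#' otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", ""))))
}

#' Pairwise Fisher comparisons of category composition across datasets
#'
#' For every pair of datasets and every category level, builds the
#' category-vs-rest 2x2 contingency table of protein counts and
#' applies a two-sided Fisher's exact test, with star annotation.
#' Empty datasets are skipped with a warning.
#'
#' @param category_lists Named list; each element a factor/character
#'   vector of per-protein categories for one dataset.
#' @return Data frame with `dataset_a`, `dataset_b`, `category`,
#'   `a_in`, `a_out`, `b_in`, `b_out`, `p`, `stars`.
#' @export
compare_datasets <- function(category_lists) {
  stopifnot(length(category_lists) >= 2)
  sizes <- lengths(category_lists)
  if (any(sizes == 0)) {
    warning(sprintf("compare_datasets: skipping empty dataset(s): %s",
                    paste(names(category_lists)[sizes == 0], collapse = ", ")))
    category_lists <- category_lists[sizes > 0]
  }
  nm <- names(category_lists)
  levels_all <- sort(unique(unlist(lapply(category_lists, as.character))))
  rows <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j <= i) next
      a <- as.character(category_lists[[i]]); b <- as.character(category_lists[[j]])
      for (lev in levels_all) {
        tab <- matrix(c(sum(a == lev), sum(a != lev),
                        sum(b == lev), sum(b != lev)), nrow = 2, byrow = TRUE)
        p <- fisher_2x2(tab)
        rows[[length(rows) + 1]] <- data.frame(
          dataset_a = nm[i], dataset_b = nm[j], category = lev,
          a_in = tab[1, 1], a_out = tab[1, 2],
          b_in = tab[2, 1], b_out = tab[2, 2],
          p = p, stars = significance_stars(p), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate log2 fold-changes between two enrichment analyses
#'
#' Pearson correlation of log2FC over the shared features, plus a
#' divergence table of features called significant (tier 1 or 2) in
#' analysis A but not in B — candidates whose chromatin association is
#' regulated beyond their expression change.
#'
#' @param results_a,results_b `enrichment_result` data frames carrying
#'   `feature_id`, `log2FC` and (for the divergence table) `tier`.
#' @return List with `r` (Pearson correlation), `n_shared`, and
#'   `divergent` (data frame of A-only significant features).
#' @export
correlate_fold_changes <- function(results_a, results_b) {
  shared <- merge(results_a, results_b, by = "feature_id",
                  suffixes = c("_a", "_b"))
  shared <- shared[!is.na(shared$log2FC_a) & !is.na(shared$log2FC_b), , drop = FALSE]
  if (nrow(shared) < 3) {
    stop("correlate_fold_changes: need >= 3 shared features with fold-changes")
  }
  r <- stats::cor(shared$log2FC_a, shared$log2FC_b, method = "pearson")
  divergent <- if (all(c("tier_a", "tier_b") %in% names(shared))) {
    sig_a <- shared$tier_a %in% c("highly_significant", "significant")
    sig_b <- shared$tier_b %in% c("highly_significant", "significant")
    shared[sig_a & !sig_b,
           c("feature_id", "log2FC_a", "log2FC_b", "tier_a", "tier_b"),
           drop = FALSE]
  } else {
    NULL
  }
  list(r = r, n_shared = nrow(shared), divergent = divergent)
}
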