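# Synthetic proteomes and quantification tables with planted ground truth.
# Every generator is deterministic under its seed; a master seed spawns
# per-stage child seeds at fixed offsets so stages can be rerun in isolation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Background amino-acid frequencies loosely following vertebrate proteome
# averages; IDRs get proline/glutamate/serine/glycine boosted, domains get
# hydrophobics boosted, so composition-enrichment recovery is testable.
.aa_background <- function() {
  f <- c(A = 7.0, C = 2.0, D = 5.0, E = 6.5, F = 3.8, G = 6.5, H = 2.5,
         I = 4.5, K = 5.8, L = 9.5, M = 2.2, N = 3.8, P = 5.5, Q = 4.5,
         R = 5.5, S = 7.5, T = 5.5, V = 6.0, W = 1.2, Y = 3.0)
  f / sum(f)
}

.aa_idr <- function() {
  f <- .aa_background()
  f[c("P", "E", "S", "G")] <- f[c("P", "E", "S", "G")] * 2.5
  f[c("L", "I", "V", "F", "W", "M")] <- f[c("L", "I", "V", "F", "W", "M")] * 0.4
  f / sum(f)
}

.aa_domain <- function() {
  f <- .aa_background()
  f[c("L", "I", "V", "F", "W", "M")] <- f[c("L", "I", "V", "F", "W", "M")] * 1.8
  f[c("P", "E", "S", "G")] <- f[c("P", "E", "S", "G")] * 0.6
  f / sum(f)
}

.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647)
}

#' Generate a synthetic proteome with domain and IDR annotations
#'
#' Draws `n_proteins` random amino-acid sequences. Each protein gets
#' 0 to `max_regions` non-overlapping regions, each classed `domain`
#' or `IDR`; IDR segments are resampled with elevated P/E/S/G
#' composition and domains with elevated hydrophobic composition.
#' A subset of proteins is planted as chromatin binders; each planted
#' protein receives one contact region (by default inside an IDR) that
#' downstream simulators treat as its chromatin interface.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param seed Integer seed; same seed gives byte-identical output.
#' @param length_mean,length_sd Log-normal protein length parameters
#'   (residues); lengths are clamped to `[60, 2000]`.
#' @param max_regions Maximum regions per protein (0-3 typical).
#' @param frac_planted Fraction of proteins planted as chromatin
#'   binders.
#' @param contact_class Region class the planted contact region lives
#'   in: `"IDR"` or `"domain"`.
#' @param effect_log2 Planted log2 enrichment (protein level and
#'   contact-peptide level).
#' @param domain_names Pool of names given to generated domains;
#'   planted contact domains are named from `contact_domain_name`.
#' @param contact_domain_name Name used for regions hosting planted
#'   contacts (numbered suffixes are appended, mimicking signature
#'   families).
#' @return List with elements `sequences` (named character vector),
#'   `regions` (a `region_annotation` data frame), and `truth` (class
#'   `synthetic_truth`: `seed`, `chromatin_protein_ids`,
#'   `contact_regions`, `protein_effects`, `effect_log2`).
#' @export
generate_proteome <- function(n_proteins,
                              seed = 1L,
                              length_mean = 450,
                              length_sd = 180,
                              max_regions = 3L,
                              frac_planted = 0.1,
                              contact_class = c("IDR", "domain"),
                              effect_log2 = 2,
                              domain_names = c("PF_kinase", "PF_helicase", "ZnF_C2H2",
                                               "WD40", "PDZ", "SH3"),
                              contact_domain_name = "RRM") {
  stopifnot(n_proteins >= 1)
  contact_class <- match.arg(contact_class)
  set.seed(.child_seed(seed, 1L))

  mu <- log(length_mean^2 / sqrt(length_mean^2 + length_sd^2))
  sig <- sqrt(log(1 + (length_sd / length_mean)^2))
  lens <- pmin(2000L, pmax(60L, as.integer(round(stats::rlnorm(n_proteins, mu, sig)))))
  ids <- sprintf("SYN%04d", seq_len(n_proteins))

  n_planted <- round(frac_planted * n_proteins)
  planted <- if (n_planted > 0) sample(ids, n_planted) else character(0)

  bg <- .aa_background(); fidr <- .aa_idr(); fdom <- .aa_domain()
  seqs <- character(n_proteins); names(seqs) <- ids
  reg_rows <- list(); contact_rows <- list()

  for (i in seq_len(n_proteins)) {
    L <- lens[i]
    chars <- sample(AA20, L, replace = TRUE, prob = bg)
    n_reg <- sample.int(max_regions + 1L, 1L) - 1L
    is_planted <- ids[i] %in% planted
    if (is_planted && n_reg == 0L) n_reg <- 1L
    regs <- list()
    if (n_reg > 0L) {
      # carve non-overlapping windows left to right with >= 5-residue spacers
      cursor <- 1L
      for (r in seq_len(n_reg)) {
        w <- sample(30:90, 1L)
        lo_max <- L - w + 1L
        if (cursor > lo_max) break
        s <- cursor + sample.int(max(1L, min(40L, lo_max - cursor + 1L)), 1L) - 1L
        if (s > lo_max) break
        e <- s + w - 1L
        cls <- sample(c("domain", "IDR"), 1L)
        regs[[length(regs) + 1L]] <- list(start = s, end = e, class = cls)
        cursor <- e + 6L
      }
    }
    if (is_planted) {
      # ensure at least one region of the contact class; retag the first if needed
      has <- vapply(regs, function(r) r$class == contact_class, logical(1))
      if (length(regs) == 0L) {
        w <- min(60L, L - 10L)
        regs <- list(list(start = 5L, end = 4L + w, class = contact_class))
        has <- TRUE
      } else if (!any(has)) {
        regs[[1L]]$class <- contact_class
        has <- c(TRUE, rep(FALSE, length(regs) - 1L))
      }
      contact_idx <- which(has)[1L]
    }
    for (r in seq_along(regs)) {
      rg <- regs[[r]]
      prof <- if (rg$class == "IDR") fidr else fdom
      chars[rg$start:rg$end] <- sample(AA20, rg$end - rg$start + 1L,
                                       replace = TRUE, prob = prof)
      nm <- if (is_planted && r == contact_idx && rg$class == "domain") {
        sprintf("%s_%d", contact_domain_name, sample.int(4L, 1L))
      } else if (rg$class == "IDR") "disorder_prediction"
      else sample(domain_names, 1L)
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        protein_id = ids[i], start = rg$start, end = rg$end,
        region_class = rg$class, name = nm,
        source_signature = if (rg$class == "IDR") "MobiDBLite" else nm,
        stringsAsFactors = FALSE)
      if (is_planted && r == contact_idx) {
        contact_rows[[length(contact_rows) + 1L]] <- data.frame(
          protein_id = ids[i], start = rg$start, end = rg$end,
          region_class = rg$class, stringsAsFactors = FALSE)
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }

  regions <- if (length(reg_rows) > 0) do.call(rbind, reg_rows) else
    data.frame(protein_id = character(0), start = integer(0), end = integer(0),
               region_class = character(0), name = character(0),
               source_signature = character(0), stringsAsFactors = FALSE)
  if (nrow(regions) > 0) {
    regions <- cbind(region_id = sprintf("reg%05d", seq_len(nrow(regions))),
                     regions, stringsAsFactors = FALSE)
  } else {
    regions$region_id <- character(0)
    regions <- regions[, c("region_id", "protein_id", "start", "end",
                           "region_class", "name", "source_signature")]
  }
  class(regions) <- c("region_annotation", "data.frame")

  contacts <- if (length(contact_rows) > 0) do.call(rbind, contact_rows) else
    data.frame(protein_id = character(0), start = integer(0), end = integer(0),
               region_class = character(0), stringsAsFactors = FALSE)

  truth <- structure(list(
    seed = seed,
    chromatin_protein_ids = sort(planted),
    contact_regions = contacts,
    protein_effects = stats::setNames(
      ifelse(ids %in% planted, effect_log2, 0), ids),
    effect_log2 = effect_log2
  ), class = "synthetic_truth")

  list(sequences = seqs, regions = regions, truth = truth)
}

#' In-silico proteolytic digestion
#'
#' Enumerates all peptides obtainable with at most `max_missed`
#' internal missed cleavages, keeping those whose length falls within
#' `[min_length, max_length]`. Trypsin/P cleaves C-terminal to K or R
#' (proline does not block); LysC cleaves C-terminal to K, a subset of
#' the Trypsin/P sites, so the default enzyme combination cuts after
#' every K and R.
#'
#' @param sequence Non-empty amino-acid string.
#' @param max_missed Maximum internal missed cleavage sites (>= 0).
#' @param min_length,max_length Peptide length bounds in residues.
#' @param enzymes Character vector from `c("trypsin_P", "lysC")`.
#' @return Data frame with `sequence`, `start`, `end` (1-based
#'   inclusive), `n_missed`.
#' @export
digest <- function(sequence, max_missed = 2L, min_length = 7L, max_length = 35L,
                   enzymes = c("trypsin_P", "lysC")) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("digest: sequence must be a non-empty amino-acid string")
  }
  stopifnot(min_length <= max_length, max_missed >= 0)
  enzymes <- match.arg(enzymes, several.ok = TRUE)
  residues <- if ("trypsin_P" %in% enzymes) c("K", "R") else "K"
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  # cut points after position i; sequence end is always a boundary
  cuts <- which(chars %in% residues)
  bounds <- sort(unique(c(0L, cuts[cuts < L], L)))
  n_frag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(n_frag)) {
    for (j in i:min(n_frag, i + max_missed)) {
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len >= min_length && len <= max_length) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = substr(sequence, s, e), start = s, end = e,
          n_missed = j - i, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), n_missed = integer(0)))
  }
  do.call(rbind, rows)
}

#' Digest a whole proteome into a peptide coordinate table
#'
#' @param sequences Named character vector of protein sequences.
#' @param ... Passed to [digest()].
#' @return Data frame with `peptide_id`, `protein_id`, `sequence`,
#'   `start`, `end`, `n_missed`.
#' @export
digest_proteome <- function(sequences, ...) {
  parts <- lapply(names(sequences), function(id) {
    d <- digest(sequences[[id]], ...)
    if (nrow(d) == 0) return(NULL)
    cbind(protein_id = id, d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), sequence = character(0),
                      start = integer(0), end = integer(0), n_missed = integer(0))
  }
  cbind(peptide_id = sprintf("pep%06d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

# Draw per-feature variances from a scaled inverse chi-square law:
# sigma^2 = d0 * s0sq / chisq(d0). d0 = Inf means constant variance s0sq.
.draw_sigma2 <- function(n, d0, s0sq) {
  if (is.infinite(d0)) return(rep(s0sq, n))
  d0 * s0sq / stats::rchisq(n, df = d0)
}

# Missingness probability decreasing in intensity: logistic in -log2(I).
.p_missing <- function(log2_intensity, miss_mid, miss_scale) {
  stats::plogis((miss_mid - log2_intensity) / miss_scale)
}

#' Simulate a protein-level SILAC chromatin-enrichment experiment
#'
#' Generates heavy/light SILAC ratios per experiment plus iBAQ columns.
#' Planted chromatin proteins are centred on `2^effect` in forward
#' experiments (heavy = crosslinked) and `2^-effect` in reverse
#' experiments (light = crosslinked); everything else on 1. Per-protein
#' log-ratio noise variance is drawn from a scaled inverse chi-square
#' law with parameters `d0_true`, `s0sq_true`; missingness probability
#' decreases with intensity.
#'
#' @param truth A `synthetic_truth` object from [generate_proteome()].
#' @param design Data frame with columns `experiment` (unique labels)
#'   and `orientation` (`"forward"`/`"reverse"`); default two forward
#'   and six reverse experiments.
#' @param seed Integer seed.
#' @param d0_true,s0sq_true Noise-variance hyperparameters (log2-ratio
#'   scale).
#' @param baseline_log2,baseline_sd Abundance model for iBAQ (log2).
#' @param miss_mid,miss_scale Missingness logistic midpoint/scale on
#'   the log2-intensity axis; `miss_scale = 0` disables missingness.
#' @param noise Set `FALSE` to plant effects with zero noise (model
#'   identity checks).
#' @return A `protein_quant` data frame with `ratio_<experiment>` and
#'   `ibaq_<experiment>` columns, plus the all-FALSE flag columns.
#' @export
simulate_space_experiment <- function(truth,
                                      design = default_silac_design(),
                                      seed = truth$seed,
                                      d0_true = 4, s0sq_true = 0.25,
                                      baseline_log2 = 25, baseline_sd = 2,
                                      miss_mid = 21, miss_scale = 1,
                                      noise = TRUE) {
  stopifnot(nrow(design) >= 1)
  if (!all(design$orientation %in% c("forward", "reverse"))) {
    stop("simulate_space_experiment: orientation must be 'forward' or 'reverse'")
  }
  set.seed(.child_seed(seed, 2L))
  ids <- names(truth$protein_effects)
  n <- length(ids)
  eff <- truth$protein_effects
  sigma2 <- if (noise) .draw_sigma2(n, d0_true, s0sq_true) else rep(0, n)
  base <- stats::rnorm(n, baseline_log2, baseline_sd)

  out <- data.frame(protein_id = ids,
                    gene_name = sub("^SYN", "Gene", ids),
                    is_reverse_decoy = FALSE, is_contaminant = FALSE,
                    only_identified_by_site = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(design))) {
    orient <- design$orientation[k]
    sgn <- if (orient == "forward") 1 else -1
    log2_ratio <- sgn * eff + stats::rnorm(n, 0, sqrt(sigma2))
    log2_ibaq <- base + stats::rnorm(n, 0, if (noise) 0.3 else 0)
    if (noise && miss_scale > 0) {
      miss <- stats::runif(n) < .p_missing(log2_ibaq, miss_mid, miss_scale)
      log2_ratio[miss] <- NA_real_
      log2_ibaq[miss] <- NA_real_
    }
    lab <- gsub("[^A-Za-z0-9]+", "_", design$experiment[k])
    out[[paste0("ratio_", lab)]] <- 2^log2_ratio
    out[[paste0("ibaq_", lab)]] <- 2^log2_ibaq
  }
  class(out) <- c("protein_quant", "data.frame")
  out
}

#' Default SILAC design: two forward and six reverse experiments
#'
#' @return Data frame with columns `experiment` and `orientation`.
#' @export
default_silac_design <- function() {
  data.frame(
    experiment = c("F1", "F2", paste0("R", 1:6)),
    orientation = c("forward", "forward", rep("reverse", 6)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a crosslinked-vs-released peptide fractionation experiment
#'
#' Peptides overlapping a planted contact region (or lying within
#' `max_gap` residues of one) get crosslinked-fraction intensities
#' elevated by the planted effect; all other peptides get the same
#' elevation in the released fraction. Noise and intensity-dependent
#' missingness as in [simulate_space_experiment()].
#'
#' @param truth A `synthetic_truth` object.
#' @param peptides Peptide coordinate table from [digest_proteome()].
#' @param n_replicates Replicates per fraction.
#' @param max_gap Residue gap within which a peptide counts as
#'   contacting a planted region.
#' @inheritParams simulate_space_experiment
#' @return A `peptide_quant` data frame with
#'   `intensity_crosslinked_<i>` and `intensity_released_<i>` columns;
#'   attribute `is_contact` holds the per-peptide truth flag.
#' @export
simulate_spacemap_experiment <- function(truth, peptides, n_replicates = 3L,
                                         seed = truth$seed,
                                         max_gap = 10L,
                                         d0_true = 4, s0sq_true = 0.25,
                                         baseline_log2 = 25, baseline_sd = 2,
                                         miss_mid = 21, miss_scale = 1,
                                         noise = TRUE) {
  set.seed(.child_seed(seed, 3L))
  n <- nrow(peptides)
  cr <- truth$contact_regions
  is_contact <- rep(FALSE, n)
  if (nrow(cr) > 0) {
    for (i in seq_len(nrow(cr))) {
      same <- peptides$protein_id == cr$protein_id[i]
      gap <- pmax(0L, cr$start[i] - peptides$end, peptides$start - cr$end[i])
      is_contact <- is_contact | (same & gap <= max_gap)
    }
  }
  eff <- ifelse(is_contact, truth$effect_log2, 0)
  # non-contact peptides are released-enriched: depleted from the
  # crosslinked fraction by the same planted effect
  shift_cross <- ifelse(is_contact, eff / 2, -truth$effect_log2 / 2)
  shift_rel <- -shift_cross
  sigma2 <- if (noise) .draw_sigma2(n, d0_true, s0sq_true) else rep(0, n)
  base <- stats::rnorm(n, baseline_log2, if (noise) baseline_sd else 0)

  out <- peptides
  for (fr in c("crosslinked", "released")) {
    shift <- if (fr == "crosslinked") shift_cross else shift_rel
    for (r in seq_len(n_replicates)) {
      v <- base + shift + stats::rnorm(n, 0, sqrt(sigma2))
      if (noise && miss_scale > 0) {
        v[stats::runif(n) < .p_missing(v, miss_mid, miss_scale)] <- NA_real_
      }
      out[[sprintf("intensity_%s_%d", fr, r)]] <- 2^v
    }
  }
  attr(out, "is_contact") <- stats::setNames(is_contact, peptides$peptide_id)
  class(out) <- c("peptide_quant", "data.frame")
  out
}

#' Synthetic GO-style annotations matching planted truth
#'
#' Planted chromatin proteins receive chromatin-related GO terms (so
#' keyword classification recovers them by construction); a configurable
#' fraction of the rest receive nuclear or cytoplasmic/translation
#' terms. Planted proteins additionally receive "RNA binding" with
#' probability `p_rbp`.
#'
#' @param truth A `synthetic_truth` object.
#' @param seed Integer seed.
#' @param p_rbp Probability a planted protein is also an RBP.
#' @return Data frame with `protein_id`, `go_terms`, `keywords`
#'   (semicolon-separated), suitable for [categorize_proteins()].
#' @export
simulate_annotations <- function(truth, seed = truth$seed, p_rbp = 0.5) {
  set.seed(.child_seed(seed, 4L))
  ids <- names(truth$protein_effects)
  planted <- ids %in% truth$chromatin_protein_ids
  go <- character(length(ids))
  for (i in seq_along(ids)) {
    if (planted[i]) {
      terms <- c("chromatin binding", "nucleus")
      if (stats::runif(1) < p_rbp) terms <- c(terms, "RNA binding")
    } else {
      terms <- switch(sample.int(3L, 1L),
                      c("nucleus", "mRNA processing"),
                      c("cytoplasm", "translation"),
                      c("plasma membrane", "cell adhesion"))
    }
    go[i] <- paste(terms, collapse = ";")
  }
  data.frame(protein_id = ids, go_terms = go, keywords = "",
             stringsAsFactors = FALSE)
}
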