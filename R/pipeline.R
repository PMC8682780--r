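# Pipeline orchestration: a single YAML scenario drives simulation and/or
# analysis, every filter stage logs its input/output counts, and outputs
# are written as TSV plus a machine-readable JSON run log.

PIPELINE_MODES <- c("space_silac", "sicap_ibaq", "spacemap",
                    "comparative_silac", "chip_space", "two_group_labelfree")

#' Read and validate a pipeline configuration
#'
#' @param path YAML file; see [default_pipeline_config()] for the
#'   recognized fields.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Default pipeline configuration (synthetic spacemap scenario)
#'
#' @param mode One of the pipeline modes.
#' @param seed Integer master seed.
#' @return Config list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(mode = "spacemap", seed = 1L) {
  list(
    mode = mode,
    seed = seed,
    simulate = list(
      n_proteins = 500L,
      frac_planted = 0.1,
      effect_log2 = 2,
      contact_class = "IDR",
      n_replicates = 3L
    ),
    thresholds = list(fc = 1, tier1_alpha = 0.01, tier2_alpha = 0.1),
    max_gap = 10L
  )
}

#' @rdname read_pipeline_config
#' @param config Config list to validate.
#' @export
validate_pipeline_config <- function(config) {
  if (is.null(config$mode) || !config$mode %in% PIPELINE_MODES) {
    stop(sprintf("config error: mode must be one of %s",
                 paste(PIPELINE_MODES, collapse = ", ")), call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  defaults <- default_pipeline_config(config$mode, config$seed)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- defaults[[nm]][[sub]]
      }
    }
  }
  th <- config$thresholds
  if (!(th$tier1_alpha <= th$tier2_alpha)) {
    stop("config error: tier1_alpha must be <= tier2_alpha", call. = FALSE)
  }
  config
}

.log_stage <- function(log, stage, n_in, n_out, params = list()) {
  log[[length(log) + 1]] <- list(stage = stage, n_in = n_in, n_out = n_out,
                                 params = params,
                                 time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  log
}

#' Run the enrichment/mapping pipeline on a scenario configuration
#'
#' Generates (or loads) the inputs, runs the stages selected by
#' `config$mode` and returns all result tables together with a run
#' log recording every stage's input and output counts. With the
#' default synthetic scenario:
#' \itemize{
#'   \item protein level — SILAC forward/reverse simulation, ratio
#'     assembly, forward+reverse evidence filter, moderated one-sample
#'     t-test, BH, two-tier calls;
#'   \item peptide level (spacemap mode) — proteome digestion,
#'     crosslinked/released simulation, group-wise quantile
#'     normalization, all-missing-fraction minimum imputation,
#'     moderated two-group t-test, tier calls, peptide-to-region
#'     matching, contact summaries, domain-type ranking and
#'     composition enrichment.
#' }
#'
#' @param config Config list (see [default_pipeline_config()]), or a
#'   path to a YAML file.
#' @param outdir Optional directory: result tables are written as TSV
#'   and the run log as JSON. Written atomically (to a temporary name,
#'   then renamed).
#' @return List of class `pipeline_run`: `config`, `truth`, result
#'   tables (`protein_results`, and in spacemap mode
#'   `peptide_results`, `matches`, `contact_summary`, `domain_ranking`,
#'   `composition`), and `run_log`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  seed <- config$seed
  sim <- config$simulate
  th <- config$thresholds
  log <- list()

  prot <- generate_proteome(n_proteins = sim$n_proteins, seed = seed,
                            frac_planted = sim$frac_planted,
                            contact_class = sim$contact_class,
                            effect_log2 = sim$effect_log2)
  log <- .log_stage(log, "generate_proteome", sim$n_proteins, sim$n_proteins,
                    sim[c("frac_planted", "effect_log2", "contact_class")])

  # --- protein-level SILAC enrichment ---
  design <- default_silac_design()
  ptab <- simulate_space_experiment(prot$truth, design = design, seed = seed)
  ptab <- filter_quant_records(ptab)
  log <- .log_stage(log, "filter_quant_records", sim$n_proteins, nrow(ptab))
  ratios <- assemble_log_ratios(ptab, design)
  kept <- filter_min_evidence(ratios, "forward_and_reverse", design = design)
  log <- .log_stage(log, "filter_min_evidence", nrow(ratios), nrow(kept),
                    list(rule = "forward_and_reverse"))
  pres <- moderated_t_test(kept, "one_sample_ratio")
  tier2_only <- config$mode %in% c("comparative_silac", "chip_space")
  pres <- classify_tiers(pres, fc_threshold = th$fc,
                         tier1_alpha = if (tier2_only) th$tier2_alpha else th$tier1_alpha,
                         tier2_alpha = th$tier2_alpha)
  log <- .log_stage(log, "moderated_t_test_protein", nrow(kept), nrow(pres),
                    list(mode = "one_sample_ratio"))
  out <- list(config = config, truth = prot$truth, regions = prot$regions,
              protein_results = pres)

  if (config$mode == "spacemap") {
    peptides <- digest_proteome(prot$sequences)
    log <- .log_stage(log, "digest_proteome", length(prot$sequences), nrow(peptides))
    pep_tab <- simulate_spacemap_experiment(prot$truth, peptides,
                                            n_replicates = sim$n_replicates,
                                            seed = seed, max_gap = config$max_gap)
    int_cols <- grep("^intensity_", names(pep_tab), value = TRUE)
    m <- log2(as.matrix(pep_tab[, int_cols]))
    rownames(m) <- pep_tab$peptide_id
    fraction <- ifelse(grepl("crosslinked", int_cols), "crosslinked", "released")
    m <- quantile_normalize(m, fraction)
    m <- impute_intensities(m, fraction, rule = "spacemap_peptide")
    kept_pep <- filter_min_evidence(m, "min_k_replicates", k = 2L)
    log <- .log_stage(log, "filter_min_evidence_peptide", nrow(m), nrow(kept_pep),
                      list(rule = "min_k_replicates", k = 2))
    res <- moderated_t_test(kept_pep, "two_group",
                            groups = fraction[match(colnames(kept_pep), colnames(m))])
    res <- classify_tiers(res, fc_threshold = th$fc,
                          tier1_alpha = th$tier1_alpha, tier2_alpha = th$tier2_alpha)
    res <- merge(res,
                 peptides[, c("peptide_id", "protein_id", "sequence", "start", "end")],
                 by.x = "feature_id", by.y = "peptide_id", sort = FALSE)
    log <- .log_stage(log, "moderated_t_test_peptide", nrow(kept_pep), nrow(res),
                      list(mode = "two_group"))

    consensus <- consensus_merge(prot$regions)
    enriched <- res[res$tier != "not_significant", , drop = FALSE]
    enriched <- data.frame(peptide_id = enriched$feature_id,
                           protein_id = enriched$protein_id,
                           start = enriched$start, end = enriched$end,
                           sequence = enriched$sequence,
                           stringsAsFactors = FALSE)
    matches <- match_peptide_to_regions(enriched, consensus,
                                        max_gap = config$max_gap)
    log <- .log_stage(log, "match_peptide_to_regions", nrow(enriched), nrow(matches),
                      list(max_gap = config$max_gap))
    summary <- summarize_protein_contacts(enriched, matches)
    ranking <- rank_domain_types(matches[matches$region_class == "domain", ,
                                         drop = FALSE])
    # composition: crosslinked-enriched IDR-mapped vs released-enriched IDR-mapped
    rel <- res[res$log2FC < -th$fc & !is.na(res$adj_p) &
                 res$adj_p < th$tier2_alpha, , drop = FALSE]
    rel_pep <- data.frame(peptide_id = rel$feature_id, protein_id = rel$protein_id,
                          start = rel$start, end = rel$end,
                          sequence = rel$sequence, stringsAsFactors = FALSE)
    # composition: crosslinked-enriched IDR-mapped peptides against the
    # released-enriched peptides (the generator draws every IDR from one
    # composition profile, so the IDR bias shows against the released set
    # as a whole, not against the IDR-mapped subset of it)
    comp <- NULL
    q_idr <- enriched$sequence[enriched$peptide_id %in%
                                 matches$peptide_id[matches$region_class == "IDR"]]
    if (length(q_idr) > 0 && nrow(rel_pep) > 0) {
      comp <- composition_enrichment(q_idr, rel_pep$sequence)
    }
    out$peptide_results <- res
    out$matches <- matches
    out$contact_summary <- summary
    out$domain_ranking <- ranking
    out$composition <- comp
  }

  out$run_log <- log
  class(out) <- "pipeline_run"
  if (!is.null(outdir)) .write_run(out, outdir)
  out
}

.write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_atomic <- function(obj, name, writer) {
    tmp <- file.path(outdir, paste0(".", name, ".tmp"))
    writer(obj, tmp)
    file.rename(tmp, file.path(outdir, name))
  }
  tables <- c("protein_results", "peptide_results", "matches",
              "domain_ranking", "composition")
  for (nm in tables) {
    if (!is.null(run[[nm]])) write_atomic(run[[nm]], paste0(nm, ".tsv"),
                                          write_result_tsv)
  }
  if (!is.null(run$contact_summary)) {
    write_atomic(run$contact_summary$per_protein, "contact_summary.tsv",
                 write_result_tsv)
  }
  write_atomic(run$run_log, "run_log.json", function(obj, path) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(outdir)
}

#' Summarize a completed run into report tables
#'
#' All report numbers are recomputed from the result tables, so the
#' report can be regenerated from the TSV outputs alone.
#'
#' @param run A `pipeline_run` list (or a subset of its tables).
#' @return List of data frames: `tier_counts` (per level, protein and
#'   peptide), `contact_fractions`, `top_domain_types`, `composition`.
#'   Missing tables produce a partial report with a warning.
#' @export
make_report <- function(run) {
  report <- list()
  tier_tab <- function(res, level) {
    tiers <- c("highly_significant", "significant", "not_significant")
    counts <- if (is.null(res)) rep(0L, 3) else
      as.integer(table(factor(res$tier, levels = tiers)))
    data.frame(level = level, tier = tiers, n = counts, stringsAsFactors = FALSE)
  }
  report$tier_counts <- rbind(tier_tab(run$protein_results, "protein"),
                              tier_tab(run$peptide_results, "peptide"))
  if (!is.null(run$contact_summary)) {
    agg <- run$contact_summary$aggregate
    report$contact_fractions <- data.frame(quantity = names(agg),
                                           fraction = as.numeric(agg),
                                           stringsAsFactors = FALSE)
  } else {
    warning("make_report: contact summary missing; partial report")
  }
  if (!is.null(run$domain_ranking)) {
    report$top_domain_types <- utils::head(run$domain_ranking, 5)
  }
  if (!is.null(run$composition)) report$composition <- run$composition
  report
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> mode=%s seed=%d\n", x$config$mode, x$config$seed))
  for (entry in x$run_log) {
    cat(sprintf("  %-28s %6d -> %6d\n", entry$stage, entry$n_in, entry$n_out))
  }
  invisible(x)
}
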