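#' Default column-name dialect for MaxQuant 1.6 tables
#'
#' Maps the logical fields of a protein-group or peptide table to the
#' column names found in the input file. Pass a modified copy of this
#' list to the readers to ingest tables from other search engines.
#'
#' @param type `"protein_groups"` or `"peptides"`.
#' @return Named list of column names and column-name prefixes.
#' @export
maxquant_dialect <- function(type = c("protein_groups", "peptides")) {
  type <- match.arg(type)
  if (type == "protein_groups") {
    list(
      protein_id              = "Protein IDs",
      gene_name               = "Gene names",
      is_reverse_decoy        = "Reverse",
      is_contaminant          = "Potential contaminant",
      only_identified_by_site = "Only identified by site",
      ratio_prefix            = "Ratio H/L ",
      ibaq_prefix             = "iBAQ "
    )
  } else {
    list(
      peptide_id       = "id",
      protein_id       = "Leading razor protein",
      sequence         = "Sequence",
      start            = "Start position",
      end              = "End position",
      intensity_prefix = "Intensity "
    )
  }
}

# "+" marks a set flag in MaxQuant tables; anything else (including NA) is unset
.flag_col <- function(df, col) {
  if (is.null(col) || !col %in% names(df)) return(rep(FALSE, nrow(df)))
  !is.na(df[[col]]) & df[[col]] == "+"
}

# MaxQuant writes 0 for "not quantified": zeros in intensity-like columns are
# missing values, not measurements.
.num_na0 <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  x[!is.na(x) & x == 0] <- NA_real_
  x
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(unlist(cols), names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: required column(s) missing from input: %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read a protein-group quantification table
#'
#' Parses a tab-separated MaxQuant-style `proteinGroups` table into a
#' `protein_quant` data frame with one row per protein group. SILAC
#' ratio columns (`Ratio H/L <experiment>`) become `ratio_<experiment>`
#' and iBAQ columns become `ibaq_<sample>`. Zeros in numeric
#' quantification columns are converted to `NA` (MaxQuant writes 0 for
#' absence). Decoy/contaminant/site-only flags become logical columns.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Column-name mapping, see [maxquant_dialect()].
#' @return A data frame of class `protein_quant` with columns
#'   `protein_id`, `gene_name`, the three flag columns, `ratio_*` and
#'   `ibaq_*`.
#' @export
read_protein_groups <- function(path, dialect = maxquant_dialect("protein_groups")) {
  df <- .read_tsv(path)
  if (!dialect$protein_id %in% names(df)) {
    stop(sprintf("protein groups table: protein id column '%s' not found",
                 dialect$protein_id), call. = FALSE)
  }
  out <- data.frame(
    protein_id = as.character(df[[dialect$protein_id]]),
    gene_name = if (dialect$gene_name %in% names(df))
      as.character(df[[dialect$gene_name]]) else NA_character_,
    is_reverse_decoy        = .flag_col(df, dialect$is_reverse_decoy),
    is_contaminant          = .flag_col(df, dialect$is_contaminant),
    only_identified_by_site = .flag_col(df, dialect$only_identified_by_site),
    stringsAsFactors = FALSE
  )
  for (prefix in c(ratio = dialect$ratio_prefix, ibaq = dialect$ibaq_prefix)) {
    hit <- startsWith(names(df), prefix)
    # avoid derived columns like "Ratio H/L normalized ..."/"iBAQ peptides"
    hit <- hit & !grepl("normalized|variability|count|peptides",
                        names(df), ignore.case = TRUE)
    for (col in names(df)[hit]) {
      label <- gsub("[^A-Za-z0-9]+", "_", sub(prefix, "", col, fixed = TRUE))
      kind <- if (identical(prefix, dialect$ratio_prefix)) "ratio" else "ibaq"
      out[[paste(kind, label, sep = "_")]] <- .num_na0(df[[col]])
    }
  }
  if (anyDuplicated(out$protein_id)) {
    warning("duplicated protein ids in protein groups table")
  }
  class(out) <- c("protein_quant", "data.frame")
  out
}

#' Read a peptide quantification table
#'
#' Parses a tab-separated MaxQuant-style `peptides` table into a
#' `peptide_quant` data frame. Intensity columns
#' (`Intensity <sample>`) become `intensity_<sample>`; zeros become
#' `NA`. Coordinates are 1-based inclusive residue positions in the
#' parent protein.
#'
#' @inheritParams read_protein_groups
#' @return A data frame of class `peptide_quant` with columns
#'   `peptide_id`, `protein_id`, `sequence`, `start`, `end` and
#'   `intensity_*`.
#' @export
read_peptides <- function(path, dialect = maxquant_dialect("peptides")) {
  df <- .read_tsv(path)
  .require_cols(df, dialect[c("protein_id", "sequence", "start", "end")],
                "peptide table")
  out <- data.frame(
    peptide_id = if (dialect$peptide_id %in% names(df))
      as.character(df[[dialect$peptide_id]]) else sprintf("pep%06d", seq_len(nrow(df))),
    protein_id = as.character(df[[dialect$protein_id]]),
    sequence   = as.character(df[[dialect$sequence]]),
    start      = as.integer(df[[dialect$start]]),
    end        = as.integer(df[[dialect$end]]),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(out$start) & !is.na(out$end) &
    (out$end - out$start + 1L) != nchar(out$sequence)
  if (any(bad)) {
    warning(sprintf("%d peptide(s) with coordinates inconsistent with sequence length",
                    sum(bad)))
  }
  for (col in names(df)[startsWith(names(df), dialect$intensity_prefix)]) {
    label <- gsub("[^A-Za-z0-9]+", "_",
                  sub(dialect$intensity_prefix, "", col, fixed = TRUE))
    out[[paste0("intensity_", label)]] <- .num_na0(df[[col]])
  }
  class(out) <- c("peptide_quant", "data.frame")
  out
}

#' Remove decoy, contaminant and site-only protein groups
#'
#' Drops records flagged as reverse decoys, potential contaminants or
#' identified only by a modification site. The removal count is
#' reported via `message()` and attached as attribute `n_removed`.
#'
#' @param table A `protein_quant` data frame (see
#'   [read_protein_groups()]).
#' @return The filtered table; idempotent.
#' @export
filter_quant_records <- function(table) {
  need <- c("is_reverse_decoy", "is_contaminant", "only_identified_by_site")
  .require_cols(table, need, "filter_quant_records")
  keep <- !(table$is_reverse_decoy | table$is_contaminant |
              table$only_identified_by_site)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_removed <- sum(!keep)
  message(sprintf("filter_quant_records: removed %d of %d records",
                  n_removed, nrow(table)))
  attr(out, "n_removed") <- n_removed
  out
}

#' Signature classes treated as IDR predictors by default
#'
#' InterProScan "analysis" values whose matches describe intrinsically
#' disordered regions rather than folded domains, plus match
#' descriptions excluded altogether (low-complexity, coils and similar
#' non-domain features).
#'
#' @return List with elements `idr_sources` and `exclude_sources`.
#' @export
default_region_config <- function() {
  list(
    idr_sources = c("MobiDBLite", "MobiDB-lite", "DisProt", "IUPred"),
    exclude_sources = c("Coils", "SignalP", "SignalP_GRAM_POSITIVE",
                        "SignalP_GRAM_NEGATIVE", "TMHMM", "Phobius", "SEG")
  )
}

#' Read domain/IDR annotations from an InterProScan-style table
#'
#' Expects a tab-separated file with (at least) the columns
#' `protein_id`, `source` (analysis/signature database), `signature`,
#' `name`, `start`, `end` — coordinates 1-based inclusive. Matches from
#' sources in `config$exclude_sources` are dropped; sources in
#' `config$idr_sources` are classed `IDR`, all others `domain`.
#' Records with `start > end` are rejected with a warning.
#'
#' @param path Path to the annotation table.
#' @param config Signature-to-class configuration, see
#'   [default_region_config()].
#' @return A data frame of class `region_annotation` with columns
#'   `region_id`, `protein_id`, `start`, `end`, `region_class`
#'   (`"domain"` or `"IDR"`), `name`, `source_signature`.
#' @export
read_region_annotations <- function(path, config = default_region_config()) {
  df <- .read_tsv(path)
  .require_cols(df, c("protein_id", "source", "signature", "name", "start", "end"),
                "region annotation table")
  start <- as.integer(df$start); end <- as.integer(df$end)
  bad <- is.na(start) | is.na(end) | start < 1L | start > end
  if (any(bad)) {
    warning(sprintf("rejected %d region annotation(s) with invalid coordinates",
                    sum(bad)))
  }
  df <- df[!bad, , drop = FALSE]
  df <- df[!df$source %in% config$exclude_sources, , drop = FALSE]
  out <- data.frame(
    region_id = sprintf("reg%05d", seq_len(nrow(df))),
    protein_id = as.character(df$protein_id),
    start = as.integer(df$start),
    end = as.integer(df$end),
    region_class = ifelse(df$source %in% config$idr_sources, "IDR", "domain"),
    name = as.character(df$name),
    source_signature = as.character(df$signature),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("region_annotation", "data.frame")
  out
}

#' Read per-protein GO/keyword annotations and assign categories
#'
#' Reads a tab-separated table with columns `protein_id`, `go_terms`
#' and `keywords` (term lists separated by `;`) and applies the
#' keyword-driven categorization of [categorize_proteins()]. Proteins
#' requested via `protein_ids` but absent from the table are returned
#' as `unexpected` with `ptp_pfp = NA`, with a warning.
#'
#' @param path Path to the annotation table.
#' @param keyword_config Keyword sets, see [default_keyword_config()].
#' @param protein_ids Optional character vector of proteins that must
#'   appear in the output even if unannotated.
#' @return A data frame of class `category_annotation`; see
#'   [categorize_proteins()] for the columns.
#' @export
read_category_annotations <- function(path,
                                      keyword_config = default_keyword_config(),
                                      protein_ids = NULL) {
  df <- .read_tsv(path)
  .require_cols(df, c("protein_id", "go_terms", "keywords"), "category annotation table")
  ann <- data.frame(protein_id = as.character(df$protein_id),
                    go_terms = as.character(df$go_terms),
                    keywords = as.character(df$keywords),
                    stringsAsFactors = FALSE)
  if (!is.null(protein_ids)) {
    absent <- setdiff(protein_ids, ann$protein_id)
    if (length(absent) > 0) {
      warning(sprintf("%d protein(s) absent from annotation table; categorized as unexpected",
                      length(absent)))
      ann <- rbind(ann, data.frame(protein_id = absent, go_terms = "",
                                   keywords = "", stringsAsFactors = FALSE))
    }
  }
  categorize_proteins(ann, keyword_config)
}

#' Read or write protein sequences in FASTA format
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()] that move between files and the
#' named character vectors used throughout this package.
#'
#' @param path FASTA file path.
#' @return `read_protein_fasta`: named character vector of amino-acid
#'   sequences (names = protein ids).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' @rdname read_protein_fasta
#' @param sequences Named character vector of amino-acid sequences.
#' @export
write_protein_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Plain tab-separated output with a header row, no quoting and `NA`
#' for missing values, so that a write/read round trip preserves
#' values.
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
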