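# Mapping crosslinked-fraction enriched peptides onto protein domains and
# intrinsically disordered regions (IDRs). All coordinates are 1-based
# inclusive residue positions; the gap between two intervals is the number
# of residues separating their closest boundaries:
#   gap = max(0, region_start - peptide_end, peptide_start - region_end)
# so gap = 0 means overlap and a match requires gap <= max_gap.

#' Merge highly overlapping region annotations into consensus regions
#'
#' Same-protein, same-class regions whose overlap covers at least
#' `overlap_fraction` of the shorter region are merged to their union;
#' merging is iterated to a fixed point, so chains of pairwise-similar
#' regions collapse into one. Names of merged regions are concatenated
#' (unique, sorted). Domains and IDRs are never merged with each other.
#'
#' @param regions A `region_annotation` data frame.
#' @param overlap_fraction Minimum shared fraction of the shorter
#'   region (default 0.7).
#' @return A `region_annotation` data frame of consensus regions,
#'   independent of input order.
#' @export
consensus_merge <- function(regions, overlap_fraction = 0.7) {
  if (nrow(regions) == 0) return(regions)
  parts <- split(regions, paste(regions$protein_id, regions$region_class, sep = "\r"))
  merged <- lapply(parts, function(grp) {
    grp <- grp[order(grp$start, grp$end, grp$name), , drop = FALSE]
    repeat {
      n <- nrow(grp)
      if (n < 2) break
      changed <- FALSE
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          ov <- min(grp$end[i], grp$end[j]) - max(grp$start[i], grp$start[j]) + 1L
          if (ov <= 0) next
          shorter <- min(grp$end[i] - grp$start[i], grp$end[j] - grp$start[j]) + 1L
          if (ov / shorter >= overlap_fraction) {
            grp$start[i] <- min(grp$start[i], grp$start[j])
            grp$end[i] <- max(grp$end[i], grp$end[j])
            nms <- sort(unique(unlist(strsplit(c(grp$name[i], grp$name[j]), ";"))))
            grp$name[i] <- paste(nms, collapse = ";")
            sigs <- sort(unique(unlist(strsplit(
              c(grp$source_signature[i], grp$source_signature[j]), ";"))))
            grp$source_signature[i] <- paste(sigs, collapse = ";")
            grp <- grp[-j, , drop = FALSE]
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
      if (!changed) break
      grp <- grp[order(grp$start, grp$end, grp$name), , drop = FALSE]
    }
    grp
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$protein_id, out$start, out$end, out$region_class), , drop = FALSE]
  out$region_id <- sprintf("creg%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("region_annotation", "data.frame")
  out
}

#' Match peptides to domain/IDR annotations
#'
#' A region matches a peptide if it overlaps it or lies within
#' `max_gap` residues of either peptide end. One match record is
#' produced per (peptide, region) pair with gap <= `max_gap`; a
#' peptide may match several regions, including a domain and an IDR
#' simultaneously.
#'
#' @param peptides Data frame with `peptide_id`, `protein_id`,
#'   `start`, `end` (1-based inclusive).
#' @param regions A `region_annotation` data frame.
#' @param max_gap Maximum residue gap for a proximal match
#'   (default 10).
#' @return Data frame with `peptide_id`, `protein_id`, `region_id`,
#'   `region_class`, `region_name`, `relation` (`"overlap"` or
#'   `"proximal"`) and `gap`.
#' @export
match_peptide_to_regions <- function(peptides, regions, max_gap = 10L) {
  empty <- data.frame(peptide_id = character(0), protein_id = character(0),
                      region_id = character(0), region_class = character(0),
                      region_name = character(0), relation = character(0),
                      gap = integer(0), stringsAsFactors = FALSE)
  if (nrow(peptides) == 0 || nrow(regions) == 0) return(empty)
  shared <- intersect(peptides$protein_id, regions$protein_id)
  rows <- vector("list", length(shared))
  reg_split <- split(seq_len(nrow(regions)), regions$protein_id)
  pep_split <- split(seq_len(nrow(peptides)), peptides$protein_id)
  for (k in seq_along(shared)) {
    pid <- shared[k]
    pi <- pep_split[[pid]]; ri <- reg_split[[pid]]
    # all pairs within one protein, vectorized over the region axis
    pair_pep <- rep(pi, each = length(ri))
    pair_reg <- rep(ri, times = length(pi))
    gap <- pmax(0L,
                regions$start[pair_reg] - peptides$end[pair_pep],
                peptides$start[pair_pep] - regions$end[pair_reg])
    hit <- gap <= max_gap
    if (!any(hit)) next
    rows[[k]] <- data.frame(
      peptide_id = peptides$peptide_id[pair_pep[hit]],
      protein_id = pid,
      region_id = regions$region_id[pair_reg[hit]],
      region_class = regions$region_class[pair_reg[hit]],
      region_name = regions$name[pair_reg[hit]],
      relation = ifelse(gap[hit] == 0L, "overlap", "proximal"),
      gap = as.integer(gap[hit]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Summarize chromatin-contact mapping per protein
#'
#' For each protein carrying crosslinked-fraction enriched peptides,
#' reports which annotation classes its peptides map to and a
#' mapping status (`domain_only`, `IDR_only`, `both`, `unmapped`).
#' Aggregates give the fraction of peptides mapped to any region /
#' domain only / IDR only / both, and the fraction of proteins with at
#' least one IDR-mapped peptide.
#'
#' @param enriched_peptides Data frame of crosslinked-enriched
#'   peptides (`peptide_id`, `protein_id`).
#' @param matches Output of [match_peptide_to_regions()] restricted to
#'   the same peptides.
#' @param intersect_set Optional protein ids to restrict to (e.g.
#'   proteins also enriched at the protein level).
#' @return List with `per_protein` (data frame: `protein_id`,
#'   `n_crosslinked_peptides`, `maps_domain`, `maps_idr`,
#'   `mapping_status`) and `aggregate` (named numeric vector of
#'   fractions).
#' @export
summarize_protein_contacts <- function(enriched_peptides, matches,
                                       intersect_set = NULL) {
  peps <- enriched_peptides
  if (!is.null(intersect_set)) {
    peps <- peps[peps$protein_id %in% intersect_set, , drop = FALSE]
  }
  matches <- matches[matches$peptide_id %in% peps$peptide_id, , drop = FALSE]
  pep_dom <- unique(matches$peptide_id[matches$region_class == "domain"])
  pep_idr <- unique(matches$peptide_id[matches$region_class == "IDR"])

  per_protein <- do.call(rbind, lapply(split(peps, peps$protein_id), function(pp) {
    has_dom <- any(pp$peptide_id %in% pep_dom)
    has_idr <- any(pp$peptide_id %in% pep_idr)
    status <- if (has_dom && has_idr) "both"
      else if (has_dom) "domain_only"
      else if (has_idr) "IDR_only"
      else "unmapped"
    data.frame(protein_id = pp$protein_id[1],
               n_crosslinked_peptides = nrow(pp),
               maps_domain = has_dom, maps_idr = has_idr,
               mapping_status = status, stringsAsFactors = FALSE)
  }))
  if (is.null(per_protein)) {
    per_protein <- data.frame(protein_id = character(0),
                              n_crosslinked_peptides = integer(0),
                              maps_domain = logical(0), maps_idr = logical(0),
                              mapping_status = character(0))
  }
  rownames(per_protein) <- NULL

  n_pep <- nrow(peps)
  in_dom <- peps$peptide_id %in% pep_dom
  in_idr <- peps$peptide_id %in% pep_idr
  aggregate <- c(
    frac_peptides_mapped     = if (n_pep) mean(in_dom | in_idr) else NA_real_,
    frac_peptides_domain_only = if (n_pep) mean(in_dom & !in_idr) else NA_real_,
    frac_peptides_idr_only   = if (n_pep) mean(in_idr & !in_dom) else NA_real_,
    frac_peptides_both       = if (n_pep) mean(in_dom & in_idr) else NA_real_,
    frac_proteins_idr_mapped = if (nrow(per_protein)) mean(per_protein$maps_idr) else NA_real_
  )
  list(per_protein = per_protein, aggregate = aggregate)
}

#' Normalize a domain name to a general domain type
#'
#' Default clustering: case-fold and strip trailing numeric suffixes
#' (`RRM_1`, `RRM_2` -> `rrm`), so signature families collapse into
#' one type. Supply `clustering_map` (named vector: name -> type) to
#' override individual names, e.g. for ontology-based grouping.
#'
#' @param name Character vector of domain names.
#' @param clustering_map Optional named character vector of explicit
#'   name -> type assignments (applied before normalization).
#' @return Character vector of types.
#' @export
normalize_domain_type <- function(name, clustering_map = NULL) {
  out <- name
  if (!is.null(clustering_map)) {
    hit <- out %in% names(clustering_map)
    out[hit] <- clustering_map[out[hit]]
  }
  out <- tolower(out)
  out <- gsub("[ _-]+[0-9]+$", "", out)
  gsub("[ ]+", "_", trimws(out))
}

#' Rank general domain types by distinct matched proteins
#'
#' Clusters the names of regions matched by crosslinked-fraction
#' peptides into general types and counts distinct proteins per type,
#' sorted descending with lexicographic tie-break.
#'
#' @param matches Output of [match_peptide_to_regions()] (typically
#'   restricted to crosslinked-enriched peptides and
#'   `region_class == "domain"`).
#' @param clustering_map Passed to [normalize_domain_type()].
#' @param top Optionally return only the first `top` rows.
#' @return Data frame with `type` and `n_proteins`.
#' @export
rank_domain_types <- function(matches, clustering_map = NULL, top = NULL) {
  if (nrow(matches) == 0) {
    return(data.frame(type = character(0), n_proteins = integer(0)))
  }
  # a merged consensus region may carry several names; count each
  expanded <- data.frame(
    protein_id = rep(matches$protein_id,
                     lengths(strsplit(matches$region_name, ";"))),
    name = unlist(strsplit(matches$region_name, ";")),
    stringsAsFactors = FALSE)
  expanded$type <- normalize_domain_type(expanded$name, clustering_map)
  counts <- stats::aggregate(protein_id ~ type, data = expanded,
                             FUN = function(x) length(unique(x)))
  names(counts)[2] <- "n_proteins"
  counts <- counts[order(-counts$n_proteins, counts$type), , drop = FALSE]
  rownames(counts) <- NULL
  if (!is.null(top)) counts <- utils::head(counts, top)
  counts
}

#' Amino-acid composition enrichment between two peptide sets
#'
#' Residue-level (length-weighted) composition over the 20 canonical
#' amino acids with an additive pseudocount per amino acid per set;
#' enrichment is `log2(freq_query / freq_reference)`.
#'
#' @param query,reference Character vectors of peptide sequences
#'   (non-empty).
#' @param pseudocount Added to every amino-acid count (default 1).
#' @return Data frame with `aa`, `freq_query`, `freq_reference`,
#'   `log2_enrichment`; each frequency column sums to 1.
#' @export
composition_enrichment <- function(query, reference, pseudocount = 1) {
  if (length(query) == 0 || length(reference) == 0) {
    stop("composition_enrichment: both peptide sets must be non-empty")
  }
  count_set <- function(seqs) {
    chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    tab <- table(factor(chars, levels = AA20))
    as.numeric(tab) + pseudocount
  }
  cq <- count_set(query); cr <- count_set(reference)
  fq <- cq / sum(cq); fr <- cr / sum(cr)
  data.frame(aa = AA20, freq_query = fq, freq_reference = fr,
             log2_enrichment = log2(fq / fr), stringsAsFactors = FALSE)
}
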