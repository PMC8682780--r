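# Independent brute-force oracles and fixture builders used across tests.

# Digestion oracle: enumerate every substring and keep those whose
# boundaries are valid cleavage boundaries (cut after K/R, or a sequence
# terminus) with at most max_missed internal cleavage sites.
brute_force_digest <- function(sequence, max_missed, min_length, max_length) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  is_cut <- chars %in% c("K", "R")
  rows <- list()
  for (s in 1:L) {
    if (!(s == 1 || is_cut[s - 1])) next
    for (e in s:L) {
      if (!(e == L || is_cut[e])) next
      len <- e - s + 1
      if (len < min_length || len > max_length) next
      internal <- if (e > s) sum(is_cut[s:(e - 1)]) else 0
      if (internal > max_missed) next
      rows[[length(rows) + 1]] <- data.frame(
        sequence = substr(sequence, s, e), start = s, end = e,
        n_missed = internal, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), n_missed = integer(0)))
  }
  do.call(rbind, rows)
}

# Interval-matching oracle: minimum residue-pair distance between two
# 1-based inclusive intervals (0 when they overlap).
brute_force_gap <- function(ps, pe, rs, re) {
  min(abs(outer(ps:pe, rs:re, "-")))
}

# Random amino-acid sequence with plenty of K/R so digestion is exercised.
random_aa_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "G", "K", "K", "R", "R", "P", "S", "V"),
               len, replace = TRUE), collapse = "")
}

make_regions <- function(protein_id, start, end, region_class, name = "dom") {
  out <- data.frame(region_id = sprintf("r%03d", seq_along(start)),
                    protein_id = protein_id, start = start, end = end,
                    region_class = region_class,
                    name = rep_len(name, length(start)),
                    source_signature = rep_len(name, length(start)),
                    stringsAsFactors = FALSE)
  class(out) <- c("region_annotation", "data.frame")
  out
}

# A small MaxQuant-style proteinGroups file on disk.
write_protein_groups_fixture <- function(path) {
  df <- data.frame(
    `Protein IDs` = c("P1", "P2", "P3", "REV__P4", "CON__P5"),
    `Gene names` = c("GeneA", "GeneB", "GeneC", "GeneD", "GeneE"),
    `Ratio H/L F1` = c(2, 0.5, 0, 1, 1),
    `Ratio H/L R1` = c(0.25, 2, 1, 1, 1),
    `iBAQ F1` = c(1e6, 2e6, 0, 5e5, 5e5),
    `iBAQ R1` = c(2e6, 1e6, 3e6, 5e5, 5e5),
    Reverse = c("", "", "", "+", ""),
    `Potential contaminant` = c("", "", "", "", "+"),
    `Only identified by site` = c("", "", "", "", ""),
    check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "chromacontact", mustWork = TRUE)
}
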