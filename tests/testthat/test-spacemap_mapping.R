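test_that("consensus merging unions highly overlapping same-class regions", {
  regs <- make_regions("P1", start = c(10, 20), end = c(100, 110),
                       region_class = "domain", name = c("A", "B"))
  out <- consensus_merge(regs)  # overlap 81 of shorter 91: 0.89 >= 0.7
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(10, 110))
  expect_equal(out$name, "A;B")

  disjoint <- make_regions("P1", c(10, 200), c(50, 260), "domain", c("A", "B"))
  expect_equal(nrow(consensus_merge(disjoint)), 2)

  dup <- make_regions("P1", c(10, 10), c(50, 50), "domain", "A")
  merged_dup <- consensus_merge(dup)
  expect_equal(nrow(merged_dup), 1)
  expect_equal(merged_dup$name, "A")

  # different classes never merge even at full overlap
  mixed <- make_regions("P1", c(10, 10), c(50, 50), c("domain", "IDR"),
                        c("A", "B"))
  expect_equal(nrow(consensus_merge(mixed)), 2)
})

test_that("consensus merging is idempotent and order-invariant", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 8
    start <- sample(1:150, n)
    regs <- make_regions("P1", start, start + sample(20:80, n, TRUE),
                         region_class = sample(c("domain", "IDR"), n, TRUE),
                         name = letters[1:n])
    a <- consensus_merge(regs)
    expect_equal(consensus_merge(a)[, -1], a[, -1])  # region ids regenerated
    perm <- regs[sample(n), ]
    b <- consensus_merge(perm)
    expect_equal(b[, -1], a[, -1])
  }
})

test_that("peptide-region matching implements the <=10-residue rule", {
  regs <- make_regions("P1", 96, 155, "domain", "Homeobox")
  hit <- match_peptide_to_regions(
    data.frame(peptide_id = "q", protein_id = "P1", start = 76, end = 87), regs)
  expect_equal(hit$relation, "proximal")
  expect_equal(hit$gap, 9L)
  none <- match_peptide_to_regions(
    data.frame(peptide_id = "q", protein_id = "P1", start = 51, end = 66), regs)
  expect_equal(nrow(none), 0)
  ident <- match_peptide_to_regions(
    data.frame(peptide_id = "q", protein_id = "P1", start = 96, end = 155), regs)
  expect_equal(ident$relation, "overlap")
  expect_equal(ident$gap, 0L)
  # a peptide may match a domain and an IDR simultaneously
  both <- match_peptide_to_regions(
    data.frame(peptide_id = "q", protein_id = "P1", start = 90, end = 100),
    make_regions("P1", c(96, 60), c(155, 92), c("domain", "IDR"), c("H", "I")))
  expect_setequal(both$region_class, c("domain", "IDR"))
})

test_that("matching agrees with the all-residue-pairs oracle on 1000 random pairs", {
  set.seed(22)
  for (i in 1:1000) {
    ps <- sample(1:300, 1); pe <- ps + sample(0:40, 1)
    rs <- sample(1:300, 1); re <- rs + sample(0:80, 1)
    regs <- make_regions("P1", rs, re, "domain")
    got <- match_peptide_to_regions(
      data.frame(peptide_id = "q", protein_id = "P1", start = ps, end = pe),
      regs, max_gap = 10)
    want_gap <- brute_force_gap(ps, pe, rs, re)
    if (want_gap <= 10) {
      expect_equal(got$gap, want_gap)
      expect_equal(got$relation, if (want_gap == 0) "overlap" else "proximal")
    } else {
      expect_equal(nrow(got), 0)
    }
  }
})

test_that("pluripotency-factor fixtures reproduce the printed domain relations", {
  regs <- read_region_annotations(fixture_path("pluripotency_regions.tsv"))
  peps <- read.delim(fixture_path("pluripotency_peptides.tsv"),
                     stringsAsFactors = FALSE)
  matches <- match_peptide_to_regions(peps, regs)
  rel <- function(pid) matches$relation[matches$peptide_id == pid]
  # Oct4: both crosslinked peptides overlap the POU-specific domain (131-205)
  expect_equal(rel("Oct4_151_170"), "overlap")
  expect_equal(rel("Oct4_180_188"), "overlap")
  # Sox2: 83-97 lies inside the HMG box (43-111); 274-293 does not touch it
  expect_equal(rel("Sox2_83_97"), "overlap")
  expect_equal(length(rel("Sox2_274_293")), 0)
  # Nanog: 51-66 is 30 residues from the homeodomain (96-155): no match;
  # 76-87 / 76-89 fall within 10 residues: proximal matches
  expect_equal(length(rel("Nanog_51_66")), 0)
  expect_equal(rel("Nanog_76_87"), "proximal")
  expect_equal(matches$gap[matches$peptide_id == "Nanog_76_89"], 7L)
})

test_that("contact summaries classify proteins by mapped region classes", {
  peps <- data.frame(peptide_id = c("a", "b", "c", "d"),
                     protein_id = c("P1", "P2", "P2", "P3"))
  matches <- data.frame(peptide_id = c("a", "b", "c"),
                        protein_id = c("P1", "P2", "P2"),
                        region_id = c("r1", "r2", "r3"),
                        region_class = c("domain", "domain", "IDR"),
                        region_name = "x", relation = "overlap", gap = 0L)
  s <- summarize_protein_contacts(peps, matches)
  st <- setNames(s$per_protein$mapping_status, s$per_protein$protein_id)
  expect_equal(st[["P1"]], "domain_only")
  expect_equal(st[["P2"]], "both")
  expect_equal(st[["P3"]], "unmapped")
  expect_equal(unname(s$aggregate["frac_peptides_mapped"]), 3 / 4)
  # restriction to an intersect set drops outside proteins
  s2 <- summarize_protein_contacts(peps, matches, intersect_set = c("P1"))
  expect_equal(s2$per_protein$protein_id, "P1")
})

test_that("domain-type ranking clusters signature families and breaks ties lexically", {
  matches <- data.frame(
    peptide_id = letters[1:5],
    protein_id = c("P1", "P2", "P2", "P3", "P4"),
    region_id = paste0("r", 1:5),
    region_class = "domain",
    region_name = c("RRM_1", "RRM_2", "RRM_1", "KH_1", "Bromodomain"),
    relation = "overlap", gap = 0L)
  rk <- rank_domain_types(matches)
  expect_equal(rk$type[1], "rrm")
  expect_equal(rk$n_proteins[1], 2)  # distinct proteins (P1, P2), not matches
  expect_equal(rk$type[2:3], c("bromodomain", "kh"))  # ties: lexicographic
  expect_equal(nrow(rank_domain_types(matches[0, ])), 0)
  # explicit clustering map overrides name normalization
  rk2 <- rank_domain_types(matches, clustering_map = c(Bromodomain = "reader"))
  expect_true("reader" %in% rk2$type)
})

test_that("composition enrichment is a smoothed residue-frequency log-ratio", {
  same <- composition_enrichment(c("ACDK", "PEST"), c("ACDK", "PEST"))
  expect_true(all(same$log2_enrichment == 0))
  expect_equal(sum(same$freq_query), 1, tolerance = 1e-9)
  expect_equal(sum(same$freq_reference), 1, tolerance = 1e-9)

  skew <- composition_enrichment("EEEEEEEEEE", "LLLLLLLLLL")
  expect_gt(skew$log2_enrichment[skew$aa == "E"], 0)
  expect_lt(skew$log2_enrichment[skew$aa == "L"], 0)
  expect_true(all(is.finite(skew$log2_enrichment)))  # pseudocount keeps it finite

  expect_error(composition_enrichment(character(0), "AA"), "non-empty")
})
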