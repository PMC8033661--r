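test_that("deduplication collapses identical residues case-insensitively", {
  recs <- toy_records(c("a", "b", "c"), c("ACDE", "ACDE", "WYF"))
  expect_equal(deduplicate(recs)$id, c("a", "c"))
  recs2 <- toy_records(c("a", "b"), c("acde", "ACDE"))
  expect_equal(deduplicate(recs2)$id, "a")
  expect_equal(deduplicate(recs2)$residues, "acde")
  # set-cardinality oracle on shuffled input
  set.seed(1)
  pool <- c("ACDE", "WYFA", "KLMN", "GHIP")
  seqs <- sample(pool, 30, replace = TRUE)
  recs3 <- toy_records(sprintf("r%02d", 1:30), seqs)
  expect_equal(nrow(deduplicate(recs3)), length(unique(seqs)))
  # idempotence
  expect_identical(deduplicate(deduplicate(recs3)), deduplicate(recs3))
})

test_that("synthetic-entry filter removes blacklisted keywords", {
  recs <- sequence_records(c("a", "synthetic_c1", "b"),
                           c("ACDE", "WYFA", "KLMN"),
                           description = c("ok", "", "artificial construct"))
  expect_equal(remove_synthetic(recs)$id, "a")
})

test_that("short nucleotide records are flagged at the 300 bp boundary", {
  nt299 <- paste(rep("ACG", 99), collapse = "")          # 297
  nt299 <- paste0(nt299, "AC")                           # 299
  nt300 <- paste0(nt299, "G")                            # 300
  recs <- toy_records(c("short", "exact"), c(nt299, nt300), "nucleotide")
  fl <- flag_short_nucleotides(recs)
  expect_equal(fl$flagged$id, "short")
  expect_equal(fl$kept$id, "exact")
  all_short <- toy_records("s", "ACGT", "nucleotide")
  fl2 <- flag_short_nucleotides(all_short)
  expect_equal(nrow(fl2$kept), 0L)
  expect_equal(nrow(fl2$flagged), 1L)
  expect_error(flag_short_nucleotides(toy_records("p", "ACDE")), "nucleotide")
})

test_that("translation uses frame 0, stops at stop, X for ambiguity", {
  r <- toy_records("t1", "ATGGCTTAA", "nucleotide")
  expect_equal(translate_cds(r)$residues, "MA")
  r2 <- toy_records("t2", "ATGGCNGGG", "nucleotide")
  expect_equal(translate_cds(r2)$residues, "MXG")
  expect_error(translate_cds(toy_records("t3", "AT", "nucleotide")),
               "codon")
  expect_error(translate_cds(toy_records("t4", "TAAATG", "nucleotide")),
               "empty")
  # codon-table oracle: random stop-free ORF of 3k bp -> protein of length k
  set.seed(7)
  codons <- c("GCT", "TGC", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
              "AAA", "CTT", "ATG", "AAT", "CCT", "CAA", "CGT", "TCT",
              "ACT", "GTT", "TGG", "TAT")
  k <- 50
  orf <- paste(sample(codons, k, replace = TRUE), collapse = "")
  out <- translate_cds(toy_records("orf", orf, "nucleotide"))
  expect_equal(nchar(out$residues), k)
  expect_equal(out$moltype, "protein")
})

test_that("merging translated records into the protein set is idempotent", {
  prot <- toy_records(c("p1", "p2"), c("ACDE", "WYFA"))
  tr <- toy_records(c("n1", "n2"), c("ACDE", "KLMN"))
  merged <- merge_nt_into_protein_set(prot, tr)
  expect_equal(merged$id, c("p1", "p2", "n2"))
  expect_identical(merge_nt_into_protein_set(merged, tr), merged)
})

test_that("representative selection: single-linkage clusters and determinism", {
  # two identical + one dissimilar at threshold 0.95 -> 2 clusters
  recs <- toy_records(c("a", "b", "c"),
                      c("ACDEFGHIKL", "ACDEFGHIKL", "WYWYWYWYWY"))
  ca <- select_representatives(recs)
  expect_equal(length(unique(ca$cluster_id)), 2L)
  expect_setequal(ca$record_id, recs$id)
  expect_equal(sum(ca$is_representative), 2L)
  # representative = longest, ties by lexicographic id
  recs2 <- toy_records(c("bb", "aa"), c("ACDEFGHIKL", "ACDEFGHIKL"))
  ca2 <- select_representatives(recs2)
  expect_true(ca2$is_representative[ca2$record_id == "aa"])
  # threshold 1.0: clusters are exact-duplicate groups
  ident1 <- function(a, b) mean(strsplit(a$residues, "")[[1]] ==
                                  strsplit(b$residues, "")[[1]])
  recs3 <- toy_records(c("a", "b", "c", "d"),
                       c("AAAA", "AAAA", "AAAC", "AAAC"))
  ca3 <- select_representatives(
    recs3, curation_config(representative_identity = 1),
    pairwise_identity = ident1)
  expect_equal(length(unique(ca3$cluster_id)), 2L)
  # monotonicity: cluster count non-increasing as threshold decreases
  set.seed(3)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "D", "E"), 12, replace = TRUE), collapse = ""),
    character(1))
  recs4 <- toy_records(sprintf("s%d", 1:8), seqs)
  counts <- vapply(c(1, 0.9, 0.7, 0.5, 0.2), function(th) {
    cc <- curation_config(representative_identity = th,
                          provenance_identity_min = min(0.19, th / 2))
    length(unique(select_representatives(recs4, cc, ident1)$cluster_id))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
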