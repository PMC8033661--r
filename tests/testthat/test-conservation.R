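test_that("column frequencies, occupancy and information content", {
  rows <- c(r1 = "AAG", r2 = "AAG", r3 = "AAG", r4 = "GA-", r5 = "-A-")
  prof <- column_frequencies(rows)
  expect_equal(unname(prof$freq[1, c("A", "G")]), c(0.75, 0.25))
  expect_equal(prof$occupancy[1], 0.8)
  # invariant column -> full information
  expect_equal(prof$bits[2], log2(20))
  # uniform 20-residue column -> zero information
  uni <- setNames(paste0(AA_LEVELS[1:20]), sprintf("u%02d", 1:20))
  prof_u <- column_frequencies(uni)
  expect_equal(prof_u$bits[1], 0)
  expect_true(all(prof$bits >= 0 & prof$bits <= log2(20) + 1e-12))
  # all-gap column
  prof_g <- column_frequencies(c(a = "-", b = "-"))
  expect_equal(prof_g$occupancy[1], 0)
  expect_equal(prof_g$bits[1], 0)
})

test_that("logo matrix applies the 20% occurrence rule without renormalising", {
  rows <- c(r1 = "AC", r2 = "AC", r3 = "AC", r4 = "GC")
  prof <- column_frequencies(rows)
  lm <- logo_matrix(prof, logo_config(min_occurrence = 0.20))
  expect_equal(unname(lm[1, c("A", "G")]), c(0.75, 0.25))  # both above 20%
  rows2 <- c(r1 = "A", r2 = "A", r3 = "A", r4 = "A", r5 = "A", r6 = "A",
             r7 = "A", r8 = "A", r9 = "A", r10 = "C")
  lm2 <- logo_matrix(column_frequencies(rows2), logo_config(0.20))
  expect_equal(unname(lm2[1, "C"]), 0)      # 0.1 <= 0.2 removed
  expect_equal(unname(lm2[1, "A"]), 0.9)    # kept, NOT renormalised
  lm3 <- logo_matrix(prof, logo_config(min_occurrence = 0))
  expect_equal(lm3, prof$freq)
})

test_that("clade logos reassemble to the global profile as a weighted mixture", {
  set.seed(6)
  mk <- function(n, bias) vapply(seq_len(n), function(i)
    paste(sample(AA_LEVELS[1:20], 8, TRUE, prob = bias), collapse = ""),
    character(1))
  b1 <- rep(1, 20); b1[1] <- 10
  b2 <- rep(1, 20); b2[5] <- 10
  rows <- setNames(c(mk(6, b1), mk(4, b2)), sprintf("r%02d", 1:10))
  g <- column_frequencies(rows)
  p1 <- column_frequencies(rows[1:6])
  p2 <- column_frequencies(rows[7:10])
  expect_equal(g$freq, (6 * p1$freq + 4 * p2$freq) / 10, tolerance = 1e-12)
})

test_that("reference map and conserved positions in reference numbering", {
  aln <- c(ref = "-AC-DE", q1 = "WACFDE", q2 = "WACFDE")
  rm <- reference_map(aln, "ref")
  expect_equal(rm$column, c(2L, 3L, 5L, 6L))
  expect_equal(rm$ref_position, 1:4)
  expect_true(all(diff(rm$column) > 0))
  expect_error(reference_map(aln, "nope"), "absent")
  prof <- column_frequencies(aln)
  # threshold 1: all columns invariant among observed residues here
  pos <- conserved_positions(prof, rm, threshold = 1)
  expect_equal(pos, 1:4)
  # a deviant row removes a position at threshold 1
  aln2 <- c(ref = "AC", q1 = "AC", q2 = "GC")
  rm2 <- reference_map(aln2, "ref")
  prof2 <- column_frequencies(aln2)
  expect_equal(conserved_positions(prof2, rm2, 1), 2L)
  # monotone in the threshold
  expect_true(all(conserved_positions(prof2, rm2, 0.9) %in%
                    conserved_positions(prof2, rm2, 0.6)))
})

test_that("binding-site substitution classes follow the residue-class table", {
  aln <- c(ref = "WLKDW", q = "RIKEK")
  rm <- reference_map(aln, "ref")
  bs <- binding_site_conservation(aln[["q"]], aln[["ref"]], 1:5, rm)
  # W->R aromatic->positive, L->I same class, K->K identical,
  # D->E same class, W->K aromatic->positive
  expect_equal(bs$class, c("non_conservative", "conservative", "identical",
                           "conservative", "non_conservative"))
  self <- binding_site_conservation(aln[["ref"]], aln[["ref"]], 1:5, rm)
  expect_true(all(self$class == "identical"))
  gapq <- c(ref = "WLK", q = "W-K")
  rmg <- reference_map(gapq, "ref")
  expect_equal(binding_site_conservation(gapq[["q"]], gapq[["ref"]],
                                         2L, rmg)$class, "missing")
})

test_that("terminal extension flags use the 100-residue default threshold", {
  expect_equal(flag_extended(330, c(30, 180))$terminus, "C")
  expect_equal(flag_extended(330, c(30, 180))$c_length, 150)
  expect_equal(flag_extended(150, c(0, 150))$terminus, "none")
  fl <- flag_extended(480, c(340, 470))
  expect_equal(fl$terminus, "N")
  expect_equal(fl$n_length, 340)
  both <- flag_extended(400, c(120, 280))
  expect_equal(both$terminus, "both")
  expect_error(flag_extended(100, c(50, 50)), "empty domain")
})
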