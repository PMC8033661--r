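toy_features <- function() {
  # one replicon of length 3000: focal gene at [1000,1400), neighbours
  # around it, distant features beyond the 500 bp window
  new_ft <- function(start, end, id, terms, focal = FALSE)
    data.frame(genome_id = "g1", replicon_id = "chr", start = start,
               end = end, strand = "+", replicon_type = "chromosome",
               feature_id = id, product = ifelse(focal, "avidin", "x"),
               is_focal = focal, terms = I(list(terms)),
               stringsAsFactors = FALSE)
  rbind(new_ft(1000L, 1400L, "focal1", character(0), TRUE),
        new_ft(300L, 500L, "left_abut", "GO:0000001"),      # ends at 500
        new_ft(300L, 501L, "left_in", "GO:0000001"),        # 1 bp inside
        new_ft(1900L, 2200L, "right_abut", "GO:0000002"),   # starts at 1900
        new_ft(1850L, 2100L, "right_in", "GO:0000002"),
        new_ft(2500L, 2800L, "far", c("GO:0000002", "GO:0000003")))
}

test_that("vicinity windows follow the 500 bp half-open convention", {
  expect_equal(vicinity(1000L, 1400L, 500L, 10000L), c(500L, 1900L))
  expect_equal(vicinity(100L, 400L, 500L, 10000L), c(0L, 900L))
  expect_equal(vicinity(1000L, 1400L, 0L, 10000L), c(1000L, 1400L))
  expect_equal(vicinity(1000L, 1400L, 500L, 1600L), c(500L, 1600L))
})

test_that("foreground membership respects half-open interval abutment", {
  uf <- build_universe_and_foreground(toy_features(),
                                      enrichment_config(window_bp = 500L))
  expect_setequal(uf$foreground_ids, c("left_in", "right_in"))
  expect_false("focal1" %in% uf$universe$feature_id)
  expect_false("focal1" %in% uf$foreground_ids)
  expect_equal(nrow(uf$universe), 5L)
  expect_error(build_universe_and_foreground(
    toy_features()[-1, ], enrichment_config()), "focal")
})

test_that("GO fallback mapping translates PFAM/IPR/TIGRFAM only when needed", {
  feats <- toy_features()
  feats$terms[[2]] <- "PF00082"
  feats$terms[[4]] <- c("GO:0000009", "PF00082")   # has GO: unchanged
  feats$terms[[6]] <- "IPR000001"
  fmap <- data.frame(accession = c("PF00082", "IPR000001"),
                     go = c("GO:0006508", "GO:0000005"))
  out <- assign_go_terms(feats, fmap)
  expect_equal(out$terms[[2]], "GO:0006508")
  expect_equal(out$terms[[4]], "GO:0000009")
  expect_equal(out$terms[[6]], "GO:0000005")
  expect_equal(out$terms[[3]], "GO:0000001")
  expect_equal(attr(out, "n_unannotated"), 1L)  # the focal gene
  expect_error(assign_go_terms(feats, data.frame(accession = "PF1",
                                                 go = "GO:12")),
               "malformed")
})

test_that("one-sided Fisher p equals exhaustive enumeration for N <= 12", {
  expect_equal(fisher_exact_greater(3, 1, 1, 7), 33 / 495,
               tolerance = 1e-12)
  expect_equal(fisher_exact_greater(0, 5, 3, 4), 1)
  expect_error(fisher_exact_greater(0, 0, 0, 0), "all-zero")
  for (N in c(4, 8, 12)) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      d <- N - a - b - cc
      expect_equal(fisher_exact_greater(a, b, cc, d),
                   hypergeom_greater_oracle(a, b, cc, d),
                   tolerance = 1e-12,
                   info = paste(a, b, cc, d))
    }
  }
})

test_that("Benjamini-Hochberg step-up: closed form, order, monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.7), 0.7)
  set.seed(10)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12) && max(q) <= 1)
  # input order preserved: shuffling and unshuffling agree
  o <- sample(50)
  expect_equal(bh_adjust(p[o])[order(o)], q)
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("enrichment results: ordering, odds ratios, degenerate term", {
  feats <- toy_features()
  res <- enrich(feats, enrichment_config())
  expect_true(!is.unsorted(res$p))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_equal(length(unique(res$a + res$b)), 1L)  # common foreground size
  # a term carried by every universe feature discriminates nothing
  feats2 <- toy_features()
  feats2$terms <- lapply(seq_len(nrow(feats2)), function(i)
    if (feats2$is_focal[i]) character(0) else "GO:0000007")
  res2 <- enrich(feats2, enrichment_config())
  expect_equal(res2$p[res2$term == "GO:0000007"], 1)
})
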