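test_that("Yule tree simulation: leaf counts and determinism", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  tr10a <- simulate_tree(10, seed = 5)
  tr10b <- simulate_tree(10, seed = 5)
  expect_equal(ape::write.tree(tr10a), ape::write.tree(tr10b))
  expect_error(simulate_tree(1), "2 leaves")
})

test_that("sequence evolution matches the model's expected divergence", {
  # zero branch lengths: all tips identical to each other
  tr <- simulate_tree(4, seed = 2)
  tr$edge.length[] <- 0
  recs <- evolve_sequences(tr, 50, "jtt", seed = 3)
  expect_equal(length(unique(recs$residues)), 1L)
  # two-leaf tree of known total length: observed p within 3 SE of p(t)
  mod <- aa_model("jtt")
  two <- ape::read.tree(text = "(a:0.25,b:0.25);")
  n_sites <- 10000
  recs2 <- evolve_sequences(two, n_sites, "jtt", seed = 7)
  p_obs <- mean(strsplit(recs2$residues[1], "")[[1]] !=
                  strsplit(recs2$residues[2], "")[[1]])
  p_exp <- expected_p_distance(mod, 0.5)
  se <- sqrt(p_exp * (1 - p_exp) / n_sites)
  expect_lt(abs(p_obs - p_exp), 3 * se)
  # determinism
  recs3 <- evolve_sequences(two, 100, "jtt", seed = 9)
  recs4 <- evolve_sequences(two, 100, "jtt", seed = 9)
  expect_identical(recs3$residues, recs4$residues)
  noblen <- two; noblen$edge.length <- NULL
  expect_error(evolve_sequences(noblen, 10), "branch lengths")
  # supplied root sequence is respected at zero divergence
  zero <- ape::read.tree(text = "(a:0,b:0);")
  recs5 <- evolve_sequences(zero, model = "jtt", seed = 1,
                            root_seq = "ACDEFGHIKL")
  expect_equal(unique(recs5$residues), "ACDEFGHIKL")
})

test_that("planted families: leaf counts, labels, degenerate single clade", {
  cfg <- family_sim_config(n_clades = 3, leaves_per_clade = 4, seed = 5)
  fam <- simulate_family_with_clades(cfg)
  expect_equal(nrow(fam$records), 12L)
  expect_equal(length(fam$truth$labels), 12L)
  expect_equal(length(unique(fam$truth$labels)), 3L)
  expect_setequal(names(fam$truth$labels), fam$records$id)
  one <- simulate_family_with_clades(
    family_sim_config(n_clades = 1, leaves_per_clade = 5, seed = 2))
  expect_equal(length(unique(one$truth$labels)), 1L)
  expect_equal(nrow(one$records), 5L)
})

test_that("toy genomes: structure, planted-term containment, fallback map", {
  cfg <- genome_sim_config(n_genomes = 2, features_per_genome = 60,
                           seed = 13)
  sim <- simulate_genomes(cfg)
  feats <- sim$features
  expect_equal(nrow(feats), 120L)
  expect_equal(sum(feats$is_focal), 2L * cfg$n_focal_per_genome)
  expect_setequal(feats$feature_id[feats$is_focal], sim$truth$focal_ids)
  expect_true(all(feats$start < feats$end))
  # every generated "near" feature overlaps an independently computed
  # vicinity interval of a focal feature on its replicon
  for (id in sim$truth$near_ids) {
    i <- which(feats$feature_id == id)
    same <- feats$genome_id == feats$genome_id[i] & !feats$is_focal
    focal <- which(feats$genome_id == feats$genome_id[i] & feats$is_focal)
    hit <- any(vapply(focal, function(f) {
      lo <- max(0, feats$start[f] - cfg$window_bp)
      hi <- feats$end[f] + cfg$window_bp
      feats$start[i] < hi && feats$end[i] > lo
    }, logical(1)))
    expect_true(hit, info = id)
  }
  # the fallback map covers every non-GO accession in use
  non_go <- setdiff(unlist(feats$terms),
                    grep("^GO:", unlist(feats$terms), value = TRUE))
  expect_true(all(non_go %in% sim$fallback_map$accession))
  # determinism
  sim2 <- simulate_genomes(cfg)
  expect_identical(sim$features$start, sim2$features$start)
  expect_identical(sim$features$terms, sim2$features$terms)
})

test_that("adjusted Rand index: worked example, bounds, null expectation", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # 6-item worked partition, pair-count arithmetic done by hand:
  # contingency 2,1,0 / 0,1,2 -> sum C(nij,2)=2, a=6, b=3, n=6
  # ARI = (2 - 6*3/15) / ((6+3)/2 - 6*3/15) = 0.8/3.3
  truth <- c(x1 = "A", x2 = "A", x3 = "A", x4 = "B", x5 = "B", x6 = "B")
  est <- c(x1 = "p", x2 = "p", x3 = "q", x4 = "q", x5 = "r", x6 = "r")
  expect_equal(adjusted_rand(truth, est), 0.8 / 3.3, tolerance = 1e-12)
  # agreement with an independent implementation
  skip_if_not_installed("mclust")
  set.seed(3)
  for (rep in 1:5) {
    a <- sample(3, 40, replace = TRUE)
    b <- sample(4, 40, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  # null: random relabeling has ARI near 0 on average
  set.seed(4)
  null_ari <- replicate(400, adjusted_rand(sample(rep(1:4, 10)),
                                           sample(rep(1:4, 10))))
  expect_lt(abs(mean(null_ari)), 0.02)
  expect_error(adjusted_rand(c(a = 1), c(b = 1)), "different item sets")
})
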