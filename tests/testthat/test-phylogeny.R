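test_that("partial deletion keeps columns meeting the coverage cut-off", {
  rows <- c(a = "ACD-E", b = "ACDFE", c = "ACD-E", d = "ACDFE",
            e = "ACDFE", f = "ACDFE", g = "ACDFE", h = "ACDFE",
            i = "ACDFE", j = "ACDFE")
  kept <- apply_partial_deletion(rows, 0.95)
  # column 4 has occupancy 0.8 < 0.95 -> dropped; the rest are gap-free
  expect_equal(attr(kept, "columns"), c(1L, 2L, 3L, 5L))
  all_cols <- apply_partial_deletion(rows, 1e-9)
  expect_equal(ncol(all_cols), 5L)
  expect_error(apply_partial_deletion(c(a = "-", b = "-"), 0.95),
               "coverage")
})

test_that("distance models: closed forms and correction ordering", {
  rows <- rbind(a = strsplit("AAAAAAAAAA", "")[[1]],
                b = strsplit("AAAAACCCCC", "")[[1]])
  expect_equal(unname(compute_distance(rows, "p")["a", "b"]), 0.5)
  expect_equal(unname(compute_distance(rows, "poisson")["a", "b"]),
               -log(0.5), tolerance = 1e-6)
  same <- rbind(a = rep("A", 8), b = rep("A", 8))
  for (m in c("p", "poisson", "jtt_ml"))
    expect_lt(unname(compute_distance(same, m)["a", "b"]), 1e-4)
  # correction monotonicity p <= poisson <= jtt_ml on random pairs
  set.seed(2)
  for (rep in 1:5) {
    s1 <- sample(AA_LEVELS[1:20], 60, replace = TRUE)
    s2 <- s1
    flip <- sample(60, 18)
    s2[flip] <- sample(AA_LEVELS[1:20], 18, replace = TRUE)
    rows2 <- rbind(a = s1, b = s2)
    dp <- unname(compute_distance(rows2, "p")["a", "b"])
    dpois <- unname(compute_distance(rows2, "poisson")["a", "b"])
    djtt <- unname(compute_distance(rows2, "jtt_ml")["a", "b"])
    expect_true(dp <= dpois + 1e-9 && dpois <= djtt + 1e-6)
  }
  # saturated / non-overlapping pairs are errors
  expect_error(compute_distance(rbind(a = c("A", "-"), b = c("-", "C")),
                                "p"), "overlap")
  expect_error(compute_distance(rbind(a = c("A", "A"), b = c("C", "C")),
                                "poisson"), "saturated")
})

test_that("JTT ML distance matches an independent grid-search oracle", {
  skip_if_not_installed("Matrix")
  mod <- aa_model("jtt")
  set.seed(9)
  for (d_true in c(0.1, 0.5, 1.2)) {
    P <- transition_matrix(mod, d_true)
    anc <- sample.int(20, 400, replace = TRUE, prob = mod$bf)
    der <- vapply(anc, function(s)
      sample.int(20, 1, prob = P[s, ]), integer(1))
    rows <- rbind(a = AA_LEVELS[anc], b = AA_LEVELS[der])
    est <- unname(compute_distance(rows, "jtt_ml")["a", "b"])
    # oracle: matrix-exponential likelihood on a fine grid
    counts <- table(factor(anc, levels = 1:20), factor(der, levels = 1:20))
    loglik <- function(d) {
      Pd <- as.matrix(Matrix::expm(mod$Q * d))
      sum(counts * log(pmax(mod$bf * Pd, 1e-300)))
    }
    grid <- seq(max(est - 0.05, 1e-4), est + 0.05, by = 1e-4)
    ll <- vapply(grid, loglik, numeric(1))
    expect_equal(est, grid[which.max(ll)], tolerance = 2e-4)
  }
})

test_that("neighbour joining: three-taxon closed form and additive recovery", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")
  # exact recovery on additive matrices from random trees, n <= 8
  set.seed(4)
  for (n in c(5, 6, 8)) {
    true <- ape::rtree(n)
    true$edge.length <- true$edge.length + 0.1
    Dm <- ape::cophenetic.phylo(true)
    est <- nj_tree(Dm[true$tip.label, true$tip.label])
    expect_equal(rf_distance(est, true), 0L)
    # permutation invariance
    perm <- sample(true$tip.label)
    est2 <- nj_tree(Dm[perm, perm])
    expect_equal(rf_distance(est, est2), 0L)
  }
})

test_that("bootstrap supports: range, determinism, strong-signal case", {
  # 4 taxa, all columns supporting the split ab|cd
  rows <- rbind(a = rep(c("A", "C"), 20), b = rep(c("A", "C"), 20),
                c = rep(c("W", "Y"), 20), d = rep(c("W", "Y"), 20))
  # perturb two sequences slightly so distances are not degenerate
  rows["b", 1] <- "D"; rows["d", 2] <- "F"
  cfg <- phylo_config(distance_model = "p", bootstrap_reps = 100, seed = 42)
  tr <- bootstrap_support(rows, cfg)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  expect_true(any(sup == 100))   # the ab|cd bipartition
  tr2 <- bootstrap_support(rows, cfg)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("clade extraction is greedy-maximal and respects thresholds", {
  # rooted caterpillar, all supports 100: one clade of all six leaves
  cat6 <- ape::read.tree(
    text = "(t1:1,(t2:1,(t3:1,(t4:1,(t5:1,t6:1)100:1)100:1)100:1)100:1)100;")
  cl <- extract_clades(cat6, 70, 3)
  expect_equal(unique(cl$clade), "clade_01")
  expect_equal(nrow(cl), 6L)
  # all supports below threshold: everything an outlier
  lowsup <- ape::read.tree(
    text = "(t1:1,(t2:1,(t3:1,(t4:1,(t5:1,t6:1)10:1)10:1)10:1)10:1)10;")
  expect_equal(unique(extract_clades(lowsup, 70, 3)$clade), "outlier")
  # min size respected
  pair <- ape::read.tree(text = "((t1:1,t2:1)100:1,(t3:1,t4:1)100:1)100;")
  expect_equal(unique(extract_clades(pair, 70, 3)$clade), "clade_01")
  expect_equal(sort(unique(extract_clades(pair, 70, 2)$clade)), "clade_01")
})

test_that("Robinson-Foulds distance: quartets, bounds, leaf-set check", {
  q1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  q2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rf_distance(q1, q1), 0L)
  expect_equal(rf_distance(q1, q2), 2L)
  set.seed(8)
  t1 <- ape::rtree(10); t2 <- ape::rtree(10)
  expect_lte(rf_distance(t1, t2), 2 * (10 - 3))
  t3 <- ape::rtree(10)
  t3$tip.label <- paste0("x", t3$tip.label)
  expect_error(rf_distance(t1, t3), "leaf")
})

test_that("bootstrap supports stabilise as replicates grow", {
  set.seed(21)
  rows <- rbind(a = sample(AA_LEVELS[1:20], 40, TRUE))
  rows <- rbind(a = rows[1, ], b = rows[1, ], c = rows[1, ], d = rows[1, ],
                e = rows[1, ])
  # mutate to create a clear ((a,b),(c,d),e) signal plus noise
  rows["b", 1:4] <- "W"; rows["c", 5:12] <- "Y"; rows["d", 5:14] <- "Y"
  rows["e", 15:24] <- "F"
  sup_at <- function(reps, seed) {
    tr <- bootstrap_support(rows, phylo_config(distance_model = "p",
                                               bootstrap_reps = reps,
                                               seed = seed))
    sort(suppressWarnings(as.numeric(tr$node.label)))
  }
  s300 <- sup_at(300, 1)
  s3000 <- sup_at(3000, 2)
  expect_true(all(abs(stats::na.omit(s300 - s3000)) <= 5))
})
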