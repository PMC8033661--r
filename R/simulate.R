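## Synthetic data with known ground truth: sequence families evolved along
## known trees with planted clade structure, and annotated toy genomes
## with a designated GO term planted in the neighbourhood of focal (avidin)
## genes at a controllable effect size.

#' Family simulation configuration
#'
#' Defaults emulate an avidin-like family: 128-residue domain, five clades
#' of six species (30 taxa), short within-clade branches and long
#' between-clade stems so that clades are clearly separated but the
#' backbone joining them is star-like (as the deep avidin phylogeny is
#' effectively unresolved between major clades).
#'
#' @param n_clades number of planted clades (default 5).
#' @param leaves_per_clade leaves per clade (default 6).
#' @param root_length sequence length in residues (default 128).
#' @param within_clade_branch mean within-clade edge length,
#'   substitutions/site (default 0.05).
#' @param between_clade_branch clade stem length (default 0.8).
#' @param model `"jtt"` or `"poisson_uniform"`.
#' @param seed integer RNG seed.
#' @export
family_sim_config <- function(n_clades = 5L, leaves_per_clade = 6L,
                              root_length = 128L,
                              within_clade_branch = 0.05,
                              between_clade_branch = 0.8,
                              model = c("jtt", "poisson_uniform"),
                              seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_clades >= 1, leaves_per_clade >= 1, root_length >= 1,
            within_clade_branch >= 0, between_clade_branch >= 0)
  list(n_clades = as.integer(n_clades),
       leaves_per_clade = as.integer(leaves_per_clade),
       root_length = as.integer(root_length),
       within_clade_branch = within_clade_branch,
       between_clade_branch = between_clade_branch,
       model = model, seed = as.integer(seed))
}

#' Simulate a Yule tree
#'
#' Pure-birth process with unit speciation rate (exponential branch
#' lengths), reproducible given the seed.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return `phylo` tree with branch lengths.
#' @export
simulate_tree <- function(n_leaves, seed = NULL) {
  if (n_leaves < 2) stop("need at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  ape::rphylo(n_leaves, birth = 1, death = 0)
}

#' Evolve sequences along a tree
#'
#' The root sequence is drawn from the model's stationary distribution
#' (or supplied); each site evolves independently down every branch with
#' transition probabilities `exp(Q t)` at that branch length.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param root_length sequence length (ignored when `root_seq` given).
#' @param model `"jtt"` or `"poisson_uniform"`.
#' @param seed RNG seed, or `NULL`.
#' @param root_seq optional explicit root sequence (string).
#' @return protein record data.frame, one row per tip.
#' @export
evolve_sequences <- function(tree, root_length = 128L, model = "jtt",
                             seed = NULL, root_seq = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(seed)) set.seed(seed)
  mod <- aa_model(model)
  n_tip <- length(tree$tip.label)
  if (!is.null(root_seq)) {
    root_states <- match(strsplit(toupper(root_seq), "")[[1]], mod$levels)
    if (anyNA(root_states)) stop("root_seq has non-standard residues")
    root_length <- length(root_states)
  } else {
    root_states <- sample.int(20, root_length, replace = TRUE,
                              prob = mod$bf)
  }
  states <- matrix(NA_integer_, n_tip + tree$Nnode, root_length)
  root <- n_tip + 1L
  states[root, ] <- root_states
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    P <- transition_matrix(mod, lens[k])
    child_states <- states[parent, ]
    for (s in unique(child_states)) {
      at <- which(child_states == s)
      child_states[at] <- sample.int(20, length(at), replace = TRUE,
                                     prob = P[s, ])
    }
    states[child, ] <- child_states
  }
  residues <- vapply(seq_len(n_tip), function(i)
    paste(mod$levels[states[i, ]], collapse = ""), character(1))
  sequence_records(tree$tip.label, residues, "protein")
}

#' Simulate a sequence family with planted clades
#'
#' A star backbone (one long stem per clade off a central node) with a
#' Yule subtree on each stem, rescaled so the mean within-clade edge
#' length matches the config; sequences evolved down the whole tree.
#' The star backbone leaves the between-clade order unresolved, which is
#' the regime where clade extraction has to rely on bootstrap support.
#'
#' @param config [family_sim_config()].
#' @return list with `records`, `truth` (list: `tree`, `labels` leaf ->
#'   clade, `config`).
#' @export
simulate_family_with_clades <- function(config = family_sim_config()) {
  set.seed(config$seed)
  sub_newick <- character(config$n_clades)
  labels <- character(0)
  for (cl in seq_len(config$n_clades)) {
    tips <- sprintf("clade%02d_t%02d", cl, seq_len(config$leaves_per_clade))
    if (config$leaves_per_clade == 1) {
      sub_newick[cl] <- sprintf("%s:%g", tips, config$between_clade_branch)
    } else {
      sub <- simulate_tree(config$leaves_per_clade)
      sub$edge.length <- sub$edge.length *
        config$within_clade_branch / mean(sub$edge.length)
      sub$tip.label <- tips
      s <- ape::write.tree(sub)
      s <- sub(";$", "", s)
      sub_newick[cl] <- sprintf("%s:%g", s, config$between_clade_branch)
    }
    labels <- c(labels, stats::setNames(rep(sprintf("true_%02d", cl),
                                            length(tips)), tips))
  }
  tree <- ape::read.tree(text = paste0("(", paste(sub_newick,
                                                  collapse = ","), ");"))
  records <- evolve_sequences(tree, config$root_length, config$model)
  list(records = records,
       truth = list(tree = tree, labels = labels, config = config))
}

#' Genome simulation configuration
#'
#' Defaults give toy genomes dense enough for the neighbourhood test to be
#' well calibrated: compact genes separated by short intergenic gaps (so a
#' 500 bp window reaches 1-2 neighbours per side), several focal genes per
#' genome (pooled foreground near 80 features), a 25-term GO vocabulary
#' with common background terms, and one planted term enriched next to the
#' focal genes.  With this design the discrete null of the exact test is
#' dense enough for the empirical false-positive rate to sit near the
#' nominal level.
#'
#' @param n_genomes number of genomes (default 5).
#' @param features_per_genome features per genome (default 150).
#' @param mean_gene_length,mean_intergenic bp (defaults 400 / 100).
#' @param term_vocabulary_size number of GO terms (default 25).
#' @param p_term_background probability a feature carries a given term
#'   (default 0.3).
#' @param p_term_near_focal probability of the planted term within the
#'   window (default 0.9; set equal to the background for a null genome).
#' @param window_bp vicinity window used for planting (default 500,
#'   matching [enrichment_config()]).
#' @param n_focal_per_genome focal (avidin) genes per genome (default 5).
#' @param pfam_fraction fraction of features annotated only with PFAM
#'   accessions translatable through the emitted fallback map.
#' @param seed RNG seed.
#' @export
genome_sim_config <- function(n_genomes = 5L, features_per_genome = 150L,
                              mean_gene_length = 400L,
                              mean_intergenic = 100L,
                              term_vocabulary_size = 25L,
                              p_term_background = 0.3,
                              p_term_near_focal = 0.9,
                              window_bp = 500L, n_focal_per_genome = 5L,
                              pfam_fraction = 0.25, seed = 1L) {
  stopifnot(p_term_background >= 0, p_term_background <= 1,
            p_term_near_focal >= 0, p_term_near_focal <= 1,
            mean_gene_length > 0, mean_intergenic > 0,
            n_focal_per_genome >= 1, term_vocabulary_size >= 2)
  list(n_genomes = as.integer(n_genomes),
       features_per_genome = as.integer(features_per_genome),
       mean_gene_length = as.integer(mean_gene_length),
       mean_intergenic = as.integer(mean_intergenic),
       term_vocabulary_size = as.integer(term_vocabulary_size),
       p_term_background = p_term_background,
       p_term_near_focal = p_term_near_focal,
       window_bp = as.integer(window_bp),
       n_focal_per_genome = as.integer(n_focal_per_genome),
       pfam_fraction = pfam_fraction, seed = as.integer(seed))
}

#' Simulate annotated toy genomes with planted neighbourhood enrichment
#'
#' Features are laid end to end with exponential intergenic gaps.  Every
#' feature carries each vocabulary term independently with the background
#' probability, except the planted term (the first of the vocabulary),
#' which features within `window_bp` of a focal gene carry with
#' `p_term_near_focal`.  A fraction of features carry the PFAM proxy of
#' their GO terms instead, translatable via the emitted fallback map.
#'
#' @param config [genome_sim_config()].
#' @return list with `features` (pooled feature data.frame),
#'   `fallback_map`, `truth` (list: `planted_term`, `focal_ids`,
#'   `near_ids`).
#' @export
simulate_genomes <- function(config = genome_sim_config()) {
  set.seed(config$seed)
  vocab <- sprintf("GO:%07d", seq_len(config$term_vocabulary_size))
  pfam_of <- stats::setNames(sprintf("PF%05d",
                                     seq_len(config$term_vocabulary_size)),
                             vocab)
  planted <- vocab[1]
  all_feat <- list()
  focal_ids <- character(0); near_ids <- character(0)
  for (g in seq_len(config$n_genomes)) {
    nf <- config$features_per_genome
    gaps <- stats::rexp(nf, 1 / config$mean_intergenic)
    lens <- pmax(150, round(stats::rexp(nf, 1 / config$mean_gene_length)))
    start <- round(cumsum(gaps) + cumsum(c(0, utils::head(lens, -1))))
    end <- start + lens
    gid <- sprintf("genome%02d", g)
    fid <- sprintf("%s_f%04d", gid, seq_len(nf))
    focal <- sample.int(nf, config$n_focal_per_genome)
    is_focal <- seq_len(nf) %in% focal
    ## which non-focal features fall in a focal vicinity window
    near <- logical(nf)
    for (f in focal) {
      v <- vicinity(start[f], end[f], config$window_bp, max(end))
      near <- near | (start < v[2] & end > v[1])
    }
    near <- near & !is_focal
    terms <- vector("list", nf)
    use_pfam <- stats::runif(nf) < config$pfam_fraction
    for (i in seq_len(nf)) {
      carry <- stats::runif(config$term_vocabulary_size) <
        config$p_term_background
      carry[1] <- stats::runif(1) <
        if (near[i]) config$p_term_near_focal else config$p_term_background
      tt <- vocab[carry]
      if (is_focal[i]) tt <- character(0)
      terms[[i]] <- if (use_pfam[i]) unname(pfam_of[tt]) else tt
    }
    feats <- new_feature_table(gid, paste0(gid, "_chr"), "chromosome",
                               start, end,
                               sample(c("+", "-"), nf, replace = TRUE),
                               fid,
                               ifelse(is_focal, "avidin",
                                      "hypothetical protein"),
                               terms, is_focal)
    all_feat[[g]] <- feats
    focal_ids <- c(focal_ids, fid[is_focal])
    near_ids <- c(near_ids, fid[near])
  }
  features <- do.call(rbind, all_feat)
  rownames(features) <- NULL
  list(features = features,
       fallback_map = data.frame(accession = unname(pfam_of), go = vocab,
                                 stringsAsFactors = FALSE),
       truth = list(planted_term = planted, focal_ids = focal_ids,
                    near_ids = near_ids))
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting formula; 1 for identical partitions, expectation 0 under
#' random labeling.
#'
#' @param labels_true,labels_est named vectors (or equal-length vectors
#'   over the same items in the same order).
#' @export
adjusted_rand <- function(labels_true, labels_est) {
  if (!is.null(names(labels_true)) && !is.null(names(labels_est))) {
    if (!setequal(names(labels_true), names(labels_est)))
      stop("label vectors cover different item sets")
    labels_est <- labels_est[names(labels_true)]
  } else if (length(labels_true) != length(labels_est)) {
    stop("label vectors cover different item sets")
  }
  tab <- table(labels_true, labels_est)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
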