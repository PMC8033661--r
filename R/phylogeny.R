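## Distance-based phylogeny: partial-deletion column filtering, pairwise
## distances (p, Poisson-corrected, JTT maximum likelihood), neighbour
## joining, bootstrap supports, clade extraction and Robinson-Foulds
## comparison.

#' Phylogeny configuration
#'
#' @param distance_model `"p"`, `"poisson"` or `"jtt_ml"`.
#' @param gamma_shape shape of the gamma rate distribution across sites, or
#'   `NULL` for no rate variation (the default; the shape is user-supplied,
#'   never estimated here).
#' @param bootstrap_reps number of bootstrap replicates (default 300).
#' @param site_coverage partial-deletion occupancy cut-off (default 0.95).
#' @param seed integer RNG seed for the bootstrap.
#' @param clade_min_support,clade_min_size clade extraction thresholds
#'   (defaults 70 / 3).
#' @param clade_min_stem minimum length (substitutions/site) of the branch
#'   subtending a clade (default 0.3); deep avidin subfamilies hang off
#'   long stems, and support alone cannot separate them from transient
#'   backbone groupings.
#' @export
phylo_config <- function(distance_model = c("jtt_ml", "p", "poisson"),
                         gamma_shape = NULL, bootstrap_reps = 300L,
                         site_coverage = 0.95, seed = 1L,
                         clade_min_support = 70, clade_min_size = 3L,
                         clade_min_stem = 0.3) {
  distance_model <- match.arg(distance_model)
  stopifnot(bootstrap_reps >= 1, site_coverage > 0, site_coverage <= 1,
            is.null(gamma_shape) || gamma_shape > 0, clade_min_stem >= 0)
  list(distance_model = distance_model, gamma_shape = gamma_shape,
       bootstrap_reps = as.integer(bootstrap_reps),
       site_coverage = site_coverage, seed = as.integer(seed),
       clade_min_support = clade_min_support,
       clade_min_size = as.integer(clade_min_size),
       clade_min_stem = clade_min_stem)
}

#' Partial deletion: drop low-occupancy alignment columns
#'
#' Keeps columns whose non-gap occupancy is at least `site_coverage`.
#'
#' @param alignment named gapped rows or a character matrix.
#' @param site_coverage occupancy cut-off in (0, 1\].
#' @return character matrix of the surviving columns, with attribute
#'   `columns` giving their original indices.
#' @export
apply_partial_deletion <- function(alignment, site_coverage = 0.95) {
  m <- if (is.matrix(alignment)) alignment else alignment_matrix(alignment)
  occ <- colMeans(m != "-")
  keep <- which(occ >= site_coverage)
  if (length(keep) == 0)
    stop("no columns reach site coverage ", site_coverage,
         "; lower the cut-off")
  structure(m[, keep, drop = FALSE], columns = keep)
}

## discrete-gamma rate categories (quantile method, mean normalised to 1)
gamma_rates <- function(shape, k = 4L) {
  r <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = shape,
                     rate = shape)
  r / mean(r)
}

jtt_pair_mldist <- function(counts, model, gamma_shape = NULL,
                            upper = 15) {
  rates <- if (is.null(gamma_shape)) 1 else gamma_rates(gamma_shape)
  negloglik <- function(d) {
    P <- Reduce(`+`, lapply(rates, function(r)
      transition_matrix(model, d * r))) / length(rates)
    lik <- model$bf * P
    -sum(counts * log(pmax(lik, 1e-300)))
  }
  opt <- stats::optimize(negloglik, interval = c(1e-8, upper), tol = 1e-6)
  opt$minimum
}

#' Pairwise evolutionary distances from alignment columns
#'
#' Pairwise comparisons use only positions where neither row has a gap (or
#' `X`).  Models: `p` = observed mismatch fraction; `poisson` =
#' `-log(1 - p)` (gamma-corrected to `a((1-p)^(-1/a) - 1)` when a shape is
#' supplied); `jtt_ml` = the distance maximising the likelihood of the
#' observed residue pairs under the JTT matrix (discrete-gamma mixture of
#' 4 categories when a shape is supplied).
#'
#' @param columns character matrix (rows = sequences).
#' @param model distance model.
#' @param gamma_shape gamma shape or `NULL`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
compute_distance <- function(columns, model = c("jtt_ml", "p", "poisson"),
                             gamma_shape = NULL) {
  model <- match.arg(model)
  n <- nrow(columns)
  stopifnot(n >= 2)
  ids <- rownames(columns)
  idx <- matrix(match(columns, AA_LEVELS), n, ncol(columns))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  jtt <- if (model == "jtt_ml") aa_model("jtt") else NULL
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    if (!any(ok))
      stop("no overlapping ungapped positions between ", ids[i], " and ",
           ids[j])
    a <- idx[i, ok]; b <- idx[j, ok]
    p <- mean(a != b)
    d <- switch(model,
      p = p,
      poisson = {
        if (p >= 1) stop("saturated distance (p >= 1) between ", ids[i],
                         " and ", ids[j])
        if (is.null(gamma_shape)) -log(1 - p)
        else gamma_shape * ((1 - p)^(-1 / gamma_shape) - 1)
      },
      jtt_ml = {
        counts <- matrix(tabulate((a - 1) * 20 + b, nbins = 400), 20, 20)
        jtt_pair_mldist(t(counts), jtt, gamma_shape)
      })
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining (via `ape::nj`); negative branch-length
#' estimates are clamped to zero.
#'
#' @param distance_matrix symmetric matrix with taxon dimnames.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(distance_matrix) {
  if (nrow(distance_matrix) < 3) stop("neighbour joining needs >= 3 taxa")
  tree <- ape::nj(stats::as.dist(distance_matrix))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Re-root an unrooted tree at its center vertex
#'
#' The stored root of an unrooted NJ tree is an artefact of join order; for
#' clade extraction the tree is re-rooted at the internal vertex with
#' minimum eccentricity (smallest maximum path length to any leaf), the
#' tree's natural deep point.  Purely a change of representation: the
#' unrooted topology and branch lengths are untouched.
#'
#' @param tree `phylo` tree.
#' @return `phylo` tree rooted at the center vertex.
#' @export
root_at_center <- function(tree) {
  n_tip <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  ecc <- apply(d[internal, seq_len(n_tip), drop = FALSE], 1, max)
  center <- internal[which.min(ecc)]
  if (center == n_tip + 1L) return(tree)
  ape::root(tree, node = center, resolve.root = FALSE)
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Columns are resampled with replacement `bootstrap_reps` times; the
#' support of each internal bipartition of the point-estimate tree is the
#' percentage of replicate trees containing it.  Replicates with a
#' saturated/undefined distance are skipped with a warning.  The root node
#' carries no support label (its bipartition is trivial).
#'
#' @param columns character matrix of alignment columns (post partial
#'   deletion).
#' @param config [phylo_config()]; `seed` controls reproducibility.
#' @return `phylo` tree with `node.label` percent supports (root `NA`),
#'   plus attribute `n_replicates_used`.
#' @export
bootstrap_support <- function(columns, config = phylo_config()) {
  point <- root_at_center(
    nj_tree(compute_distance(columns, config$distance_model,
                             config$gamma_shape)))
  set.seed(config$seed)
  reps <- vector("list", config$bootstrap_reps)
  n_ok <- 0L
  n_skip <- 0L
  for (r in seq_len(config$bootstrap_reps)) {
    cols <- columns[, sample.int(ncol(columns), replace = TRUE),
                    drop = FALSE]
    t_r <- tryCatch(
      nj_tree(compute_distance(cols, config$distance_model,
                               config$gamma_shape)),
      error = function(e) NULL)
    if (is.null(t_r)) { n_skip <- n_skip + 1L; next }
    n_ok <- n_ok + 1L
    reps[[n_ok]] <- t_r
  }
  if (n_skip > 0)
    warning(n_skip, " bootstrap replicate(s) skipped (saturated distance)")
  if (n_ok == 0) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(point, reps[seq_len(n_ok)], rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_ok, 1)
  support[1] <- NA  # root: trivial bipartition
  point$node.label <- support
  attr(point, "n_replicates_used") <- n_ok
  point
}

#' Extract well-supported clades from a tree
#'
#' Greedy root-down search: a maximal subtree whose node support is at
#' least `clade_min_support`, whose leaf count is at least
#' `clade_min_size` and whose stem branch (the edge subtending it) is at
#' least `clade_min_stem` long becomes a clade; descent stops there.
#' The stem criterion operationalizes the deep long branches that
#' delimit avidin subfamilies — bootstrap support alone cannot tell a
#' subfamily stem from a transient grouping of the (effectively
#' unresolved) backbone.  Nodes without a support label (including the
#' root of a bootstrap tree) are never clades themselves but are
#' descended through; a labelled root is exempt from the stem criterion
#' (it has no stem).  Unassigned leaves are labelled `"outlier"`.
#'
#' @param tree `phylo` tree with `node.label` supports.
#' @param clade_min_support percent threshold (default 70).
#' @param clade_min_size minimum leaf count (default 3).
#' @param clade_min_stem minimum stem branch length (default 0.3); set 0
#'   to disable.
#' @return data.frame with columns `leaf`, `clade`.
#' @export
extract_clades <- function(tree, clade_min_support = 70,
                           clade_min_size = 3L, clade_min_stem = 0.3) {
  n_tip <- length(tree$tip.label)
  support <- suppressWarnings(as.numeric(tree$node.label))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  stem_len <- rep(Inf, n_tip + tree$Nnode)   # root keeps Inf (no stem)
  if (!is.null(tree$edge.length))
    stem_len[tree$edge[, 2]] <- tree$edge.length
  assignment <- stats::setNames(rep("outlier", n_tip), tree$tip.label)
  clade_counter <- 0L
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(children[[as.character(node)]], tips_under))
  }
  visit <- function(node) {
    if (node <= n_tip) return(invisible())
    s <- support[node - n_tip]
    tips <- tips_under(node)
    if (!is.na(s) && s >= clade_min_support &&
        stem_len[node] >= clade_min_stem &&
        length(tips) >= clade_min_size) {
      clade_counter <<- clade_counter + 1L
      assignment[tree$tip.label[tips]] <<-
        sprintf("clade_%02d", clade_counter)
      return(invisible())
    }
    for (ch in children[[as.character(node)]]) visit(ch)
    invisible()
  }
  visit(n_tip + 1L)
  data.frame(leaf = names(assignment), clade = unname(assignment),
             stringsAsFactors = FALSE)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets.
#'
#' @param tree_a,tree_b `phylo` trees over the same leaf set.
#' @return integer distance.
#' @export
rf_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(tree_a, tree_b))
}

#' Midpoint-root a tree (display only)
#' @param tree `phylo` tree.
#' @export
midpoint_root <- function(tree) phangorn::midpoint(tree)
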