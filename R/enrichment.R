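## Gene-neighbourhood GO enrichment: vicinity windows around focal
## (avidin) genes, GO assignment with PFAM/IPR/TIGRFAM fallback mapping,
## one-sided Fisher's exact tests per term, Benjamini-Hochberg adjustment.

#' Enrichment configuration
#'
#' @param window_bp vicinity half-width: the window extends this many bp
#'   upstream and downstream of the focal gene's termini (default 500).
#' @param alternative `"greater"` (clustering with avidin more often than
#'   expected) or `"two_sided"`.
#' @param adjust `"BH"` or `"none"`.
#' @param alpha significance level (reporting only).
#' @export
enrichment_config <- function(window_bp = 500L,
                              alternative = c("greater", "two_sided"),
                              adjust = c("BH", "none"), alpha = 0.05) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  stopifnot(window_bp >= 0)
  list(window_bp = as.integer(window_bp), alternative = alternative,
       adjust = adjust, alpha = alpha)
}

#' Vicinity window of a gene
#'
#' `[start - window, end + window)`, strand-independent, clipped to
#' `[0, replicon_length)`.
#'
#' @param start,end 0-based half-open gene interval.
#' @param window_bp window size in bp.
#' @param replicon_length replicon length in bp.
#' @return length-2 integer vector (0-based half-open interval).
#' @export
vicinity <- function(start, end, window_bp = 500L, replicon_length = Inf) {
  c(max(0L, start - window_bp), min(replicon_length, end + window_bp))
}

#' Map all feature annotations to GO terms
#'
#' Features already carrying at least one GO term keep exactly their GO
#' terms; otherwise PFAM/IPR/TIGRFAM accessions are translated through the
#' fallback map.  Untranslatable features end with empty GO sets; their
#' count is attached as attribute `n_unannotated`.
#'
#' @param features feature data.frame.
#' @param fallback_map data.frame with columns `accession`, `go`
#'   (multi-mapping allowed).
#' @export
assign_go_terms <- function(features, fallback_map = NULL) {
  if (!is.null(fallback_map)) {
    if (!all(c("accession", "go") %in% names(fallback_map)))
      stop("fallback map needs columns 'accession' and 'go'")
    if (any(!grepl(TERM_PATTERNS[["GO"]], fallback_map$go)))
      stop("malformed GO accession(s) in fallback map")
  }
  out <- features
  n_un <- 0L
  out$terms <- lapply(features$terms, function(tt) {
    go <- tt[grepl(TERM_PATTERNS[["GO"]], tt)]
    if (length(go)) return(unique(go))
    if (!is.null(fallback_map) && length(tt)) {
      mapped <- fallback_map$go[fallback_map$accession %in% tt]
      if (length(mapped)) return(unique(mapped))
    }
    n_un <<- n_un + 1L
    character(0)
  })
  attr(out, "n_unannotated") <- n_un
  out
}

#' Pool genomes into a test universe and vicinity foreground
#'
#' Universe: all non-focal features pooled across genomes.  Foreground:
#' non-focal features whose interval overlaps (>= 1 bp) the vicinity
#' window of any focal feature on the same replicon of the same genome.
#'
#' @param features pooled feature data.frame (must contain focal
#'   features).
#' @param config [enrichment_config()].
#' @return list with `universe` (feature data.frame) and `foreground_ids`.
#' @export
build_universe_and_foreground <- function(features,
                                          config = enrichment_config()) {
  if (!any(features$is_focal)) stop("no focal features")
  key <- paste(features$genome_id, features$replicon_id)
  in_fg <- logical(nrow(features))
  for (k in unique(key)) {
    rows <- which(key == k)
    focal <- rows[features$is_focal[rows]]
    if (!length(focal)) next
    rep_len <- max(features$end[rows])
    for (f in focal) {
      v <- vicinity(features$start[f], features$end[f], config$window_bp,
                    rep_len)
      hit <- rows[features$start[rows] < v[2] & features$end[rows] > v[1]]
      in_fg[hit] <- TRUE
    }
  }
  universe <- features[!features$is_focal, , drop = FALSE]
  list(universe = universe,
       foreground_ids = features$feature_id[in_fg & !features$is_focal])
}

#' One-sided (greater) Fisher's exact p-value for a 2x2 table
#'
#' Upper tail of the hypergeometric distribution:
#' `P(X >= a)` with `X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b)`.
#'
#' @param a,b,c,d cell counts: in-vicinity with/without the term,
#'   outside with/without.
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) stop("all-zero contingency table")
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment (input order preserved)
#' @param p_values numeric vector in \[0, 1\].
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-neighbourhood GO enrichment
#'
#' One test per GO term present in at least one universe feature; results
#' are sorted by p ascending, ties broken by term accession.  Odds ratio
#' is `(a*d)/(b*c)`, `Inf` when `b*c == 0` and `a*d > 0`.
#'
#' @param features pooled feature data.frame (focal features marked).
#' @param config [enrichment_config()].
#' @param fallback_map see [assign_go_terms()].
#' @return data.frame with columns term, a, b, c, d, odds_ratio, p, q.
#' @export
enrich <- function(features, config = enrichment_config(),
                   fallback_map = NULL) {
  features <- assign_go_terms(features, fallback_map)
  uf <- build_universe_and_foreground(features, config)
  universe <- uf$universe
  fg <- universe$feature_id %in% uf$foreground_ids
  terms <- sort(unique(unlist(universe$terms)))
  if (!length(terms))
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      q = numeric(0)))
  n_fg <- sum(fg); n_bg <- sum(!fg)
  rows <- lapply(terms, function(tm) {
    has <- vapply(universe$terms, function(tt) tm %in% tt, logical(1))
    a <- sum(has & fg); b <- n_fg - a
    cc <- sum(has & !fg); d <- n_bg - cc
    p <- if (config$alternative == "greater") fisher_exact_greater(a, b, cc, d)
         else stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    orr <- if (b * cc == 0) { if (a * d > 0) Inf else NA_real_ }
           else (a * d) / (b * cc)
    data.frame(term = tm, a = a, b = b, c = cc, d = d, odds_ratio = orr,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- if (config$adjust == "BH") bh_adjust(res$p) else res$p
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
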