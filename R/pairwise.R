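## Pairwise global alignment and identity/similarity statistics
## (MatGAT-style matrices).
##
## Identity and similarity use the shorter-sequence denominator: identical
## (or positively scoring) aligned residue pairs divided by the length of
## the shorter input, times 100.

.blosum_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#' @return integer matrix as shipped with Biostrings.
#' @export
blosum62 <- function() {
  if (is.null(.blosum_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$B62 <- e$BLOSUM62
  }
  .blosum_cache$B62
}

#' Alignment scoring scheme
#'
#' Affine gap penalties: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend` (both negative).
#'
#' @param substitution_matrix named integer matrix, default BLOSUM62.
#' @param gap_open,gap_extend negative scores, defaults -11 / -1.
#' @export
scoring_scheme <- function(substitution_matrix = NULL, gap_open = -11,
                           gap_extend = -1) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  stopifnot(gap_open <= gap_extend, gap_extend < 0,
            isTRUE(all.equal(substitution_matrix,
                             t(substitution_matrix),
                             check.attributes = FALSE)))
  list(matrix = substitution_matrix, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Optimal global pairwise alignment (Needleman-Wunsch/Gotoh)
#'
#' @param a,b protein sequences (plain strings, no gaps).
#' @param scoring [scoring_scheme()].
#' @return list with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings), `score`, `identity_pct`, `similarity_pct`.
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scoring$matrix,
    gapOpening = -(scoring$gap_open - scoring$gap_extend),
    gapExtension = -scoring$gap_extend, type = "global")
  res <- list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
              aligned_b = as.character(Biostrings::alignedSubject(pa)),
              score = Biostrings::score(pa))
  stats <- identity_similarity(res, scoring)
  res$identity_pct <- stats[["identity_pct"]]
  res$similarity_pct <- stats[["similarity_pct"]]
  res
}

#' Identity and similarity percentages of an alignment
#'
#' Identity: identical aligned pairs / length of the shorter input x 100.
#' Similarity: aligned pairs that are identical or have a positive
#' substitution score, same denominator.
#'
#' @param result list with `aligned_a`, `aligned_b`.
#' @param scoring [scoring_scheme()].
#' @export
identity_similarity <- function(result, scoring = scoring_scheme()) {
  x <- strsplit(result$aligned_a, "")[[1]]
  y <- strsplit(result$aligned_b, "")[[1]]
  stopifnot(length(x) == length(y))
  both <- x != "-" & y != "-"
  shorter <- min(sum(x != "-"), sum(y != "-"))
  ident <- sum(both & x == y)
  pos <- both & (x == y |
                   scoring$matrix[cbind(ifelse(both, x, "A"),
                                        ifelse(both, y, "A"))] > 0)
  c(identity_pct = 100 * ident / shorter,
    similarity_pct = 100 * sum(pos & both) / shorter)
}

#' All-pairs identity and similarity matrices
#'
#' @param records protein record data.frame (>= 2 rows).
#' @param scoring [scoring_scheme()].
#' @return list of two symmetric percent matrices (`identity`,
#'   `similarity`) with diagonal 100 and record ids as dimnames;
#'   attribute `n_alignments` records the number of alignments performed.
#' @export
pairwise_matrix <- function(records, scoring = scoring_scheme()) {
  n <- nrow(records)
  stopifnot(n >= 2)
  ids <- records$id
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  simm <- idm
  n_aln <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    r <- global_align(records$residues[i], records$residues[j], scoring)
    idm[i, j] <- idm[j, i] <- r$identity_pct
    simm[i, j] <- simm[j, i] <- r$similarity_pct
    n_aln <- n_aln + 1L
  }
  structure(list(identity = idm, similarity = simm),
            n_alignments = n_aln)
}

#' Write a percent matrix as TSV with ids as header row/column
#' @param mat square matrix with dimnames.
#' @param path output path.
#' @export
write_percent_matrix <- function(mat, path) {
  utils::write.table(data.frame(id = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
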