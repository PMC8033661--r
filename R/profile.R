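## Profile-seeded multiple alignment.
##
## The verified-avidin seed alignment is terminally trimmed, summarised as a
## per-column residue-frequency profile, and every putative sequence is
## aligned to that fixed profile by global dynamic programming.  The master
## column space equals the trimmed seed columns; residues falling between
## seed columns are recorded in an insertion log, never as new columns, so
## logo columns stay comparable across clades.

#' Convert an alignment (named gapped strings) to a character matrix
#' @param alignment named character vector of equal-length gapped strings.
#' @export
alignment_matrix <- function(alignment) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("ragged alignment")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Read / write an aligned FASTA file (gaps allowed)
#' @param path file path.
#' @return named character vector of gapped rows.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty alignment file: ", path)
  aln <- toupper(as.character(set))
  names(aln) <- sub("\\s.*$", "", names(set))
  if (length(unique(nchar(aln))) != 1) stop("ragged alignment in ", path)
  aln
}

#' @rdname read_alignment
#' @param alignment named character vector of gapped rows.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment)) {
    writeLines(paste0(">", names(alignment)[i]), con)
    s <- alignment[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Build a column-frequency profile from a seed alignment
#'
#' Terminal columns that are gap in more than half of the seed rows are
#' trimmed from both ends before profile construction.  Per-column residue
#' frequencies (gap-excluded) receive an additive pseudocount.
#'
#' @param seed_alignment named character vector of equal-length gapped rows.
#' @param pseudocount additive pseudocount weight per residue (default
#'   0.01).
#' @return list with `freq` (L x 20 matrix, rows sum to 1), `gap_freq`,
#'   `columns` (indices into the untrimmed seed), `seed` (trimmed rows).
#' @export
build_profile <- function(seed_alignment, pseudocount = 0.01) {
  m <- alignment_matrix(seed_alignment)
  gap_frac <- colMeans(m == "-")
  keep_from <- which(gap_frac <= 0.5)
  if (length(keep_from) == 0) stop("seed alignment is all gaps")
  lo <- min(keep_from); hi <- max(keep_from)
  cols <- lo:hi
  m <- m[, cols, drop = FALSE]
  freq <- t(apply(m, 2, function(col) {
    counts <- table(factor(col[col %in% AA_LEVELS], levels = AA_LEVELS))
    (counts + pseudocount) / (sum(counts) + 20 * pseudocount)
  }))
  dimnames(freq) <- list(NULL, AA_LEVELS)
  trimmed <- apply(m, 1, paste, collapse = "")
  list(freq = freq, gap_freq = colMeans(m == "-"), columns = cols,
       seed = stats::setNames(trimmed, rownames(m)),
       pseudocount = pseudocount)
}

#' Align one sequence to a fixed profile
#'
#' Global sequence-to-profile dynamic programming with affine gaps.  The
#' column match score is the expected substitution score of the residue
#' against the column's frequency vector.  Residues consumed between
#' profile columns go to the insertion log, anchored at the preceding
#' profile column (0 = before the first column).
#'
#' @param residues ungapped protein sequence.
#' @param profile result of [build_profile()].
#' @param scoring [scoring_scheme()].
#' @return list with `aligned` (string of length `ncol(profile)` over
#'   residues and `-`), `insertions` (data.frame anchor_col / residues),
#'   `score`, `domain_span` (0-based half-open residue interval aligned
#'   into the master columns).
#' @export
align_to_profile <- function(residues, profile, scoring = scoring_scheme()) {
  if (!nzchar(residues)) stop("empty record")
  seq_chars <- strsplit(toupper(residues), "")[[1]]
  m <- length(seq_chars)
  L <- nrow(profile$freq)
  go <- scoring$gap_open; ge <- scoring$gap_extend
  sub <- scoring$matrix[AA_LEVELS, AA_LEVELS]
  ## expected score of residue r against column j
  colscore <- profile$freq %*% t(sub)        # L x 20, col = residue
  ridx <- match(seq_chars, AA_LEVELS)        # NA for X
  S <- matrix(0, m, L)
  known <- !is.na(ridx)
  S[known, ] <- t(colscore[, ridx[known], drop = FALSE])
  NEG <- -1e9
  ## DP over (i residues, j columns); states M (consume both),
  ## D (consume column -> gap in row), I (consume residue -> insertion).
  ## Row-vectorised Gotoh: M and I depend on the previous row only; the
  ## horizontal D recurrence D[j+1] = max(c[j] + go, D[j] + ge) with
  ## c = pmax(M, I) unrolls to a running maximum.
  M <- matrix(NEG, m + 1, L + 1); D <- M; I <- M
  M[1, 1] <- 0
  if (L > 0) D[1, 2:(L + 1)] <- go + (seq_len(L) - 1) * ge
  jj <- seq_len(L)
  for (i in seq_len(m)) {
    Mp <- M[i, ]; Dp <- D[i, ]; Ip <- I[i, ]
    Mrow <- c(NEG, pmax(Mp[jj], Dp[jj], Ip[jj]) + S[i, ])
    Irow <- pmax(Mp + go, Dp + go, Ip + ge)
    cvec <- pmax(Mrow, Irow)
    t_k <- cvec[1:L] - (0:(L - 1)) * ge
    Drow <- c(NEG, go + (jj - 1) * ge + cummax(t_k))
    M[i + 1, ] <- Mrow; D[i + 1, ] <- Drow; I[i + 1, ] <- Irow
  }
  ends <- c(M[m + 1, L + 1], D[m + 1, L + 1], I[m + 1, L + 1])
  state <- which.max(ends)   # ties: M > D > I via which.max order
  score <- ends[state]
  ## traceback by recomputing, at each cell, which predecessor attains the
  ## stored value (tie-break M > D > I)
  eps <- 1e-7
  pick <- function(target, vm, vd, vi) {
    if (abs(vm - target) < eps) 1L
    else if (abs(vd - target) < eps) 2L else 3L
  }
  aligned <- character(L)
  ins_anchor <- integer(0); ins_res <- character(0)
  i <- m; j <- L
  while (i > 0 || j > 0) {
    if (state == 1L) {
      aligned[j] <- seq_chars[i]
      target <- M[i + 1, j + 1] - S[i, j]
      state <- pick(target, M[i, j], D[i, j], I[i, j])
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      aligned[j] <- "-"
      target <- D[i + 1, j + 1]
      state <- pick(target, M[i + 1, j] + go, D[i + 1, j] + ge,
                    I[i + 1, j] + go)
      j <- j - 1
    } else {
      ins_anchor <- c(ins_anchor, j); ins_res <- c(ins_res, seq_chars[i])
      target <- I[i + 1, j + 1]
      state <- pick(target, M[i, j + 1] + go, D[i, j + 1] + go,
                    I[i, j + 1] + ge)
      i <- i - 1
    }
  }
  insertions <- if (length(ins_anchor)) {
    sp <- split(rev(ins_res), rev(ins_anchor))
    data.frame(anchor_col = as.integer(names(sp)),
               residues = vapply(sp, paste, character(1), collapse = ""),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(anchor_col = integer(0), residues = character(0))
  n_lead <- if (nrow(insertions) && insertions$anchor_col[1] == 0)
    nchar(insertions$residues[1]) else 0L
  n_trail <- if (nrow(insertions) &&
                 insertions$anchor_col[nrow(insertions)] == L)
    nchar(insertions$residues[nrow(insertions)]) else 0L
  list(aligned = paste(aligned, collapse = ""), insertions = insertions,
       score = score, domain_span = c(n_lead, m - n_trail))
}

#' Build the master alignment of putative records over the seed columns
#'
#' Every record is aligned independently to the seed profile; the master
#' alignment contains the trimmed seed rows followed by the aligned
#' putative rows, all in the seed column space.
#'
#' @param seed_alignment named character vector of gapped seed rows.
#' @param records protein record data.frame (may be empty).
#' @param scoring [scoring_scheme()].
#' @param pseudocount see [build_profile()].
#' @return list with `alignment` (named gapped rows), `profile`,
#'   `insertions` (per-record list), `domain_spans` (per-record 0-based
#'   half-open residue intervals), `seed_ids`.
#' @export
build_master_alignment <- function(seed_alignment, records,
                                   scoring = scoring_scheme(),
                                   pseudocount = 0.01) {
  profile <- build_profile(seed_alignment, pseudocount)
  rows <- profile$seed
  insertions <- list()
  spans <- list()
  for (i in seq_len(NROW(records))) {
    r <- align_to_profile(records$residues[i], profile, scoring)
    rows[records$id[i]] <- r$aligned
    insertions[[records$id[i]]] <- r$insertions
    spans[[records$id[i]]] <- r$domain_span
  }
  list(alignment = rows, profile = profile, insertions = insertions,
       domain_spans = spans, seed_ids = names(profile$seed))
}
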