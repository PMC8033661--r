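## Conservation profiling over the master alignment: per-column residue
## frequencies and information content, sequence-logo matrices with the
## 20% occurrence rule, conserved-position calling in chicken-avidin
## reference numbering, biotin-binding-site substitution scoring, and
## terminal-extension flagging.

#' Residue physicochemical classes
#'
#' aromatic FWY; aliphatic-hydrophobic AVLIM; polar STNQ; positive KRH;
#' negative DE; special GPC.  Used to call substitutions conservative
#' (same class) or non-conservative (class change).
#' @export
RESIDUE_CLASSES <- c(F = "aromatic", W = "aromatic", Y = "aromatic",
                     A = "aliphatic", V = "aliphatic", L = "aliphatic",
                     I = "aliphatic", M = "aliphatic",
                     S = "polar", T = "polar", N = "polar", Q = "polar",
                     K = "positive", R = "positive", H = "positive",
                     D = "negative", E = "negative",
                     G = "special", P = "special", C = "special")

#' Logo configuration
#' @param min_occurrence residues at or below this frequency are dropped
#'   from logo matrices (default 0.20).
#' @param per_clade compute logos per clade as well as globally.
#' @export
logo_config <- function(min_occurrence = 0.20, per_clade = TRUE) {
  stopifnot(min_occurrence >= 0, min_occurrence < 1)
  list(min_occurrence = min_occurrence, per_clade = per_clade)
}

#' Per-column conservation profile
#'
#' Gap-excluded residue frequencies, occupancy and information content
#' (log2(20) minus the Shannon entropy of the frequencies) per master
#' column.  All-gap columns get zero occupancy and zero information.
#'
#' @param alignment named gapped rows or character matrix.
#' @return list with `freq` (L x 20), `occupancy`, `bits`.
#' @export
column_frequencies <- function(alignment) {
  m <- if (is.matrix(alignment)) alignment else alignment_matrix(alignment)
  L <- ncol(m)
  freq <- matrix(0, L, 20, dimnames = list(NULL, AA_LEVELS))
  occupancy <- colMeans(m != "-")
  bits <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    counts <- table(factor(col[col %in% AA_LEVELS], levels = AA_LEVELS))
    tot <- sum(counts)
    if (tot > 0) {
      f <- counts / tot
      freq[j, ] <- f
      nz <- f[f > 0]
      bits[j] <- log2(20) - (-sum(nz * log2(nz)))
    }
  }
  list(freq = freq, occupancy = occupancy, bits = bits)
}

#' Sequence-logo matrix with the 20% occurrence rule
#'
#' Residues whose column frequency is at or below `min_occurrence` are set
#' to zero; remaining frequencies are deliberately NOT renormalised (the
#' logo shows true occurrence).
#'
#' @param profile result of [column_frequencies()].
#' @param config [logo_config()].
#' @return L x 20 filtered frequency matrix.
#' @export
logo_matrix <- function(profile, config = logo_config()) {
  f <- profile$freq
  f[f <= config$min_occurrence] <- 0
  f
}

#' Map master columns to reference residue numbers
#'
#' @param alignment master alignment (named gapped rows).
#' @param ref_id row name of the reference sequence (e.g. chicken avidin).
#' @param ref_offset number of the reference's first residue (default 1).
#' @return data.frame with columns `column`, `ref_position`; one row per
#'   non-gap reference position, strictly increasing in both.
#' @export
reference_map <- function(alignment, ref_id, ref_offset = 1L) {
  if (!ref_id %in% names(alignment))
    stop("reference row '", ref_id, "' absent from alignment")
  chars <- strsplit(alignment[[ref_id]], "")[[1]]
  cols <- which(chars != "-")
  data.frame(column = cols,
             ref_position = seq_along(cols) + ref_offset - 1L)
}

#' Conserved positions in reference numbering
#'
#' Columns whose modal residue frequency reaches `threshold`, reported as
#' reference residue numbers (columns not covered by the reference are
#' dropped).
#'
#' @param profile result of [column_frequencies()].
#' @param ref_map result of [reference_map()].
#' @param threshold modal-frequency threshold (default 0.9).
#' @return integer vector of reference positions.
#' @export
conserved_positions <- function(profile, ref_map, threshold = 0.9) {
  modal <- apply(profile$freq, 1, max)
  cols <- which(modal >= threshold)
  sort(ref_map$ref_position[match(cols, ref_map$column, nomatch = 0)])
}

#' Classify binding-site residues of one aligned row
#'
#' At each biotin-binding reference position: `identical` if the residue
#' matches the reference, `conservative` if it belongs to the same
#' physicochemical class, `non_conservative` otherwise, `missing` if the
#' row is gapped there.
#'
#' @param aligned_row gapped string in master column space.
#' @param reference_row gapped reference string in the same column space.
#' @param binding_positions reference residue numbers in direct biotin
#'   contact.
#' @param ref_map result of [reference_map()].
#' @return data.frame with columns `ref_position`, `ref_residue`,
#'   `residue`, `class`.
#' @export
binding_site_conservation <- function(aligned_row, reference_row,
                                      binding_positions, ref_map) {
  a <- strsplit(aligned_row, "")[[1]]
  r <- strsplit(reference_row, "")[[1]]
  cols <- ref_map$column[match(binding_positions, ref_map$ref_position)]
  if (anyNA(cols))
    stop("binding position(s) outside the reference map: ",
         paste(binding_positions[is.na(cols)], collapse = ", "))
  res <- a[cols]; ref <- r[cols]
  cls <- ifelse(res == "-", "missing",
         ifelse(res == ref, "identical",
         ifelse(!is.na(RESIDUE_CLASSES[res]) & !is.na(RESIDUE_CLASSES[ref]) &
                  RESIDUE_CLASSES[res] == RESIDUE_CLASSES[ref],
                "conservative", "non_conservative")))
  data.frame(ref_position = binding_positions, ref_residue = ref,
             residue = res, class = unname(cls), stringsAsFactors = FALSE)
}

#' Flag terminal extensions beyond the aligned avidin domain
#'
#' @param record_length total residue count of the unaligned record.
#' @param domain_span 0-based half-open residue interval aligned into the
#'   master columns (from [align_to_profile()]).
#' @param min_extension minimum length (residues) to flag (default 100).
#' @return list with `terminus` (`"N"`, `"C"`, `"both"`, `"none"`),
#'   `n_length`, `c_length`.
#' @export
flag_extended <- function(record_length, domain_span, min_extension = 100L) {
  if (length(domain_span) != 2 || domain_span[2] <= domain_span[1])
    stop("empty domain span (no aligned residues)")
  n_len <- domain_span[1]
  c_len <- record_length - domain_span[2]
  stopifnot(n_len >= 0, c_len >= 0)
  terminus <- if (n_len >= min_extension && c_len >= min_extension) "both"
    else if (n_len >= min_extension) "N"
    else if (c_len >= min_extension) "C"
    else "none"
  list(terminus = terminus, n_length = n_len, c_length = c_len)
}

#' Chicken-avidin biotin-binding residue numbers (direct contacts)
#'
#' Mature chicken-avidin numbering of residues in direct contact with
#' bound biotin, assembled from the structural literature on the
#' avidin-biotin complex (includes the Trp70 / Trp110 positions whose
#' substitution abolishes binding).
#' @export
AVIDIN_BIOTIN_CONTACTS <- c(12L, 13L, 14L, 15L, 16L, 33L, 35L, 37L, 40L,
                            43L, 70L, 72L, 77L, 97L, 110L, 117L)
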