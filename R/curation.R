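## Post-search curation of the candidate avidin set: removal of synthetic
## entries, deduplication, short-nucleotide flagging, translation, merging
## translated records into the protein set, and representative selection by
## single-linkage identity clustering.

#' Curation configuration
#'
#' @param min_nt_length nucleotide records shorter than this (bp) are
#'   flagged as needing genomic-context extension; default 300.
#' @param provenance_evalue_max,provenance_identity_min provenance filters
#'   applied to user-supplied hit tables (E-value cut-off 0.01, identity
#'   > 19%); retained as record-keeping thresholds.
#' @param representative_identity single-linkage identity threshold for
#'   representative selection; default 0.95.
#' @param synthetic_keywords id/description keywords marking synthetic or
#'   engineered entries to be removed.
#' @export
curation_config <- function(min_nt_length = 300L,
                            provenance_evalue_max = 0.01,
                            provenance_identity_min = 0.19,
                            representative_identity = 0.95,
                            synthetic_keywords = c("synthetic", "artificial",
                                                   "vector", "construct")) {
  stopifnot(min_nt_length > 0,
            provenance_identity_min > 0,
            provenance_identity_min < representative_identity,
            representative_identity <= 1)
  list(min_nt_length = as.integer(min_nt_length),
       provenance_evalue_max = provenance_evalue_max,
       provenance_identity_min = provenance_identity_min,
       representative_identity = representative_identity,
       synthetic_keywords = synthetic_keywords)
}

#' Remove synthetic / engineered entries
#'
#' Drops records whose id or description contains any configured keyword
#' (case-insensitive).
#'
#' @param records sequence record data.frame.
#' @param config [curation_config()].
#' @export
remove_synthetic <- function(records, config = curation_config()) {
  if (nrow(records) == 0) return(records)
  pat <- paste(config$synthetic_keywords, collapse = "|")
  hit <- grepl(pat, records$id, ignore.case = TRUE) |
    grepl(pat, records$description, ignore.case = TRUE)
  records[!hit, , drop = FALSE]
}

#' Collapse records with identical residues
#'
#' Case-insensitive on the residue string; the first-seen record of each
#' group is kept, input order otherwise preserved.
#'
#' @param records sequence record data.frame.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  keep <- !duplicated(toupper(records$residues))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag nucleotide records too short to span an avidin domain
#'
#' Records shorter than `min_nt_length` bp are flagged `needs_extension`
#' (extension from genomic context requires the genome and is out of scope);
#' nothing is dropped.
#'
#' @param records nucleotide record data.frame.
#' @param config [curation_config()].
#' @return list with elements `kept` and `flagged`.
#' @export
flag_short_nucleotides <- function(records, config = curation_config()) {
  if (any(records$moltype != "nucleotide"))
    stop("flag_short_nucleotides expects nucleotide records")
  short <- nchar(records$residues) < config$min_nt_length
  list(kept = records[!short, , drop = FALSE],
       flagged = records[short, , drop = FALSE])
}

#' Translate a nucleotide record (frame 0, standard code)
#'
#' Translation runs up to (and excluding) the first stop codon; codons
#' containing an ambiguity code translate to `X`.
#'
#' @param record single-row nucleotide record data.frame.
#' @return single-row protein record with the same id.
#' @export
translate_cds <- function(record) {
  stopifnot(nrow(record) == 1)
  if (record$moltype != "nucleotide") stop("expected a nucleotide record")
  n <- nchar(record$residues)
  if (n < 3) stop("sequence shorter than one codon")
  s <- substr(record$residues, 1, n - n %% 3)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X"))
  aa <- sub("\\*.*$", "", aa)
  if (!nzchar(aa)) stop("translation is empty (immediate stop codon)")
  sequence_records(record$id, aa, "protein",
                   description = record$description,
                   organism = record$organism)
}

#' Merge translated records into the protein set
#'
#' Translated records whose residues exactly match an existing protein
#' (case-insensitive, full length) are discarded; novel ones are appended.
#'
#' @param proteins,translated deduplicated protein record data.frames.
#' @export
merge_nt_into_protein_set <- function(proteins, translated) {
  if (nrow(translated) == 0) return(proteins)
  novel <- !toupper(translated$residues) %in% toupper(proteins$residues) &
    !translated$id %in% proteins$id
  out <- rbind(proteins, translated[novel, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Select representative sequences by single-linkage identity clustering
#'
#' Records joined by pairwise identity >= `representative_identity` fall in
#' one cluster; the representative is the longest sequence, ties broken by
#' lexicographic id.
#'
#' @param records protein record data.frame.
#' @param config [curation_config()].
#' @param pairwise_identity function(record_a, record_b) -> identity
#'   fraction in \[0, 1\]; defaults to BLOSUM62 global alignment identity
#'   from the alignment module.
#' @return data.frame with columns record_id, cluster_id,
#'   is_representative.
#' @export
select_representatives <- function(records, config = curation_config(),
                                   pairwise_identity = NULL) {
  n <- nrow(records)
  if (is.null(pairwise_identity)) {
    scheme <- scoring_scheme()
    pairwise_identity <- function(a, b)
      global_align(a$residues, b$residues, scheme)$identity_pct / 100
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (pairwise_identity(records[i, ], records[j, ]) >=
          config$representative_identity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cluster_id <- match(root, unique(root))
  rep_flag <- logical(n)
  for (cl in unique(cluster_id)) {
    members <- which(cluster_id == cl)
    len <- nchar(records$residues[members])
    best <- members[order(-len, records$id[members])][1]
    rep_flag[best] <- TRUE
  }
  data.frame(record_id = records$id,
             cluster_id = sprintf("cluster_%03d", cluster_id),
             is_representative = rep_flag, stringsAsFactors = FALSE)
}

#' Run the full curation stage
#'
#' Synthetic-entry removal and deduplication of the protein set;
#' deduplication, short-record flagging and translation of the nucleotide
#' set; merge of novel translations into the protein set.
#'
#' @param proteins protein records (may have 0 rows).
#' @param nucleotides nucleotide records (may be NULL).
#' @param config [curation_config()].
#' @return list with `records` (curated protein set), `flagged_short`
#'   (nucleotide records needing extension), `n_removed_synthetic`.
#' @export
curate_sequences <- function(proteins, nucleotides = NULL,
                             config = curation_config()) {
  n0 <- nrow(proteins)
  proteins <- remove_synthetic(proteins, config)
  n_removed_synthetic <- n0 - nrow(proteins)
  proteins <- deduplicate(proteins)
  flagged <- NULL
  if (!is.null(nucleotides) && nrow(nucleotides) > 0) {
    nucleotides <- deduplicate(remove_synthetic(nucleotides, config))
    fl <- flag_short_nucleotides(nucleotides, config)
    flagged <- fl$flagged
    translated <- do.call(rbind, lapply(seq_len(nrow(fl$kept)), function(i)
      translate_cds(fl$kept[i, , drop = FALSE])))
    if (!is.null(translated))
      proteins <- merge_nt_into_protein_set(proteins, deduplicate(translated))
  }
  list(records = proteins, flagged_short = flagged,
       n_removed_synthetic = n_removed_synthetic)
}
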