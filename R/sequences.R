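## Sequence records and FASTA input/output.
##
## A sequence set is a plain data.frame with columns id, description,
## residues, moltype ("protein" or "nucleotide") and organism, one row per
## record.  Identifier = header token before the first whitespace.

PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                      "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
NUCLEOTIDE_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a sequence record set
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of sequences (no gaps).
#' @param moltype `"protein"` or `"nucleotide"` (recycled).
#' @param description,organism optional character vectors.
#' @return data.frame with one row per record.
#' @export
sequence_records <- function(id, residues, moltype = "protein",
                             description = "", organism = NA_character_) {
  stopifnot(length(id) == length(residues))
  df <- data.frame(id = as.character(id),
                   description = rep_len(as.character(description), length(id)),
                   residues = as.character(residues),
                   moltype = rep_len(moltype, length(id)),
                   organism = rep_len(as.character(organism), length(id)),
                   stringsAsFactors = FALSE)
  validate_records(df)
  df
}

#' @keywords internal
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(invisible(records))
  if (any(!nzchar(records$id)))
    stop("empty sequence id")
  dup <- records$id[duplicated(records$id)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(records$residues)))
    stop("empty residues for id(s): ",
         paste(records$id[!nzchar(records$residues)], collapse = ", "))
  if (!all(records$moltype %in% c("protein", "nucleotide")))
    stop("moltype must be 'protein' or 'nucleotide'")
  for (i in seq_len(nrow(records))) {
    alphabet <- if (records$moltype[i] == "protein") PROTEIN_ALPHABET
                else NUCLEOTIDE_ALPHABET
    chars <- strsplit(toupper(records$residues[i]), "")[[1]]
    bad <- which(!chars %in% alphabet)
    if (length(bad))
      stop(sprintf("record '%s': character '%s' at position %d not in %s alphabet",
                   records$id[i], chars[bad[1]], bad[1], records$moltype[i]))
  }
  invisible(records)
}

#' Read a FASTA file
#'
#' Wrapped lines are concatenated; the header is split at the first
#' whitespace into id and description.  Duplicate ids and characters outside
#' the moltype alphabet (plus ambiguity codes X/N) are errors.
#'
#' @param path file path.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return sequence record data.frame (see [sequence_records()]).
#' @export
read_fasta <- function(path, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  records <- data.frame(id = id, description = description,
                        residues = toupper(as.character(set)),
                        moltype = moltype, organism = NA_character_,
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  validate_records(records)
  records
}

#' Write records to FASTA
#'
#' @param records sequence record data.frame.
#' @param path output path.
#' @param wrap_width sequence line width (default 60).
#' @export
write_fasta <- function(records, path, wrap_width = 60L) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("no records to write")
  validate_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[i]))
      paste(records$id[i], records$description[i]) else records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = wrap_width)
    writeLines(substring(s, starts, pmin(starts + wrap_width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @export
survey_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "avidinsurvey")))
  path <- system.file("extdata", file, package = "avidinsurvey",
                      mustWork = TRUE)
  path
}
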