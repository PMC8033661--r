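## Genome feature tables, functional-term references, species metadata and
## fixed-layout results tables.
##
## Internal coordinates are 0-based half-open [start, end); GFF3 input
## (1-based inclusive) is converted at the boundary, and written back out as
## the identity on the original values.

TERM_PATTERNS <- c(GO = "^GO:\\d{7}$", PFAM = "^PF\\d{5}$",
                   IPR = "^IPR\\d{6}$", TIGRFAM = "^TIGR\\d{5}$")

#' Namespace of a functional-term accession
#'
#' @param accession character vector of accessions such as `"GO:0006310"`,
#'   `"PF00082"`, `"IPR000001"`, `"TIGR00001"`.
#' @return character vector over `{GO, PFAM, IPR, TIGRFAM}`; error for an
#'   accession matching no known pattern.
#' @export
term_namespace <- function(accession) {
  out <- rep(NA_character_, length(accession))
  for (ns in names(TERM_PATTERNS))
    out[grepl(TERM_PATTERNS[[ns]], accession)] <- ns
  if (anyNA(out))
    stop("unrecognized term accession(s): ",
         paste(accession[is.na(out)], collapse = ", "))
  out
}

new_feature_table <- function(genome_id, replicon_id, replicon_type, start,
                              end, strand, feature_id, product, terms,
                              is_focal) {
  stopifnot(all(start >= 0), all(start < end))
  df <- data.frame(genome_id = genome_id, replicon_id = replicon_id,
                   replicon_type = replicon_type,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, feature_id = feature_id,
                   product = product, is_focal = as.logical(is_focal),
                   stringsAsFactors = FALSE)
  df$terms <- terms  # list column of character accession vectors
  if (anyDuplicated(paste(df$genome_id, df$feature_id)))
    stop("duplicate feature_id within a genome")
  df
}

parse_gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]*)"), attr))
  vapply(m, function(x) if (length(x) == 2) utils::URLdecode(x[2]) else
         NA_character_, character(1))
}

#' Read a genome feature table
#'
#' Two dialects: `"gff3"` (standard 1-based inclusive coordinates, attribute
#' keys `ID`, `product`, `Ontology_term`, `Dbxref`; converted to internal
#' 0-based half-open) and `"tsv"` (the package's own tab-separated layout,
#' already 0-based half-open, written by [write_feature_table()]).
#'
#' @param path file path.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param genome_id genome label for gff3 input (tsv carries its own).
#' @param replicon_types named character vector mapping replicon id to
#'   `"chromosome"`/`"plasmid"`; unmapped replicons become `"unknown"`.
#' @param focal_ids feature ids to mark as focal (avidin) genes for gff3
#'   input; the tsv dialect carries an `is_focal` column.
#' @return feature data.frame with columns genome_id, replicon_id,
#'   replicon_type, start, end, strand, feature_id, product, is_focal and a
#'   list column `terms`.
#' @export
read_feature_table <- function(path, dialect = c("gff3", "tsv"),
                               genome_id = "genome", replicon_types = NULL,
                               focal_ids = character()) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "gff3") {
    g <- ape::read.gff(path)
    if (any(g$start > g$end)) stop("GFF3 start > end")
    ids <- parse_gff_attr(g$attributes, "ID")
    missing_id <- which(is.na(ids))
    if (length(missing_id)) {
      ids[missing_id] <- sprintf("%s_feat%04d", genome_id, missing_id)
      warning(length(missing_id), " feature(s) missing ID; synthesized")
    }
    product <- parse_gff_attr(g$attributes, "product")
    product[is.na(product)] <- ""
    terms <- lapply(seq_len(nrow(g)), function(i) {
      raw <- c(parse_gff_attr(g$attributes[i], "Ontology_term"),
               parse_gff_attr(g$attributes[i], "Dbxref"))
      raw <- as.character(unlist(strsplit(raw[!is.na(raw)], ",")))
      raw <- raw[grepl(paste(TERM_PATTERNS, collapse = "|"), raw)]
      unique(raw)
    })
    rtype <- rep("unknown", nrow(g))
    if (!is.null(replicon_types)) {
      hit <- match(as.character(g$seqid), names(replicon_types))
      rtype[!is.na(hit)] <- replicon_types[hit[!is.na(hit)]]
    }
    new_feature_table(genome_id, as.character(g$seqid), rtype,
                      g$start - 1L, g$end, as.character(g$strand), ids,
                      product, terms, ids %in% focal_ids)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("genome_id", "replicon_id", "replicon_type", "start", "end",
              "strand", "feature_id", "product", "terms", "is_focal")
    if (!all(need %in% names(d)))
      stop("tsv feature table missing column(s): ",
           paste(setdiff(need, names(d)), collapse = ", "))
    if (any(as.integer(d$start) > as.integer(d$end))) stop("start > end")
    terms <- lapply(strsplit(d$terms, ";", fixed = TRUE),
                    function(x) x[nzchar(x) & x != "."])
    new_feature_table(d$genome_id, d$replicon_id, d$replicon_type,
                      as.integer(d$start), as.integer(d$end), d$strand,
                      d$feature_id, ifelse(d$product == ".", "", d$product),
                      terms, d$is_focal %in% c("TRUE", "true", "1"))
  }
}

#' Write a feature table in the package's tsv dialect
#'
#' @param features feature data.frame.
#' @param path output path.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  out$terms <- vapply(features$terms, function(x)
    if (length(x)) paste(x, collapse = ";") else ".", character(1))
  out$product <- ifelse(nzchar(out$product), out$product, ".")
  cols <- c("genome_id", "replicon_id", "replicon_type", "start", "end",
            "strand", "feature_id", "product", "terms", "is_focal")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

HABITAT_VOCABULARY <- c("soil", "aquatic", "plant-associated",
                        "animal-associated")
PATHOGEN_VOCABULARY <- c("human/animal", "plant", "fungus", "none")

#' Read a species metadata table
#'
#' Delimited text with a header row and columns `species`, `phylum`,
#' `habitats`, `pathogen_of`, `gene_location`, `copy_count`; multi-valued
#' cells use `";"`.  Vocabulary is normalised to lower case; habitat tokens
#' outside the controlled vocabulary are kept verbatim with a warning.
#'
#' @param path file path (tab-separated).
#' @return data.frame, one row per species, with list columns `habitats`
#'   and `pathogen_of`.
#' @export
read_species_metadata <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("species", "phylum", "habitats", "pathogen_of", "gene_location",
            "copy_count")
  if (!all(need %in% names(d)))
    stop("metadata missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  dup <- d$species[duplicated(d$species)]
  if (length(dup)) stop("duplicate species: ", paste(dup, collapse = ", "))
  split_multi <- function(x) lapply(strsplit(tolower(x), ";", fixed = TRUE),
                                    function(v) trimws(v[nzchar(trimws(v))]))
  habitats <- split_multi(d$habitats)
  unknown <- setdiff(unique(unlist(habitats)), HABITAT_VOCABULARY)
  if (length(unknown))
    warning("habitat token(s) outside controlled vocabulary kept verbatim: ",
            paste(unknown, collapse = ", "))
  loc <- tolower(trimws(d$gene_location))
  loc[!loc %in% c("plasmid", "genome")] <- NA_character_
  copies <- suppressWarnings(as.integer(d$copy_count))
  if (any(!is.na(copies) & copies < 1)) stop("copy_count must be >= 1")
  out <- data.frame(species = d$species, phylum = d$phylum,
                    gene_location = loc, copy_count = copies,
                    stringsAsFactors = FALSE)
  out$habitats <- habitats
  out$pathogen_of <- split_multi(d$pathogen_of)
  out
}

RESULTS_SCHEMAS <- list(
  enrichment   = c("term", "a", "b", "c", "d", "odds_ratio", "p", "q"),
  clusters     = c("record_id", "cluster_id", "is_representative"),
  clades       = c("leaf", "clade"),
  conservation = c("column", "ref_position", "top_residue", "top_frequency",
                   "occupancy", "bits"),
  extensions   = c("record_id", "terminus", "n_length", "c_length"),
  identity     = NULL  # square matrix, ids as header row/column
)

#' Write a results table with a fixed column order
#'
#' Tab-separated, `"."` for missing values, p/q values in scientific
#' notation with 4 significant digits.  Column order is fixed per table
#' type (see `RESULTS_SCHEMAS`).
#'
#' @param rows data.frame of results.
#' @param path output path.
#' @param type one of `"enrichment"`, `"clusters"`, `"clades"`,
#'   `"conservation"`, `"extensions"`.
#' @export
write_results_table <- function(rows, path,
                                type = names(RESULTS_SCHEMAS)[1:5]) {
  type <- match.arg(type)
  cols <- RESULTS_SCHEMAS[[type]]
  if (!is.data.frame(rows))
    stop("rows must be a data.frame with a homogeneous schema")
  if (nrow(rows) > 0 && !all(cols %in% names(rows)))
    stop("missing column(s) for ", type, " table: ",
         paste(setdiff(cols, names(rows)), collapse = ", "))
  if (nrow(rows) == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- rows[, cols, drop = FALSE]
  for (pcol in intersect(c("p", "q"), cols))
    out[[pcol]] <- format(out[[pcol]], digits = 4, scientific = TRUE)
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v)) v <- ifelse(is.infinite(v), "Inf", as.character(v))
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
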