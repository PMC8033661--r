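## Habitat / lifestyle / genomic-location / copy-number tabulations of the
## species metadata table (the survey's ecological overview).

#' Habitat and pathogen-lifestyle tabulation
#'
#' Habitat categories overlap: a species counts once in every category it
#' carries; the percent denominator is the total species count, rounded to
#' the nearest integer (reporting convention of the survey).
#'
#' @param metadata species metadata (see [read_species_metadata()]).
#' @return list with `habitat` (data.frame category/count/percent),
#'   `pathogen_species` (count of species that are pathogens of anything),
#'   `pathogen_percent`, `n_species`.
#' @export
summarize_habitats <- function(metadata) {
  n <- nrow(metadata)
  if (n == 0) stop("empty metadata table")
  cats <- sort(unique(unlist(metadata$habitats)))
  counts <- vapply(cats, function(cat)
    sum(vapply(metadata$habitats, function(h) cat %in% h, logical(1))),
    integer(1))
  pathogen <- vapply(metadata$pathogen_of, function(p)
    length(setdiff(p, "none")) > 0, logical(1))
  list(habitat = data.frame(category = cats, count = unname(counts),
                            percent = round(100 * unname(counts) / n),
                            stringsAsFactors = FALSE),
       pathogen_species = sum(pathogen),
       pathogen_percent = round(100 * sum(pathogen) / n),
       n_species = n)
}

#' Genomic-location tabulation
#'
#' Counts by gene location (plasmid / genome / NA) and the mobile-element
#' percentage `plasmid / (plasmid + genome) * 100` (one decimal).
#'
#' @param metadata species metadata.
#' @export
summarize_location <- function(metadata) {
  loc <- metadata$gene_location
  plasmid <- sum(loc == "plasmid", na.rm = TRUE)
  genome <- sum(loc == "genome", na.rm = TRUE)
  na <- sum(is.na(loc))
  list(plasmid = plasmid, genome = genome, not_available = na,
       mobile_percent = if (plasmid + genome > 0)
         round(100 * plasmid / (plasmid + genome), 1) else NA_real_)
}

#' Copy-number histogram and multi-copy count
#'
#' @param metadata species metadata.
#' @return list with `histogram` (named counts over copy number),
#'   `multi_copy` (species with more than one avidin gene),
#'   `not_available`.
#' @export
summarize_copies <- function(metadata) {
  copies <- metadata$copy_count
  known <- copies[!is.na(copies)]
  hist <- table(known)
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       multi_copy = sum(known > 1),
       not_available = sum(is.na(copies)))
}

#' Full ecological survey summary
#'
#' @param metadata species metadata.
#' @return list combining [summarize_habitats()], [summarize_location()]
#'   and [summarize_copies()].
#' @export
survey_summary <- function(metadata) {
  list(habitats = summarize_habitats(metadata),
       location = summarize_location(metadata),
       copies = summarize_copies(metadata))
}
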