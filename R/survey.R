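## End-to-end orchestration of the survey: curation, pairwise matrices,
## profile-seeded master alignment, phylogeny with bootstrap, clades,
## conservation / logos / extension flags, neighbourhood enrichment and
## ecology tabulations, with a run manifest.

#' Survey configuration
#'
#' All stage configurations in one object.  Inputs may be in-memory
#' objects or file paths (paths are read with the io functions).
#'
#' @param sequences protein records (data.frame) or FASTA path. Mandatory.
#' @param seed_alignment named gapped rows or aligned-FASTA path.
#'   Mandatory.
#' @param nucleotides optional nucleotide records or FASTA path.
#' @param features optional pooled feature data.frame or tsv-dialect path.
#' @param fallback_map optional data.frame (accession, go) or TSV path.
#' @param metadata optional species metadata data.frame or TSV path.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param seed global RNG seed.
#' @param curation,scoring,phylo,logo,enrichment stage configurations.
#' @param conservation_threshold modal frequency for a conserved call.
#' @param min_extension terminal-extension flag threshold (residues).
#' @export
survey_config <- function(sequences, seed_alignment, nucleotides = NULL,
                          features = NULL, fallback_map = NULL,
                          metadata = NULL, outdir = NULL, seed = 1L,
                          curation = curation_config(),
                          scoring = scoring_scheme(),
                          phylo = phylo_config(seed = seed),
                          logo = logo_config(),
                          enrichment = enrichment_config(),
                          conservation_threshold = 0.9,
                          min_extension = 100L) {
  if (missing(sequences) || is.null(sequences))
    stop("sequences input is mandatory")
  if (missing(seed_alignment) || is.null(seed_alignment))
    stop("seed_alignment input is mandatory")
  list(sequences = sequences, seed_alignment = seed_alignment,
       nucleotides = nucleotides, features = features,
       fallback_map = fallback_map, metadata = metadata, outdir = outdir,
       seed = as.integer(seed), curation = curation, scoring = scoring,
       phylo = phylo, logo = logo, enrichment = enrichment,
       conservation_threshold = conservation_threshold,
       min_extension = as.integer(min_extension))
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) reader(x) else x
}

#' Run the full avidin-family survey
#'
#' Stages: curation and representative selection; pairwise
#' identity/similarity matrices; profile-seeded master alignment; partial
#' deletion, JTT-ML distances, neighbour joining with bootstrap supports;
#' clade extraction; conservation profile, logo matrices (global and per
#' clade) and terminal-extension flags; neighbourhood GO enrichment (if
#' feature tables are given); ecology tabulations (if metadata is given).
#' Stages with absent optional inputs are skipped with a notice in the
#' manifest.
#'
#' @param config [survey_config()].
#' @return list with elements `curation`, `clusters`, `pairwise`,
#'   `master`, `tree`, `clades`, `conservation`, `logos`, `extensions`,
#'   `enrichment`, `ecology`, `manifest`; files are written under
#'   `config$outdir` when set.
#' @export
run_survey <- function(config) {
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, stages = character(0),
                   warnings = character(0))
  note <- function(msg) manifest$warnings <<- c(manifest$warnings, msg)
  stage <- function(nm) manifest$stages <<- c(manifest$stages, nm)

  proteins <- resolve_input(config$sequences,
                            function(p) read_fasta(p, "protein"))
  seed_aln <- resolve_input(config$seed_alignment, read_alignment)
  nts <- resolve_input(config$nucleotides,
                       function(p) read_fasta(p, "nucleotide"))
  features <- resolve_input(config$features,
                            function(p) read_feature_table(p, "tsv"))
  fmap <- resolve_input(config$fallback_map, function(p)
    utils::read.delim(p, stringsAsFactors = FALSE))
  metadata <- resolve_input(config$metadata, read_species_metadata)

  ## --- curation ---------------------------------------------------------
  stage("curate")
  cur <- curate_sequences(proteins, nts, config$curation)
  records <- cur$records
  clusters <- select_representatives(records, config$curation)
  reps <- records[records$id %in%
                    clusters$record_id[clusters$is_representative], ,
                  drop = FALSE]

  ## --- pairwise matrices ------------------------------------------------
  stage("pairwise")
  pw <- if (nrow(reps) >= 2) pairwise_matrix(reps, config$scoring) else NULL

  ## --- master alignment -------------------------------------------------
  stage("align")
  master <- build_master_alignment(seed_aln, reps, config$scoring)

  ## --- phylogeny --------------------------------------------------------
  stage("tree")
  putative_rows <- master$alignment[setdiff(names(master$alignment),
                                            master$seed_ids)]
  tree_rows <- if (length(putative_rows) >= 3) putative_rows
               else master$alignment
  cols <- apply_partial_deletion(tree_rows, config$phylo$site_coverage)
  tree <- bootstrap_support(cols, config$phylo)
  clades <- extract_clades(tree, config$phylo$clade_min_support,
                           config$phylo$clade_min_size,
                           config$phylo$clade_min_stem)

  ## --- conservation -----------------------------------------------------
  stage("conserve")
  profile <- column_frequencies(master$alignment)
  logos <- list(global = logo_matrix(profile, config$logo))
  if (config$logo$per_clade) {
    for (cl in setdiff(unique(clades$clade), "outlier")) {
      rows <- master$alignment[clades$leaf[clades$clade == cl]]
      logos[[cl]] <- logo_matrix(column_frequencies(rows), config$logo)
    }
  }
  extensions <- do.call(rbind, lapply(names(master$domain_spans),
    function(id) {
      fl <- flag_extended(nchar(records$residues[records$id == id]),
                          master$domain_spans[[id]], config$min_extension)
      data.frame(record_id = id, terminus = fl$terminus,
                 n_length = fl$n_length, c_length = fl$c_length,
                 stringsAsFactors = FALSE)
    }))

  ## --- enrichment -------------------------------------------------------
  enr <- NULL
  if (!is.null(features)) {
    stage("enrich")
    enr <- enrich(features, config$enrichment, fmap)
  } else note("no feature tables: enrichment skipped")

  ## --- ecology ----------------------------------------------------------
  eco <- NULL
  if (!is.null(metadata)) {
    stage("ecology")
    eco <- survey_summary(metadata)
  } else note("no species metadata: ecology skipped")

  manifest$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out <- list(curation = cur, clusters = clusters, pairwise = pw,
              master = master, tree = tree, clades = clades,
              conservation = profile, logos = logos,
              extensions = extensions, enrichment = enr, ecology = eco,
              manifest = manifest)
  if (!is.null(config$outdir)) write_survey_outputs(out, config)
  out
}

#' @keywords internal
write_survey_outputs <- function(out, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)
  write_fasta(out$curation$records, p("curated.fasta"))
  write_results_table(out$clusters, p("clusters.tsv"), "clusters")
  if (!is.null(out$pairwise)) {
    write_percent_matrix(out$pairwise$identity, p("identity.tsv"))
    write_percent_matrix(out$pairwise$similarity, p("similarity.tsv"))
  }
  write_alignment(out$master$alignment, p("master_alignment.fasta"))
  write_newick(out$tree, p("tree.nwk"))
  write_results_table(out$clades, p("clades.tsv"), "clades")
  prof <- out$conservation
  cons <- data.frame(column = seq_along(prof$occupancy),
                     ref_position = NA_integer_,
                     top_residue = AA_LEVELS[max.col(prof$freq,
                                                     ties.method = "first")],
                     top_frequency = apply(prof$freq, 1, max),
                     occupancy = prof$occupancy, bits = prof$bits)
  write_results_table(cons, p("conservation.tsv"), "conservation")
  write_results_table(out$extensions, p("extensions.tsv"), "extensions")
  if (!is.null(out$enrichment))
    write_results_table(out$enrichment, p("enrichment.tsv"), "enrichment")
  if (!is.null(out$ecology))
    jsonlite::write_json(out$ecology, p("ecology.json"), auto_unbox = TRUE,
                         digits = NA)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$outdir)
}
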