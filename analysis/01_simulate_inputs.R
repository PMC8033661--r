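#!/usr/bin/env Rscript
# Generate the synthetic study inputs: an avidin-like protein family of
# 30 sequences in 5 planted clades (128 residues, JTT model), a 6-row
# verified-seed alignment drawn from the family, five annotated toy
# genomes with a GO term planted next to the focal avidin genes, and the
# species metadata table.  Everything downstream reads from results/inputs.

suppressMessages(library(avidinsurvey))

outdir <- "results/inputs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fam <- simulate_family_with_clades(family_sim_config(seed = 101))
seed_ids <- fam$records$id[seq(1, nrow(fam$records), by = 5)]
seed_aln <- setNames(fam$records$residues[match(seed_ids, fam$records$id)],
                     seed_ids)
putative <- fam$records[!fam$records$id %in% seed_ids, ]

write_fasta(putative, file.path(outdir, "putative_avidins.fasta"))
write_alignment(seed_aln, file.path(outdir, "seed_alignment.fasta"))
write_newick(fam$truth$tree, file.path(outdir, "true_tree.nwk"))
utils::write.table(
  data.frame(leaf = names(fam$truth$labels),
             clade = unname(fam$truth$labels)),
  file.path(outdir, "true_clades.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

sim <- simulate_genomes(genome_sim_config(seed = 101))
write_feature_table(sim$features, file.path(outdir, "features.tsv"))
utils::write.table(sim$fallback_map, file.path(outdir, "fallback_map.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(sim$truth, file.path(outdir, "genome_truth.json"),
                     auto_unbox = TRUE)

file.copy(survey_example("table_s1_synthetic.tsv"),
          file.path(outdir, "species_metadata.tsv"), overwrite = TRUE)

cat(sprintf("wrote %d putative sequences, %d seed rows, %d genome features\n",
            nrow(putative), length(seed_aln), nrow(sim$features)))
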