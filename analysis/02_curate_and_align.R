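#!/usr/bin/env Rscript
# Curate the candidate set (dedup, synthetic-entry filter, representative
# selection), compute MatGAT-style identity/similarity matrices, and build
# the profile-seeded master alignment over the verified-seed columns.

suppressMessages(library(avidinsurvey))

indir <- "results/inputs"; outdir <- "results"
records <- read_fasta(file.path(indir, "putative_avidins.fasta"), "protein")
seed_aln <- read_alignment(file.path(indir, "seed_alignment.fasta"))

cur <- curate_sequences(records, config = curation_config())
clusters <- select_representatives(cur$records)
reps <- cur$records[cur$records$id %in%
                      clusters$record_id[clusters$is_representative], ]
cat(sprintf("curated %d -> %d records (%d clusters)\n", nrow(records),
            nrow(reps), length(unique(clusters$cluster_id))))
write_fasta(cur$records, file.path(outdir, "curated.fasta"))
write_results_table(clusters, file.path(outdir, "clusters.tsv"), "clusters")

pw <- pairwise_matrix(reps)
write_percent_matrix(pw$identity, file.path(outdir, "identity.tsv"))
write_percent_matrix(pw$similarity, file.path(outdir, "similarity.tsv"))
offdiag <- pw$identity[lower.tri(pw$identity)]
cat(sprintf("pairwise identity: median %.1f%%, range %.1f-%.1f%%\n",
            median(offdiag), min(offdiag), max(offdiag)))

master <- build_master_alignment(seed_aln, reps)
write_alignment(master$alignment,
                file.path(outdir, "master_alignment.fasta"))
cat(sprintf("master alignment: %d rows x %d columns, %d insertion events\n",
            length(master$alignment), nchar(master$alignment[[1]]),
            sum(vapply(master$insertions, nrow, integer(1)))))
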