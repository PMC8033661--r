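#!/usr/bin/env Rscript
# Ecological tabulations of the species metadata table: overlapping
# habitat categories with percentages, pathogen lifestyles, genomic
# location of the avidin gene (plasmid vs chromosome) with the
# mobile-element fraction, and the gene copy-number histogram.

suppressMessages(library(avidinsurvey))

md <- read_species_metadata("results/inputs/species_metadata.tsv")
s <- survey_summary(md)
jsonlite::write_json(s, "results/ecology.json", auto_unbox = TRUE,
                     digits = NA)

hab <- s$habitats$habitat
cat(sprintf("%d species; habitats:\n", s$habitats$n_species))
for (i in seq_len(nrow(hab)))
  cat(sprintf("  %-18s %3d species (%d%%)\n", hab$category[i],
              hab$count[i], hab$percent[i]))
cat(sprintf("pathogens: %d species (%d%%)\n", s$habitats$pathogen_species,
            s$habitats$pathogen_percent))
cat(sprintf("gene location: plasmid %d, genome %d, NA %d (mobile %.1f%%)\n",
            s$location$plasmid, s$location$genome, s$location$not_available,
            s$location$mobile_percent))
cat(sprintf("multi-copy species: %d\n", s$copies$multi_copy))
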