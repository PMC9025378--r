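#!/usr/bin/env Rscript
# Generate the synthetic phyllosphere study: two sites, five adult trees
# per site (one tree sequenced leaf by leaf), five plantlets, 50,000 reads
# per sample, with planted cores, an antagonist trio, and a plantlet
# dominance shift. Writes the raw tables and the truth record that the
# later steps try to recover.

suppressMessages(library(phyllocore))

seed <- 20240406L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

g <- generate_dataset(synth_config(), seed = seed)

write_abundance_table(g$table, "results/data/otu_table.tsv")
write_metadata(g$metadata, "results/data/metadata.tsv")
write_guild_db(g$guild_db, "results/data/guild_db.tsv")
write_truth_json(g$truth, "results/data/truth.json")

cat(sprintf("simulated %d taxa x %d samples at depth %s (seed %d)\n",
            nrow(g$table$counts), ncol(g$table$counts),
            format(unique(colSums(g$table$counts)), big.mark = ","), seed))
cat(sprintf("planted cores: all=%d adults=%d plantlets=%d\n",
            length(g$truth$planted_core$all),
            length(g$truth$planted_core$adults),
            length(g$truth$planted_core$plantlets)))
cat(sprintf("antagonist pairs: %s-%s (target %.2f), %s-%s (target %.2f)\n",
            g$truth$antagonist_pairs$taxon_a[1],
            g$truth$antagonist_pairs$taxon_b[1],
            g$truth$antagonist_pairs$target_rho[1],
            g$truth$antagonist_pairs$taxon_a[2],
            g$truth$antagonist_pairs$taxon_b[2],
            g$truth$antagonist_pairs$target_rho[2]))
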