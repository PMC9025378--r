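#!/usr/bin/env Rscript
# Trophic modes and set algebra: guild assignment from the local lookup
# table, per-stage trophic-mode profiles, and Venn partitions of the
# group-wise strict cores.

suppressMessages(library(phyllocore))

tab <- read_abundance_table("results/data/otu_table.tsv")
meta <- read_metadata("results/data/metadata.tsv")
db <- read_guild_db("results/data/guild_db.tsv")
dir.create("results/guilds", showWarnings = FALSE, recursive = TRUE)

assignments <- assign_guilds(tab, db)
write.table(assignments, "results/guilds/guild_assignments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

groups <- split(meta$sample_id, meta$stage)
groups$all <- meta$sample_id
prof_taxa <- trophic_mode_profile(assignments, tab, groups, weight = "taxa")
prof_reads <- trophic_mode_profile(assignments, tab, groups,
                                   weight = "reads")
write.table(cbind(weight = "taxa", prof_taxa),
            "results/guilds/trophic_profile_taxa.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(weight = "reads", prof_reads),
            "results/guilds/trophic_profile_reads.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
all_prof <- prof_taxa[prof_taxa$group == "all", ]
for (m in c("saprotroph", "pathotroph", "symbiotroph")) {
  v <- all_prof$proportion[all_prof$trophic_mode == m]
  cat(sprintf("%-12s %5.1f%% of taxa\n", m, 100 * ifelse(length(v), v, 0)))
}

inc <- to_incidence(tab)
hier <- default_hierarchy(meta)
ch <- hierarchical_cores(inc, hier)
venn <- venn_partition(list(adults = ch$cores$adults$members,
                            plantlets = ch$cores$plantlets$members))
write_venn_tsv(venn, "results/guilds/venn_core_adults_plantlets.tsv")
cat(sprintf("core taxa: %d adult-only, %d plantlet-only, %d shared\n",
            venn$regions[["adults"]]$count,
            venn$regions[["plantlets"]]$count,
            venn$regions[["adults&plantlets"]]$count))
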