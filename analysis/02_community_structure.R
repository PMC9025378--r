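#!/usr/bin/env Rscript
# Community structure: composition summaries per rank, Hellinger
# transformation, Jensen-Shannon ordination (PCoA), and the PERMDISP test
# of dispersion between developmental stages and between sites.

suppressMessages(library(phyllocore))

tab <- read_abundance_table("results/data/otu_table.tsv")
meta <- read_metadata("results/data/metadata.tsv")
dir.create("results/community", showWarnings = FALSE, recursive = TRUE)

comp <- do.call(rbind, lapply(c("phylum", "order", "genus"), function(r)
  cbind(rank = r, summarize_composition(tab, meta, r, group_by = "stage"))))
write.table(comp, "results/community/composition_by_stage.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

jsd <- jensen_shannon_matrix(tab)
write_square_tsv(jsd, "results/community/distance_jsd.tsv")
ord <- pcoa(jsd)
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE),
            "results/community/pcoa_coordinates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA axis 1-2 explain %.1f%% + %.1f%% (of positive inertia)\n",
            100 * ord$proportion_explained[1],
            100 * ord$proportion_explained[2]))

groups <- meta$stage[match(colnames(tab$counts), meta$sample_id)]
disp_stage <- permdisp(jsd, groups, n_perm = 999, seed = 101)
sites <- meta$site[match(colnames(tab$counts), meta$sample_id)]
disp_site <- permdisp(jsd, sites, n_perm = 999, seed = 102)
write.table(data.frame(comparison = c("stage", "site"),
                       F = c(disp_stage$F, disp_site$F),
                       p_perm = c(disp_stage$p_perm, disp_site$p_perm),
                       n_perm = 999),
            "results/community/permdisp.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("PERMDISP stage: F = %.3f, p = %.4f | site: F = %.3f, p = %.4f\n",
            disp_stage$F, disp_stage$p_perm, disp_site$F, disp_site$p_perm))
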