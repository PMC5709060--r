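#!/usr/bin/env Rscript
# Mutation -> methylation -> expression integration on the study cohort:
# the drvA vs drvB groups play the role of the two mutually exclusive
# mutation groups. Planted couplings (20 genes, probes hyper in the drvA
# group, expression tied to the probe with sign +/-1) should land in
# up_in_A_only / down_in_A_only; a hypergeometric enrichment against a
# small synthetic gene-set collection closes the loop.

suppressPackageStartupMessages(library(methdriver))

ch_dir <- "results/cohorts/study"
beta <- load_beta_matrix(file.path(ch_dir, "beta.tsv"),
                         file.path(ch_dir, "groups.tsv"))
mut <- load_mutations(file.path(ch_dir, "mutations.tsv"), "binary")
ann <- load_probe_annotation(file.path(ch_dir, "annotation.tsv"))
expr <- load_expression(file.path(ch_dir, "expression.tsv"))
truth <- jsonlite::read_json(file.path(ch_dir, "truth.json"),
                             simplifyVector = TRUE)

st <- mut$status
groups <- list(A = colnames(st)[st["drvA", ] == 1],
               B = colnames(st)[st["drvB", ] == 1])
cat(sprintf("groups: A (drvA-mutated) n=%d, B (drvB-mutated) n=%d\n",
            length(groups$A), length(groups$B)))

links <- map_probes_to_genes(ann, tss_window = 1500)
links <- correlate_methylation_expression(beta, expr, links)
cat(sprintf("links: %d probe-gene pairs, %d significant at q<0.05\n",
            nrow(links), sum(links$significant)))

ab <- call_group_aberrant_probes(beta, groups)
cls <- classify_group_specific_genes(links, ab, expr, beta, groups)
write.table(cls, "results/gene_categories.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(table(cls$category))

want <- with(truth$coupled_pairs,
             setNames(ifelse(sign == -1, "down_in_A_only", "up_in_A_only"),
                      gene))
got <- setNames(cls$category, cls$gene)[names(want)]
cat(sprintf("planted recovery: %d/%d correct, %d misassigned\n",
            sum(got == want, na.rm = TRUE), length(want),
            sum(!is.na(got) & got != want)))

ht <- filter_highly_transcribed(cls, expr, beta, groups)
cat(sprintf("highly transcribed (median > 10 log2, >= doubled vs normals): %d genes\n",
            length(ht)))

# enrichment against a synthetic collection: one set = the planted
# downregulated genes, one = the upregulated, plus background sets
dn <- names(want)[want == "down_in_A_only"]
up <- names(want)[want == "up_in_A_only"]
sets <- gene_set_collection(list(PLANTED_DOWN = dn, PLANTED_UP = up,
                                 BACKGROUND1 = sprintf("bg%03d", 1:10),
                                 BACKGROUND2 = sprintf("bg%03d", 11:20)))
universe <- unique(links$gene)
enr <- enrich_gene_sets(cls$gene[startsWith(cls$category, "down")],
                        sets, universe)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("enrichment of the down_in_A_only list (top rows):\n")
print(head(enr[, c("set", "hits", "set_size", "p", "q")], 3))
cat("-> results/gene_categories.tsv, results/enrichment.tsv\n")
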