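#!/usr/bin/env Rscript
# Stage 05 - ancestral methylation, deamination enrichment, conservation.
#
# Calls methylation on the D-lineage ancestor's cytosine report, stratifies
# D-subgenome positions by ancestral state, and measures how much more
# often accessions carry a divergent homozygous allele at ancestrally
# methylated cytosines (expected: about fourfold, biased to C-to-T/G-to-A),
# then quantifies ancestor-to-descendant methylation conservation.

suppressMessages(library(hexmeth))
sim <- readRDS("scratch/sim/panel.rds")
panel <- sim$panel

anc <- call_sites(panel$ancestor_report)
anc_calls <- anc[anc$status %in% c("methylated", "unmethylated"),
                 c("chrom", "pos", "strand", "status")]
alleles <- lapply(panel$vcf, function(v) v[v$chrom == "chrD", ])
de <- deamination_enrichment(anc_calls, alleles)
write.table(de$per_accession, "results/05_deamination_per_accession.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# descendant = accession 1's D-subgenome calls
desc <- call_sites(panel$reports[[1]])
desc <- desc[desc$chrom == "chrD", ]
cons <- ancestral_conservation(anc_calls,
                               desc[, c("chrom", "pos", "strand", "status")])
cons_df <- data.frame(quantity = c("conserved_methylated", "lost", "gained",
                                   "conserved_unmethylated"),
                      fraction = unlist(cons[1:4]))
write.table(cons_df, "results/05_ancestral_conservation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Divergence at ancestrally methylated vs unmethylated cytosines: fold = %.2f (paired t = %.1f, p = %.3g).\n",
            de$fold, de$t_divergence$statistic, de$t_divergence$p.value))
cat(sprintf("C-to-T/G-to-A fraction among divergent sites: %.0f%% (methylated) vs %.0f%% (unmethylated); paired t p = %.3g.\n",
            100 * mean(de$per_accession$frac_ct_methylated, na.rm = TRUE),
            100 * mean(de$per_accession$frac_ct_unmethylated, na.rm = TRUE),
            de$t_ct$p.value))
cat(sprintf("Ancestor-descendant: %.1f%% methylation conserved, %.1f%% gained.\n",
            100 * cons$conserved_methylated, 100 * cons$gained))
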