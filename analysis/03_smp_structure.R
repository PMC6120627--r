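#!/usr/bin/env Rscript
# Stage 03 - SMP identification and population structure.
#
# Identifies single methylation polymorphisms (full coverage, intact
# sequence context, >= 2 methylated and >= 2 unmethylated accessions),
# profiles their conservation, clusters accessions on SMP epiallele codes
# and on SNP allele indicators, and compares the two layers: Mantel
# correlation of the distance matrices, a runs test on the interleaved
# cluster labels, geographic concordance of the SMP clusters, and AU
# bootstrap support for the SMP tree.

suppressMessages(library(hexmeth))
sim <- readRDS("scratch/sim/panel.rds")
panel <- sim$panel
seed <- sim$cfg$seed

broken <- context_broken_sites(panel$truth$sites,
                               lapply(panel$vcf, function(v)
                                 v[v$homozygous, ]))
smp <- identify_smps(panel$reports,
                     excluded_sites = panel$truth$sites[broken, ])
cons <- conservation_profile(smp)
write.table(cbind(smp$sites, smp$codes), "results/03_smp_matrix.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cons$bins, "results/03_smp_conservation_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# SMP clustering (epiallele codes as numeric features)
d_smp <- distance_matrix(t(smp$codes))
tree_smp <- hcluster(d_smp)
lab_smp <- cut_tree(tree_smp, 2)

# SNP clustering: homozygous-allele indicator per segregating position
snp_keys <- sort(unique(unlist(lapply(panel$vcf, function(v)
  paste(v$chrom, v$pos)))))
geno <- sapply(panel$vcf, function(v)
  as.numeric(snp_keys %in% paste(v$chrom, v$pos)[v$homozygous]))
d_snp <- distance_matrix(t(geno))
lab_snp <- cut_tree(hcluster(d_snp), 2)

mant <- mantel_test(d_smp, d_snp, n_perm = 999, seed = seed + 301L)
# interleave the two cluster label sequences in shared leaf order for the
# randomness (runs) test, as for merged SMP/SNP dendrograms
ord <- tree_smp$order
seq_labels <- as.vector(rbind(paste0("smp", lab_smp[ord]),
                              paste0("snp", lab_snp[ord])))
rt <- runs_test(ifelse(grepl("1$", seq_labels), "c1", "c2"))
conc <- geography_concordance(lab_smp, panel$accessions$region)
perm <- geography_concordance_test(lab_smp, panel$accessions$region,
                                   n_perm = 999, seed = seed + 302L)
au <- au_support(t(smp$codes), n_boot = 2000, seed = seed + 303L)
write.table(au$support, "results/03_smp_tree_support.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

stats <- data.frame(
  statistic = c("n_smps", "mantel_r", "mantel_p", "runs_Z", "runs_p",
                "geography_majority_fraction", "geography_perm_p",
                "ari_smp_vs_population"),
  value = c(nrow(smp$sites), mant$r, mant$p, rt$Z, rt$p,
            conc$majority_fraction, perm$p,
            adjusted_rand_index(lab_smp, panel$truth$population_labels)))
write.table(stats, "results/03_structure_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d SMPs; Mantel r = %.3f (p = %.3g) between SMP and SNP distances.\n",
            nrow(smp$sites), mant$r, mant$p))
cat(sprintf("Runs test on interleaved cluster labels: Z = %.2f, p = %.3g.\n",
            rt$Z, rt$p))
cat(sprintf("%.0f%% of regions have a majority SMP cluster (permutation p = %.3g).\n",
            100 * conc$majority_fraction, perm$p))
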