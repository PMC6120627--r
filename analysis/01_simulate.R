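#!/usr/bin/env Rscript
# Stage 01 - simulate the hexaploid diversity panel.
#
# Builds the synthetic study panel used by every downstream stage: a
# three-subgenome toy genome derived from one ancestor (2% divergence,
# small indels), 20 accessions in two geography-linked populations,
# bisulfite counts at 98.7% conversion and 30x mean coverage, a fourfold
# deamination elevation at ancestrally methylated cytosines, and TE
# profiles with a planted SINE expansion. Raw per-accession files go to
# scratch/sim/ (bulky, regenerable); a compact panel summary goes to
# results/.

suppressMessages(library(hexmeth))

seed <- as.integer(Sys.getenv("HEXMETH_SEED", "1"))
cfg <- sim_config(n_accessions = 20, subgenome_length = 40000, seed = seed)

genome <- simulate_genome(cfg)
panel <- simulate_panel(cfg, genome, epi_block_bp = 200)

out_raw <- "scratch/sim"
dir.create(out_raw, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

write_fasta(genome$sequences, file.path(out_raw, "reference.fa"))
write_homoeolog_map(genome$map, file.path(out_raw, "homoeolog_map.tsv"))
write_bed(genome$annotation, file.path(out_raw, "annotation.bed"))
for (acc in panel$accessions$id) {
  write_cytosine_report(panel$reports[[acc]],
                        file.path(out_raw, paste0(acc, ".cx.txt")))
  write_vcf(panel$vcf[[acc]], file.path(out_raw, paste0(acc, ".vcf")),
            sample = acc)
}
write_cytosine_report(panel$ancestor_report,
                      file.path(out_raw, "ancestor_D.cx.txt"))
saveRDS(list(cfg = cfg, genome = genome, panel = panel),
        file.path(out_raw, "panel.rds"))  # scratch only, never shipped

summary <- data.frame(
  accession = panel$accessions$id,
  population = panel$accessions$population,
  region = panel$accessions$region,
  n_sites = vapply(panel$reports, nrow, 0L),
  n_hom_snps = vapply(panel$vcf, function(v) sum(v$homozygous), 0L))
write.table(summary, "results/01_panel_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d accessions over a 3 x %d bp genome: %d cytosine sites, %d segregating positions.\n",
            cfg$n_accessions, cfg$subgenome_length, nrow(panel$truth$sites),
            nrow(panel$truth$snps)))
cat("Raw panel in scratch/sim/, summary in results/01_panel_summary.tsv\n")
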