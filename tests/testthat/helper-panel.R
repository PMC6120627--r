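# Small simulated panels shared across test files, built once per run.
.panel_cache <- new.env(parent = emptyenv())

# Perfect-conversion panel at depth 30: the SMP/clustering workhorse.
clean_panel <- function() {
  if (is.null(.panel_cache$clean)) {
    cfg <- sim_config(n_accessions = 12, subgenome_length = 6000,
                      conversion_rate = 1, mean_coverage = 30,
                      epiallele_rate = 0.3, seed = 42)
    g <- simulate_genome(cfg)
    .panel_cache$clean <- list(cfg = cfg, genome = g,
                               panel = simulate_panel(cfg, g))
  }
  .panel_cache$clean
}

# Default-parameter panel (conversion 0.987) for conversion/deamination
# checks.
noisy_panel <- function() {
  if (is.null(.panel_cache$noisy)) {
    cfg <- sim_config(n_accessions = 10, subgenome_length = 6000, seed = 99)
    g <- simulate_genome(cfg)
    .panel_cache$noisy <- list(cfg = cfg, genome = g,
                               panel = simulate_panel(cfg, g))
  }
  .panel_cache$noisy
}

# Hand-built cytosine report row.
report_row <- function(chrom, pos, strand, nm, nu, ctx) {
  data.frame(chrom = chrom, pos = pos, strand = strand, n_meth = nm,
             n_unmeth = nu, context = ctx, stringsAsFactors = FALSE)
}

# Zero-row allele table for deamination tests.
empty_vcf_like <- function() {
  data.frame(chrom = character(), pos = integer(), alt = character(),
             homozygous = logical(), stringsAsFactors = FALSE)
}
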