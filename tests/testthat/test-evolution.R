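mk_anc <- function(n_meth, n_unmeth) {
  data.frame(chrom = "chrD", pos = seq_len(n_meth + n_unmeth), strand = "+",
             status = rep(c("methylated", "unmethylated"),
                          c(n_meth, n_unmeth)),
             stringsAsFactors = FALSE)
}

test_that("zero divergence gives zero fractions and an undefined fold", {
  anc <- mk_anc(50, 50)
  alleles <- list(a1 = empty_vcf_like(), a2 = empty_vcf_like())
  out <- deamination_enrichment(anc, alleles)
  expect_true(all(out$per_accession$p_divergent_methylated == 0))
  expect_true(is.na(out$fold))
  expect_true(out$degenerate)
  expect_error(deamination_enrichment(mk_anc(0, 10), alleles),
               "no methylated")
})

test_that("heterozygous calls never count as divergent", {
  anc <- mk_anc(10, 10)
  al <- data.frame(chrom = "chrD", pos = c(1L, 2L), alt = "T",
                   homozygous = c(TRUE, FALSE), stringsAsFactors = FALSE)
  out <- deamination_enrichment(anc, list(a1 = al, a2 = al))
  expect_equal(out$per_accession$p_divergent_methylated, c(0.1, 0.1))
})

test_that("equal mutation rates give fold near 1 and a quiet paired t", {
  set.seed(55)
  n_sites <- 4000; n_acc <- 12
  anc <- mk_anc(n_sites / 2, n_sites / 2)
  rejections <- 0
  for (rep in 1:20) {
    alleles <- lapply(seq_len(n_acc), function(i) {
      hit <- which(runif(n_sites) < 0.01)
      data.frame(chrom = "chrD", pos = hit,
                 alt = sample(c("T", "G", "A"), length(hit), replace = TRUE),
                 homozygous = TRUE, stringsAsFactors = FALSE)
    })
    names(alleles) <- paste0("a", seq_len(n_acc))
    out <- deamination_enrichment(anc, alleles)
    if (!is.na(out$t_divergence$p.value) && out$t_divergence$p.value < 0.01)
      rejections <- rejections + 1
  }
  expect_lte(rejections, 3)  # ~alpha=0.01 over 20 replicates, generous cap
})

test_that("the generator's fourfold elevation is recovered end to end", {
  cfg <- sim_config(n_accessions = 16, subgenome_length = 24000,
                    deamination_fold = 4, mean_coverage = 40, seed = 23)
  g <- simulate_genome(cfg)
  p <- simulate_panel(cfg, g)
  anc <- call_sites(p$ancestor_report)
  anc_calls <- anc[anc$status %in% c("methylated", "unmethylated"),
                   c("chrom", "pos", "strand", "status")]
  alleles <- lapply(p$vcf, function(v) v[v$chrom == "chrD", ])
  out <- deamination_enrichment(anc_calls, alleles)
  # at this genome size the shared segregation draw leaves ~0.85 SE on the
  # fold; 3-SE band around the planted 4 (tight recovery is checked at
  # larger scale in the acceptance suite)
  expect_gt(out$fold, 1.5)
  expect_lt(out$fold, 6.5)
  expect_lt(out$t_divergence$p.value, 0.01)
  # C-to-T/G-to-A predominance in the methylated stratum
  expect_gt(mean(out$per_accession$frac_ct_methylated, na.rm = TRUE),
            mean(out$per_accession$frac_ct_unmethylated, na.rm = TRUE))
  # invariant to accession and site order
  out2 <- deamination_enrichment(anc_calls[sample(nrow(anc_calls)), ],
                                 rev(alleles))
  expect_equal(out2$fold, out$fold)
})

test_that("ancestral conservation fractions behave at the extremes", {
  a <- mk_anc(30, 20)
  expect_equal(ancestral_conservation(a, a)$conserved_methylated, 1)
  expect_equal(ancestral_conservation(a, a)$lost, 0)
  expect_equal(ancestral_conservation(a, a)$gained, 0)
  flipped <- a
  flipped$status <- ifelse(a$status == "methylated", "unmethylated",
                           "methylated")
  out <- ancestral_conservation(a, flipped)
  expect_equal(out$conserved_methylated, 0)
  expect_equal(out$gained, 1)
  b <- a; b$chrom <- "chrX"
  expect_error(ancestral_conservation(a, b), "no shared")
})

test_that("conserved + lost = 1 over ancestor-methylated sites", {
  set.seed(9)
  a <- mk_anc(200, 300)
  d <- a
  flip <- runif(nrow(d)) < 0.2
  d$status[flip] <- ifelse(d$status[flip] == "methylated", "unmethylated",
                           "methylated")
  out <- ancestral_conservation(a, d)
  expect_equal(out$conserved_methylated + out$lost, 1)
  expect_equal(out$gained + out$conserved_unmethylated, 1)
})

test_that("measured ancestral conservation matches the generator's truth", {
  cl <- clean_panel()  # perfect conversion: threshold miscalls are rare
  p <- cl$panel
  anc <- call_sites(p$ancestor_report)
  anc_calls <- anc[anc$status %in% c("methylated", "unmethylated"),
                   c("chrom", "pos", "strand", "status")]
  desc <- call_sites(p$reports[[1]])
  desc <- desc[desc$chrom == "chrD", c("chrom", "pos", "strand", "status")]
  out <- ancestral_conservation(anc_calls, desc)
  sites <- p$truth$sites
  d <- sites$chrom == "chrD"
  am <- p$truth$ancestor_methylation[d] == 1
  dm <- p$truth$meth_state[d, 1] == 1
  truth_cons <- mean(dm[am])
  truth_gain <- mean(dm[!am])
  expect_lt(abs(out$conserved_methylated - truth_cons), 0.03)
  expect_lt(abs(out$gained - truth_gain), 0.03)
})
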