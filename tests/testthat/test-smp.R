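# Hand-built panels: one site per scenario, full coverage.
mk_reports <- function(meth_counts, unmeth_counts, ctx = "CpG") {
  lapply(seq_along(meth_counts), function(i)
    report_row("chr1A", 100L, "+", meth_counts[i], unmeth_counts[i], ctx))
}

test_that("SMP definition needs >= 2 methylated and >= 2 unmethylated", {
  # 1 methylated, 5 unmethylated: not an SMP
  r <- mk_reports(c(19, 0, 0, 0, 0, 0), c(1, 20, 20, 20, 20, 20))
  expect_equal(nrow(identify_smps(r)$sites), 0)
  # 5 methylated / 5 unmethylated: retained with codes 100/0
  r <- mk_reports(c(rep(19, 5), rep(0, 5)), c(rep(1, 5), rep(20, 5)))
  m <- identify_smps(r)
  expect_equal(nrow(m$sites), 1)
  expect_equal(as.vector(m$codes), c(rep(100L, 5), rep(0L, 5)))
  # intermediate accessions are coded 50 and count to neither side
  r <- mk_reports(c(19, 19, 10, 0, 0), c(1, 1, 10, 20, 20))
  m <- identify_smps(r)
  expect_equal(as.vector(m$codes), c(100L, 100L, 50L, 0L, 0L))
})

test_that("uncovered accessions drop the site; <4 accessions error", {
  r <- mk_reports(c(19, 19, 0, 0), c(1, 1, 20, 20))
  r[[2]]$n_meth <- 5L; r[[2]]$n_unmeth <- 4L  # coverage 9 < 10
  expect_equal(nrow(identify_smps(r)$sites), 0)
  expect_error(identify_smps(mk_reports(c(19, 0, 0), c(1, 20, 20))),
               "at least 4")
})

test_that("a context-altering SNP in one accession excludes the site", {
  r <- mk_reports(c(19, 19, 0, 0), c(1, 1, 20, 20))
  excl <- data.frame(chrom = "chr1A", pos = 100L, strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(identify_smps(r)$sites), 1)
  expect_equal(nrow(identify_smps(r, excluded_sites = excl)$sites), 0)
})

test_that("identify_smps is invariant to accession order", {
  cl <- clean_panel()
  reports <- cl$panel$reports
  m1 <- identify_smps(reports)
  perm <- rev(seq_along(reports))
  m2 <- identify_smps(reports[perm])
  expect_equal(m1$sites, m2$sites)
  expect_equal(m1$codes, m2$codes[, colnames(m1$codes)])
})

test_that("accession SMPs are exactly the 100-coded sites", {
  r <- mk_reports(c(19, 19, 0, 0, 10), c(1, 1, 20, 20, 10))
  m <- identify_smps(r)
  expect_equal(nrow(accession_smps(m, "acc1")), 1)
  expect_equal(nrow(accession_smps(m, "acc3")), 0)
  expect_error(accession_smps(m, "nope"), "unknown accession")
  # conservation identity: total 100 codes = sum over accessions
  total <- sum(vapply(colnames(m$codes), function(a)
    nrow(accession_smps(m, a)), 0L))
  expect_equal(total, sum(m$codes == 100L))
})

test_that("monomorphic sites are never SMPs; planted epialleles are recovered", {
  cl <- clean_panel()
  p <- cl$panel
  excl_keys <- context_broken_sites(
    p$truth$sites, lapply(p$vcf, function(v) v[v$homozygous, ]))
  m <- identify_smps(p$reports,
                     excluded_sites = p$truth$sites[excl_keys, ])
  truth <- p$truth
  key_m <- paste(m$sites$chrom, m$sites$pos, m$sites$strand)
  key_t <- paste(truth$sites$chrom, truth$sites$pos, truth$sites$strand)
  n_meth_true <- rowSums(truth$meth_state)
  n <- ncol(truth$meth_state)
  poly <- n_meth_true >= 2 & n_meth_true <= n - 2 & !excl_keys
  mono <- n_meth_true %in% c(0L, n)
  # no monomorphic site reported
  expect_equal(sum(key_m %in% key_t[mono]), 0)
  # planted polymorphic sites recovered at >= 95%
  recovered <- mean(key_t[poly] %in% key_m)
  expect_gte(recovered, 0.95)
})

test_that("conservation profile fractions and bins are consistent", {
  codes <- matrix(0L, 3, 105)
  codes[1, 1:21] <- 100L    # 20%
  codes[2, 1:100] <- 100L   # >= 90% bin
  codes[3, 1:5] <- 100L     # < 10% bin
  m <- structure(list(
    sites = data.frame(chrom = "chr1A", pos = 1:3, strand = "+",
                       context = "CpG", stringsAsFactors = FALSE),
    codes = codes), class = "smp_matrix")
  pr <- conservation_profile(m)
  expect_equal(pr$profile$frac_methylated, c(20, 100 * 100 / 105, 100 / 21))
  expect_equal(pr$bins$n_high, 1)
  expect_equal(pr$bins$n_low, 1)
})

test_that("planted high-frequency epialleles land in the >= 90% bin", {
  cl <- clean_panel()
  m <- identify_smps(cl$panel$reports)
  truth <- cl$panel$truth
  key_m <- paste(m$sites$chrom, m$sites$pos, m$sites$strand)
  key_t <- paste(truth$sites$chrom, truth$sites$pos, truth$sites$strand)
  frac_true <- rowMeans(truth$meth_state)[match(key_m, key_t)]
  pr <- conservation_profile(m)
  # highest-frequency epialleles an SMP can carry in a 12-accession panel:
  # 10/12 methylated; observed conservation must be within one accession
  high_true <- frac_true >= 10 / 12
  expect_gt(sum(high_true), 0)
  n_acc <- ncol(m$codes)
  expect_true(all(pr$profile$frac_methylated[high_true] >=
                    100 * (frac_true[high_true] * n_acc - 1) / n_acc))
})

test_that("gene groups partition by scaled accession-count thresholds", {
  presence <- matrix(0, 4, 105,
                     dimnames = list(paste0("g", 1:4), NULL))
  presence[1, 1:95] <- 1   # high
  presence[2, 1:60] <- 1   # medium
  presence[3, 1:39] <- 1   # low
  gr <- gene_methylation_groups(presence)
  expect_equal(gr$high, "g1")
  expect_equal(gr$medium, "g2")
  expect_equal(gr$low, "g3")   # g4 absent everywhere: in no group
  expect_setequal(unlist(gr), c("g1", "g2", "g3"))
})

test_that("family profile flags >= 25% mean representation", {
  presence <- matrix(0, 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  presence[1, ] <- 1                      # methylated in all accessions
  fams <- list(f1 = c("g1", "g2", "g3", "g4"), f2 = "g5")
  pr <- family_methylation_profile(fams, presence)
  expect_equal(unname(pr$mean_fraction), c(0.25, 0))
  expect_equal(unname(pr$flagged), c(TRUE, FALSE))
  expect_true(all(pr$fractions %in% c(0, 0.25, 1)))
  expect_error(family_methylation_profile(list(f0 = character()), presence),
               "zero member")
})

test_that("gene-level conservation exceeds site-level conservation", {
  cl <- clean_panel()
  p <- cl$panel
  ann <- p$truth$annotation
  genes <- ann[ann$type == "gene", ]
  calls <- lapply(p$reports, call_sites)
  presence <- matrix(FALSE, nrow(genes), length(calls),
                     dimnames = list(genes$name, names(calls)))
  site_fracs <- c()
  for (j in seq_along(calls)) {
    r <- calls[[j]]
    meth_cpg <- r[r$context == "CpG" & r$status == "methylated", ]
    for (i in seq_len(nrow(genes))) {
      presence[i, j] <- any(meth_cpg$chrom == genes$chrom[i] &
                              meth_cpg$pos > genes$start[i] &
                              meth_cpg$pos <= genes$end[i])
    }
  }
  gene_cons <- rowMeans(presence)
  # site-level conservation over CpG sites inside gene bodies
  r1 <- calls[[1]]
  in_gene <- rep(FALSE, nrow(r1))
  for (i in seq_len(nrow(genes)))
    in_gene <- in_gene | (r1$chrom == genes$chrom[i] &
                            r1$pos > genes$start[i] & r1$pos <= genes$end[i])
  key_sets <- lapply(calls, function(r)
    paste(r$chrom, r$pos, r$strand)[r$context == "CpG" &
                                      r$status == "methylated"])
  site_keys <- paste(r1$chrom, r1$pos, r1$strand)[in_gene &
                                                    r1$context == "CpG"]
  site_cons <- rowMeans(sapply(key_sets, function(ks) site_keys %in% ks))
  expect_gt(mean(gene_cons[gene_cons > 0]), mean(site_cons[site_cons > 0]))
})
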