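test_that("translation applies indel offsets exactly", {
  # block with a 2-base insertion in the target after source offset 5:
  # source positions 1..5 map to 1..5, position 6 maps to 8
  anc2sub <- list(A = 1:10, B = c(1:5, 8:12), D = 1:10)
  map <- homoeolog_map_from_ancestor(anc2sub, c(A = 10L, B = 12L, D = 10L))
  expect_equal(translate(map, "A", "B", 5), 5)
  expect_equal(translate(map, "A", "B", 6), 8)
  expect_equal(translate(map, "B", "A", 8), 6)
  expect_true(all(is.na(translate(map, "B", "A", 6:7))))  # inserted bases
  expect_equal(translate(map, "B", "D", 10), 8)           # composes via ancestor
  expect_error(translate(map, "A", "Z", 1), "unknown subgenome")
  expect_error(translate(map, "A", "B", 11), "outside reference")
})

test_that("duplicate targets are rejected at construction", {
  expect_error(homoeolog_map(list(AB = c(1L, 1L)), c(A = 2L, B = 2L)),
               "one-to-one")
})

mk_triple <- function(am, au, bm, bu, dm, du, ctx = "CpG") {
  data.frame(a_meth = am, a_unmeth = au, b_meth = bm, b_unmeth = bu,
             d_meth = dm, d_unmeth = du, context = ctx,
             stringsAsFactors = FALSE)
}

test_that("clean contrasts classify as uni, bi and tri", {
  sites <- rbind(mk_triple(100, 0, 0, 100, 0, 100),   # uni on A
                 mk_triple(10, 0, 10, 0, 10, 0),      # tri
                 mk_triple(100, 0, 100, 0, 0, 100),   # bi on A+B
                 mk_triple(6, 4, 5, 5, 0, 10))        # 60 vs 50: diff < 50
  out <- classify_sites(sites)
  expect_equal(out$class, c("uni", "tri", "bi", "unclassified"))
  expect_equal(out$meth_genomes[1], "A")
  expect_equal(out$meth_genomes[3], "A,B")
  # the uni contrast at full scale is overwhelmingly significant
  expect_lt(out$q_ab[1], 1e-10)
})

test_that("insufficient coverage skips the site with a reason", {
  out <- classify_sites(mk_triple(5, 0, 0, 5, 0, 5))
  expect_true(is.na(out$class))
  expect_equal(out$skip_reason, "coverage")
})

test_that("classification is symmetric under subgenome relabeling", {
  sites <- rbind(mk_triple(100, 0, 0, 100, 0, 100),
                 mk_triple(0, 100, 100, 0, 0, 100),
                 mk_triple(10, 0, 10, 0, 10, 0))
  out1 <- classify_sites(sites)$class
  # swap A and D columns
  swapped <- sites[, c(5, 6, 3, 4, 1, 2, 7)]
  names(swapped) <- names(sites)
  out2 <- classify_sites(swapped)$class
  expect_equal(sort(out1), sort(out2))
})

test_that("under the null few sites are called uni or bi", {
  set.seed(21)
  n <- 400
  cov <- 30
  m_a <- rbinom(n, cov, 0.5); m_b <- rbinom(n, cov, 0.5)
  m_d <- rbinom(n, cov, 0.5)
  sites <- mk_triple(m_a, cov - m_a, m_b, cov - m_b, m_d, cov - m_d)
  out <- classify_sites(sites)
  frac <- mean(out$class %in% c("uni", "bi"), na.rm = TRUE)
  expect_lte(frac, 0.01 + 3 * sqrt(0.01 * 0.99 / n))
})

test_that("homoeologous SNP context flags the differentiating genome", {
  # A has CpG at pos 2 (+), B and D have CHH at the homoeologous position
  seqs <- Biostrings::DNAStringSet(c(chrA = "ACGAA", chrB = "ACAAA",
                                     chrD = "ACAAA"))
  anc2sub <- list(A = 1:5, B = 1:5, D = 1:5)
  map <- homoeolog_map_from_ancestor(anc2sub, c(A = 5L, B = 5L, D = 5L))
  sites <- data.frame(genome = "A", pos = 2L, strand = "+", meth_genome = "A",
                      stringsAsFactors = FALSE)
  out <- homoeolog_snp_context(sites, seqs, map)
  expect_true(out$snp_differentiates)
  expect_true(out$cpg_from_non_cpg)
  # identical trinucleotides: not flagged
  seqs2 <- Biostrings::DNAStringSet(c(chrA = "ACGAA", chrB = "ACGAA",
                                      chrD = "ACGAA"))
  out2 <- homoeolog_snp_context(sites, seqs2, map)
  expect_false(out2$snp_differentiates)
})

test_that("class conservation separates stable tri from unstable uni", {
  set.seed(4)
  n_sites <- 120; n_acc <- 15
  cm <- matrix("unclassified", n_sites, n_acc)
  # tri sites methylated in most accessions; uni sites in few
  for (i in 1:60) cm[i, sample(n_acc, sample(10:14, 1))] <- "tri"
  for (i in 61:120) cm[i, sample(n_acc, sample(1:3, 1))] <- "uni"
  cm[1, 1] <- "bi"  # keep the bi stratum non-empty
  cons <- class_conservation(cm)
  expect_gt(cons$medians["tri"], cons$medians["uni"])
  expect_gt(cons$t_tri_vs_uni$statistic, 0)
  expect_lt(cons$t_tri_vs_uni$p.value, 0.01)
  # all-accession tri site scores 100%
  cm2 <- matrix("tri", 2, 4); cm2[2, ] <- c("uni", "bi", "tri", "tri")
  cons2 <- class_conservation(cm2)
  expect_equal(max(cons2$values$tri), 100)
  expect_error(class_conservation(matrix("unclassified", 3, 3)),
               "empty stratum")
})

test_that("identical strata give t = 0", {
  cm <- matrix("unclassified", 4, 10)
  cm[1, 1:5] <- "tri"; cm[2, 1:5] <- "uni"; cm[3, 1:5] <- "bi"
  cons <- class_conservation(cm)
  expect_equal(cons$t_tri_vs_uni$statistic, 0)
})

test_that("planted CpG-creating homoeologous SNPs are recovered at their rate", {
  set.seed(71)
  n_sites <- 200
  gap <- 10L
  pos <- seq(5L, by = gap, length.out = n_sites)
  L <- max(pos) + 5L
  base <- rep("A", L)
  planted <- runif(n_sites) < 0.65
  mk_seq <- function(trinucs) {
    b <- base
    for (i in seq_len(n_sites)) {
      b[pos[i]:(pos[i] + 2)] <- strsplit(trinucs[i], "")[[1]]
    }
    paste(b, collapse = "")
  }
  # methylated genome (A) always CpG; B/D carry CHH at planted sites
  tri_a <- rep("CGA", n_sites)
  tri_other <- ifelse(planted, "CAA", "CGA")
  seqs <- Biostrings::DNAStringSet(c(chrA = mk_seq(tri_a),
                                     chrB = mk_seq(tri_other),
                                     chrD = mk_seq(tri_other)))
  map <- homoeolog_map_from_ancestor(
    list(A = seq_len(L), B = seq_len(L), D = seq_len(L)),
    c(A = L, B = L, D = L))
  sites <- data.frame(genome = "A", pos = pos, strand = "+",
                      meth_genome = "A", stringsAsFactors = FALSE)
  out <- homoeolog_snp_context(sites, seqs, map)
  recovered <- mean(out$snp_differentiates)
  expect_lt(abs(recovered - mean(planted)),
            3 * sqrt(0.65 * 0.35 / n_sites) + 1e-9)
  expect_true(all(out$cpg_from_non_cpg[planted]))
  expect_false(any(out$snp_differentiates[!planted]))
})
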