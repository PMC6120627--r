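test_that("configuration invariants are enforced", {
  expect_error(sim_config(conversion_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(deamination_fold = 0.5), ">= 1")
  expect_error(sim_config(subgenome_length = 500), ">= 1000")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("zero divergence yields identical subgenomes and an identity map", {
  cfg <- sim_config(ancestor_divergence = 0, indel_rate = 0,
                    subgenome_length = 2000, seed = 5)
  g <- simulate_genome(cfg)
  s <- as.character(g$sequences)
  expect_equal(s[["chrA"]], s[["chrB"]])
  expect_equal(s[["chrA"]], s[["chrD"]])
  pos <- seq_len(2000)
  expect_equal(translate(g$map, "A", "B", pos), pos)
  expect_equal(translate(g$map, "B", "D", pos), pos)
})

test_that("substitution count is within 3 binomial SDs of expectation", {
  cfg <- sim_config(ancestor_divergence = 0.02, indel_rate = 0,
                    subgenome_length = 10000, seed = 8)
  g <- simulate_genome(cfg)
  anc <- paste(g$ancestor, collapse = "")
  for (chr in c("chrA", "chrB", "chrD")) {
    diffs <- sum(strsplit(as.character(g$sequences[[chr]]), "")[[1]] !=
                   g$ancestor)
    expect_lt(abs(diffs - 200), 3 * sqrt(10000 * 0.02 * 0.98))
  }
})

test_that("translation round-trips are identity inside aligned blocks", {
  g <- noisy_panel()$genome  # indel_rate > 0
  for (pair in list(c("A", "B"), c("A", "D"), c("B", "D"))) {
    from <- pair[1]; to <- pair[2]
    fwd <- g$map$pairs[[paste0(from, to)]]
    pos <- which(!is.na(fwd))
    back <- translate(g$map, to, from, translate(g$map, from, to, pos))
    expect_equal(back, pos)
  }
  # indels present: at least one block boundary, map not globally identity
  expect_true(any(is.na(g$map$pairs$AB)))
})

test_that("fixing the seed fixes every emitted file byte-for-byte", {
  cfg <- sim_config(n_accessions = 4, subgenome_length = 2000, seed = 13)
  run <- function() {
    g <- simulate_genome(cfg)
    p <- simulate_panel(cfg, g)
    d <- withr::local_tempdir()
    write_fasta(g$sequences, file.path(d, "ref.fa"))
    write_homoeolog_map(g$map, file.path(d, "map.tsv"))
    write_cytosine_report(p$reports[[1]], file.path(d, "r1.txt"))
    write_vcf(p$vcf[[2]], file.path(d, "a2.vcf"))
    lapply(list.files(d, full.names = TRUE), readLines)
  }
  expect_identical(run(), run())
})

test_that("chloroplast reads are pure conversion failures", {
  p <- noisy_panel()$panel
  cfg <- noisy_panel()$cfg
  cp <- do.call(rbind, lapply(p$reports, function(r)
    r[r$chrom == "chloroplast", ]))
  rate <- sum(cp$n_meth) / sum(cp$n_meth + cp$n_unmeth)
  se <- sqrt(0.013 * 0.987 / sum(cp$n_meth + cp$n_unmeth))
  expect_lt(abs(rate - (1 - cfg$conversion_rate)), 3 * se)
})

test_that("marginal levels at truly methylated sites match configured rates", {
  cl <- clean_panel()
  p <- cl$panel; cfg <- cl$cfg
  r <- p$reports[[1]]
  r <- r[r$chrom != "chloroplast", ]
  ix <- match(paste(r$chrom, r$pos, r$strand),
              paste(p$truth$sites$chrom, p$truth$sites$pos,
                    p$truth$sites$strand))
  truth_state <- p$truth$meth_state[ix, 1]
  for (ctx in c("CpG", "CHH")) {
    sel <- r$context == ctx & truth_state == 1
    lev <- sum(r$n_meth[sel]) / sum(r$n_meth[sel] + r$n_unmeth[sel])
    target <- if (ctx == "CpG") cfg$cpg_meth_high else cfg$chh_meth_mean
    n <- sum(r$n_meth[sel] + r$n_unmeth[sel])
    expect_lt(abs(lev - target), 3 * sqrt(target * (1 - target) / n))
  }
})

test_that("deamination carriers lose the mutated cytosine from their report", {
  cl <- clean_panel()
  p <- cl$panel
  snps <- p$truth$snps
  geno <- p$truth$genotypes
  c_sites <- paste(p$truth$sites$chrom, p$truth$sites$pos)
  at_c <- which(paste(snps$chrom, snps$pos) %in% c_sites)
  skip_if(length(at_c) == 0, "no SNP landed on a cytosine in this draw")
  i <- at_c[1]
  carrier <- which(geno[i, ] == 2)[1]
  skip_if(is.na(carrier), "no homozygous carrier in this draw")
  rep_c <- p$reports[[carrier]]
  expect_false(any(rep_c$chrom == snps$chrom[i] & rep_c$pos == snps$pos[i]))
})

test_that("noise-free expression reproduces the planted shares exactly", {
  cl <- clean_panel()
  e <- simulate_expression(cl$cfg, cl$panel$truth, noise_sd = 0,
                           de_fraction = 0)
  tr <- e$triads
  shares <- sapply(c("A", "B", "D"), function(s)
    e$expr[sprintf("g%d_%s", tr$triad, s), 1])
  shares <- 100 * shares / rowSums(shares)
  bal <- tr$class == "balanced"
  expect_equal(unname(shares[bal, ]),
               matrix(100 / 3, sum(bal), 3), tolerance = 1e-9)
  uni <- which(tr$class == "uni")
  skip_if(length(uni) == 0, "no uni triad in this draw")
  i <- uni[1]
  mg <- tr$meth_genome[i]
  expect_equal(unname(shares[i, mg]), 28.82, tolerance = 1e-6)
  expect_equal(unname(shares[i, setdiff(c("A", "B", "D"), mg)]),
               c(35.59, 35.59), tolerance = 1e-6)
})

test_that("planted fourfold deamination elevation is recovered", {
  cfg <- sim_config(n_accessions = 20, subgenome_length = 30000,
                    deamination_fold = 4, seed = 17)
  g <- simulate_genome(cfg)
  p <- simulate_panel(cfg, g)
  snps <- p$truth$snps
  # divergence frequency ratio at ancestrally methylated vs unmethylated
  # cytosine positions, from the generator's own SNP table
  sites <- p$truth$sites
  is_c <- !duplicated(paste(sites$chrom, sites$pos))
  cpos <- paste(sites$chrom, sites$pos)[is_c]
  meth <- p$truth$ancestor_methylation[is_c] == 1
  seg <- cpos %in% paste(snps$chrom, snps$pos)
  ratio <- mean(seg[meth]) / mean(seg[!meth])
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
})
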