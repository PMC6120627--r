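#' Configuration for the synthetic hexaploid panel generator
#'
#' Collects every knob of the generative model. The defaults describe the
#' study conditions emulated throughout the package: a panel of landrace
#' accessions from two ancestral population groups, bimodal CpG methylation
#' with low non-CpG methylation, incomplete bisulfite conversion at 98.7%,
#' and a fourfold elevation of the mutation rate at ancestrally methylated
#' cytosines biased towards C-to-T transitions.
#'
#' @param n_accessions Number of accessions in the panel.
#' @param n_populations Number of ancestral populations (>= 2).
#' @param subgenome_length Length of each subgenome in bases (>= 1000).
#' @param ancestor_divergence Substitutions per base separating each
#'   subgenome from the common ancestor.
#' @param indel_rate Indel events per base per subgenome (sizes 1-3 bp).
#' @param panel_snp_rate Per-base probability that a position segregates in
#'   the panel (baseline, before deamination elevation). The default 0.02
#'   matches the density implied by ~89% of well-covered cytosines sharing
#'   their 3-bp sequence context across a ~105-accession panel.
#' @param epiallele_rate Per-cytosine probability that the site is an
#'   epiallele (methylation state polymorphic across the panel).
#' @param conversion_rate Bisulfite conversion success fraction; an
#'   unmethylated cytosine is read as methylated with probability
#'   `1 - conversion_rate`.
#' @param mean_coverage Mean of the per-site Poisson read coverage.
#' @param deamination_fold Mutation-rate elevation (>= 1) at ancestrally
#'   methylated cytosines.
#' @param cpg_meth_high Read-level methylation probability at a truly
#'   methylated CpG site (the upper mode of the bimodal CpG distribution).
#' @param chh_meth_mean Read-level methylation probability at a truly
#'   methylated CHH site.
#' @param te_families Number of transposable-element families.
#' @param seed Integer seed; fixes every generator output bit-for-bit.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accessions = 20,
                       n_populations = 2,
                       subgenome_length = 20000,
                       ancestor_divergence = 0.02,
                       indel_rate = 0.001,
                       panel_snp_rate = 0.02,
                       epiallele_rate = 0.3,
                       conversion_rate = 0.987,
                       mean_coverage = 30,
                       deamination_fold = 4,
                       cpg_meth_high = 0.9,
                       chh_meth_mean = 0.25,
                       te_families = 20,
                       seed = 1) {
  cfg <- list(n_accessions = n_accessions, n_populations = n_populations,
              subgenome_length = subgenome_length,
              ancestor_divergence = ancestor_divergence,
              indel_rate = indel_rate, panel_snp_rate = panel_snp_rate,
              epiallele_rate = epiallele_rate,
              conversion_rate = conversion_rate,
              mean_coverage = mean_coverage,
              deamination_fold = deamination_fold,
              cpg_meth_high = cpg_meth_high, chh_meth_mean = chh_meth_mean,
              te_families = te_families, seed = as.integer(seed))
  rates <- c("ancestor_divergence", "indel_rate", "panel_snp_rate",
             "epiallele_rate", "conversion_rate", "cpg_meth_high",
             "chh_meth_mean")
  for (r in rates)
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]")
  if (cfg$deamination_fold < 1) stop("deamination_fold must be >= 1")
  if (cfg$subgenome_length < 1000) stop("subgenome_length must be >= 1000")
  if (cfg$n_accessions < 1 || cfg$n_populations < 1)
    stop("counts must be positive")
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be positive")
  structure(cfg, class = "sim_config")
}

# Internal generative constants (documented in the methods vignette):
# per-context probability that a cytosine is ancestrally methylated, the
# read-level methylation probability of a methylated CHG site, the C-to-T
# bias of deamination mutations, the population-differentiation Fst of
# panel SNPs, the geography kernel range of epialleles, and the scatter of
# accessions around their population centre.
sim_const <- list(p_meth = c(CpG = 0.5, CHG = 0.2, CHH = 0.08),
                  chg_level = 0.6, ct_bias = 0.9, fst = 0.2,
                  epi_range = 0.2, pop_scatter = 0.04, het_rate = 0.02)

#' Simulate the three-subgenome toy genome
#'
#' Derives subgenomes A, B and D from a single common-ancestor sequence by
#' binomially sampled substitutions and Poisson-sampled indels (1-3 bp),
#' recording the full ancestor alignment so the homoeolog map is known by
#' construction. A separate, unmethylated chloroplast sequence is emitted
#' for conversion-rate estimation, and a gene/promoter annotation is tiled
#' along each subgenome so that gene i on A, B and D forms a homoeolog
#' triad.
#'
#' @param cfg A [sim_config()].
#' @return A `hexmeth_genome`: list with `sequences` (DNAStringSet `chrA`,
#'   `chrB`, `chrD`, `chloroplast`), `map` (a `homoeolog_map`), `ancestor`
#'   (character), `annotation` (BED-style data.frame with `type`),
#'   `n_triads`, `cfg`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$subgenome_length
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, L, replace = TRUE, prob = c(.27, .23, .23, .27))
  subs <- c("A", "B", "D")
  edited <- lapply(subs, function(s)
    mutate_sequence(ancestor, cfg$ancestor_divergence, cfg$indel_rate))
  names(edited) <- subs
  lengths <- vapply(edited, function(e) length(e$sub2anc), 0L)
  map <- homoeolog_map_from_ancestor(lapply(edited, `[[`, "anc2sub"), lengths)
  cp_len <- max(1000L, L %/% 5L)
  chloroplast <- paste(sample(bases, cp_len, replace = TRUE,
                              prob = c(.28, .22, .22, .28)), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(
    chrA = paste(edited$A$seq, collapse = ""),
    chrB = paste(edited$B$seq, collapse = ""),
    chrD = paste(edited$D$seq, collapse = ""),
    chloroplast = chloroplast))
  annotation <- tile_annotation(lengths)
  structure(list(sequences = seqs, map = map, ancestor = ancestor,
                 annotation = annotation,
                 n_triads = max(annotation$triad),
                 cfg = cfg),
            class = "hexmeth_genome")
}

# Apply substitutions and small indels to a character vector of bases,
# returning the edited sequence plus both alignment vectors.
mutate_sequence <- function(anc, divergence, indel_rate) {
  L <- length(anc)
  bases <- c("A", "C", "G", "T")
  sub_pos <- which(stats::runif(L) < divergence)
  seq_chars <- anc
  if (length(sub_pos)) {
    shift <- sample(1:3, length(sub_pos), replace = TRUE)
    seq_chars[sub_pos] <- bases[(match(anc[sub_pos], bases) - 1 + shift) %% 4 + 1]
  }
  n_ind <- stats::rpois(1, L * indel_rate)
  keep <- rep(TRUE, L)
  ins_len <- rep(0L, L)
  if (n_ind > 0) {
    ev_pos <- sort(sample(3:(L - 3), n_ind))
    ev_del <- stats::runif(n_ind) < 0.5
    ev_size <- sample(1:3, n_ind, replace = TRUE)
    for (i in seq_len(n_ind)) {
      if (ev_del[i]) keep[ev_pos[i]:min(L, ev_pos[i] + ev_size[i] - 1)] <- FALSE
      else ins_len[ev_pos[i]] <- ins_len[ev_pos[i]] + ev_size[i]
    }
  }
  contrib <- as.integer(keep) + ins_len
  csum <- cumsum(contrib)
  anc2sub <- ifelse(keep, csum - ins_len, NA_integer_)
  sub_len <- csum[L]
  out <- character(sub_len)
  out[anc2sub[keep]] <- seq_chars[keep]
  gaps <- which(out == "")
  if (length(gaps)) out[gaps] <- sample(bases, length(gaps), replace = TRUE)
  sub2anc <- rep(NA_integer_, sub_len)
  sub2anc[anc2sub[keep]] <- which(keep)
  list(seq = out, anc2sub = anc2sub, sub2anc = sub2anc)
}

# Genes of 400 bp every 1000 bp on each subgenome, with a 200-bp promoter
# immediately upstream; BED 0-based half-open coordinates. Gene i across
# the three subgenomes forms triad i.
tile_annotation <- function(lengths) {
  out <- lapply(names(lengths), function(s) {
    starts <- seq(300L, lengths[[s]] - 700L, by = 1000L)
    idx <- seq_along(starts)
    rbind(
      data.frame(chrom = paste0("chr", s), start = starts,
                 end = starts + 400L,
                 name = sprintf("gene|g%d_%s", idx, s), score = 0L,
                 strand = "+", type = "gene", triad = idx,
                 subgenome = s, stringsAsFactors = FALSE),
      data.frame(chrom = paste0("chr", s), start = starts - 200L,
                 end = starts,
                 name = sprintf("promoter|g%d_%s", idx, s), score = 0L,
                 strand = "+", type = "promoter", triad = idx,
                 subgenome = s, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  n_triads <- min(tapply(out$triad[out$type == "gene"],
                         out$subgenome[out$type == "gene"], max))
  out <- out[out$triad <= n_triads, ]
  rownames(out) <- NULL
  out
}

#' Simulate the diversity panel
#'
#' Generates, for every accession: population-structured homozygous SNPs
#' (Balding-Nichols allele frequencies around geography-linked
#' populations), per-cytosine methylation states with geography-linked
#' epialleles, and read counts drawn binomially at Poisson coverage with
#' incomplete bisulfite conversion. Ancestrally methylated cytosines
#' mutate at `deamination_fold` times the baseline rate, with the mutant
#' allele being T (A for minus-strand cytosines) with high probability;
#' carriers of such a mutation lose the site from their methylation-callable
#' set. The chloroplast is fully unmethylated. Promoter CpG sites are
#' overridden panel-wide to match each triad's planted promoter methylation
#' class (balanced / uni / tri), and per-accession TE-family base counts
#' are drawn with known copy-number multipliers and sequencing-depth
#' factors.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param pop_scatter Geographic scatter (SD) of accessions around their
#'   population centre on the unit square. At 0 every accession in a
#'   population shares coordinates, so epiallele states have zero
#'   within-population variance (the fully separable limit).
#' @param epi_range Decay range of the exponential geography kernel that
#'   links epiallele state to distance from each epiallele's focal point.
#' @param epi_block_bp Length in bp of regional epiallele blocks. At the
#'   default 1 every epiallele cytosine switches independently; larger
#'   values flip all cytosines within a block coherently (per accession),
#'   emulating the regional methylation variation that windowed DMR
#'   calling targets. The expected fraction of cytosines inside epiallele
#'   blocks stays at `epiallele_rate` either way.
#' @return A `hexmeth_panel`: list with `accessions` (id, population, x, y,
#'   region), `reports` (per-accession cytosine report data.frames,
#'   chloroplast included), `vcf` (per-accession homozygous+het SNP
#'   data.frames), `te` (per-accession TE count data.frames),
#'   `ancestor_report` (cytosine report of the D-subgenome ancestor),
#'   `truth` (ground-truth list), `cfg`.
#' @export
simulate_panel <- function(cfg, genome, pop_scatter = 0.04, epi_range = 0.2,
                           epi_block_bp = 1) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genome, "hexmeth_genome"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_accessions
  K <- sim_const
  K$pop_scatter <- pop_scatter
  K$epi_range <- epi_range

  ## accessions, populations, geography -----------------------------------
  pop <- sort(rep_len(seq_len(cfg$n_populations), n))
  theta <- 2 * pi * (seq_len(cfg$n_populations) - 1) / cfg$n_populations
  centers <- cbind(0.5 + 0.35 * cos(theta), 0.5 + 0.35 * sin(theta))
  coords <- centers[pop, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, 0, K$pop_scatter), n, 2)
  region <- paste0("r", pmin(pmax(floor(coords[, 1] * 4), 0), 3),
                   pmin(pmax(floor(coords[, 2] * 4), 0), 3))
  accessions <- data.frame(id = sprintf("acc%03d", seq_len(n)),
                           population = pop, x = coords[, 1], y = coords[, 2],
                           region = region, stringsAsFactors = FALSE)
  D <- as.matrix(stats::dist(coords))

  ## cytosine sites and ancestral methylation -----------------------------
  subs <- c("A", "B", "D")
  seqs <- as.character(genome$sequences)
  sites <- do.call(rbind, lapply(subs, function(s)
    derive_contexts(stats::setNames(seqs[paste0("chr", s)], paste0("chr", s)))))
  rownames(sites) <- NULL
  ns <- nrow(sites)
  anc_meth <- stats::rbinom(ns, 1, K$p_meth[sites$context])

  ## promoter class planting ----------------------------------------------
  ann <- genome$annotation
  n_triads <- max(ann$triad)
  triad_class <- sample(c("balanced", "uni", "tri"), n_triads, replace = TRUE,
                        prob = c(0.6, 0.25, 0.15))
  triad_meth_genome <- ifelse(triad_class == "uni",
                              sample(subs, n_triads, replace = TRUE),
                              NA_character_)
  prom <- ann[ann$type == "promoter", ]
  site_override <- rep(NA_integer_, ns)   # panel-wide promoter CpG states
  for (i in seq_len(nrow(prom))) {
    in_prom <- sites$chrom == prom$chrom[i] &
      sites$pos > prom$start[i] & sites$pos <= prom$end[i] &
      sites$context == "CpG"
    cl <- triad_class[prom$triad[i]]
    mg <- triad_meth_genome[prom$triad[i]]
    state <- if (cl == "tri") 1L
             else if (cl == "uni" && prom$subgenome[i] == mg) 1L
             else 0L
    site_override[in_prom] <- state
  }
  anc_meth[!is.na(site_override)] <- site_override[!is.na(site_override)]

  ## epialleles: geography-linked state flips ------------------------------
  meth <- matrix(anc_meth, ns, n)
  if (epi_block_bp <= 1) {
    epi <- stats::runif(ns) < cfg$epiallele_rate & is.na(site_override)
    n_epi <- sum(epi)
    if (n_epi > 0) {
      epicenter <- sample.int(n, n_epi, replace = TRUE)
      u <- stats::runif(n_epi)
      kern <- exp(-D[epicenter, , drop = FALSE] / K$epi_range)  # n_epi x n
      flip <- kern > u
      meth[epi, ] <- (anc_meth[epi] + flip) %% 2
    }
  } else {
    # regional blocks: whole stretches of cytosines switch coherently
    total_len <- sum(vapply(subs, function(s)
      nchar(seqs[paste0("chr", s)]), 0L))
    density <- ns / total_len
    n_events <- max(1L, round(cfg$epiallele_rate * ns /
                                (epi_block_bp * density)))
    anchors <- sample.int(ns, n_events)
    epicenter <- sample.int(n, n_events, replace = TRUE)
    u <- stats::runif(n_events)
    kern <- exp(-D[epicenter, , drop = FALSE] / K$epi_range)
    epi <- rep(FALSE, ns)
    for (ev in seq_len(n_events)) {
      i <- anchors[ev]
      sel <- which(sites$chrom == sites$chrom[i] &
                     sites$pos >= sites$pos[i] &
                     sites$pos < sites$pos[i] + epi_block_bp)
      sel <- sel[is.na(site_override[sel])]
      if (!length(sel)) next
      epi[sel] <- TRUE
      flip <- kern[ev, ] > u[ev]
      meth[sel, ] <- (anc_meth[sel] +
                        matrix(flip, length(sel), n, byrow = TRUE)) %% 2
    }
  }

  ## panel SNPs with deamination elevation ---------------------------------
  lens <- vapply(subs, function(s) nchar(seqs[paste0("chr", s)]), 0L)
  snp_tab <- make_panel_snps(cfg, seqs, lens, sites, anc_meth, subs, K)
  geno <- draw_genotypes(snp_tab, pop, cfg, K)      # n_snp x n in {0,1,2}

  ## per-accession VCFs -----------------------------------------------------
  vcfs <- lapply(seq_len(n), function(i) {
    carrier <- which(geno[, i] > 0)
    if (!length(carrier)) return(empty_vcf())
    het <- geno[carrier, i] == 1
    dp <- pmax(1L, stats::rpois(length(carrier), cfg$mean_coverage))
    altc <- ifelse(het, stats::rbinom(length(carrier), dp, 0.5), dp)
    altc <- pmax(altc, 1L)
    df <- data.frame(chrom = snp_tab$chrom[carrier], pos = snp_tab$pos[carrier],
                     ref = snp_tab$ref[carrier], alt = snp_tab$alt[carrier],
                     qual = round(stats::runif(length(carrier), 35, 60), 1),
                     gt = ifelse(het, "0/1", "1/1"), depth = dp,
                     ref_count = dp - altc, alt_count = altc,
                     stringsAsFactors = FALSE)
    df$alt_fraction <- df$alt_count / df$depth
    df$homozygous <- !het
    df[order(df$chrom, df$pos), ]
  })
  names(vcfs) <- accessions$id

  ## cytosine reports -------------------------------------------------------
  # homozygous SNP at the C abolishes the site for that accession
  site_key <- paste(sites$chrom, sites$pos)
  abolished <- matrix(FALSE, ns, n)
  hom_at_c <- which(paste(snp_tab$chrom, snp_tab$pos) %in% site_key)
  if (length(hom_at_c)) {
    row_of <- match(paste(snp_tab$chrom, snp_tab$pos)[hom_at_c], site_key)
    for (i in seq_len(n)) {
      hom <- geno[hom_at_c, i] == 2
      if (any(hom)) {
        rows <- row_of[hom]
        # a position can host two site rows (one per strand)
        both <- which(site_key %in% site_key[rows])
        abolished[both, i] <- TRUE
      }
    }
  }
  lev_meth <- c(CpG = cfg$cpg_meth_high, CHG = K$chg_level,
                CHH = cfg$chh_meth_mean)[sites$context]
  cp_ctx <- derive_contexts(stats::setNames(seqs["chloroplast"], "chloroplast"))
  reports <- lapply(seq_len(n), function(i) {
    keep <- !abolished[, i]
    p <- ifelse(meth[keep, i] == 1, lev_meth[keep], 1 - cfg$conversion_rate)
    nuc <- sample_counts(sum(keep), cfg$mean_coverage, p)
    nuc_cp <- sample_counts(nrow(cp_ctx), cfg$mean_coverage,
                            1 - cfg$conversion_rate)
    rbind(
      data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                 strand = sites$strand[keep], n_meth = nuc$n_meth,
                 n_unmeth = nuc$n_unmeth, context = sites$context[keep],
                 stringsAsFactors = FALSE),
      data.frame(chrom = cp_ctx$chrom, pos = cp_ctx$pos,
                 strand = cp_ctx$strand, n_meth = nuc_cp$n_meth,
                 n_unmeth = nuc_cp$n_unmeth, context = cp_ctx$context,
                 stringsAsFactors = FALSE))
  })
  names(reports) <- accessions$id

  ## ancestor (D-lineage progenitor) report ---------------------------------
  d_rows <- which(sites$chrom == "chrD")
  p_anc <- ifelse(anc_meth[d_rows] == 1, lev_meth[d_rows],
                  1 - cfg$conversion_rate)
  nuc_a <- sample_counts(length(d_rows), cfg$mean_coverage, p_anc)
  ancestor_report <- data.frame(
    chrom = sites$chrom[d_rows], pos = sites$pos[d_rows],
    strand = sites$strand[d_rows], n_meth = nuc_a$n_meth,
    n_unmeth = nuc_a$n_unmeth, context = sites$context[d_rows],
    stringsAsFactors = FALSE)

  ## transposable elements ---------------------------------------------------
  te <- simulate_te(cfg, accessions, K)

  truth <- list(
    map = genome$map, sites = sites, meth_state = meth,
    epiallele = epi, ancestor_methylation = anc_meth,
    population_labels = stats::setNames(pop, accessions$id),
    coords = coords, snps = snp_tab, genotypes = geno,
    te_multipliers = te$multipliers, depth_factors = te$depth_factors,
    triads = data.frame(triad = seq_len(n_triads), class = triad_class,
                        meth_genome = triad_meth_genome,
                        stringsAsFactors = FALSE),
    annotation = ann)

  log_info("simulate_panel: %d accessions, %d cytosine sites, %d SNPs",
           n, ns, nrow(snp_tab))
  structure(list(accessions = accessions, reports = reports, vcf = vcfs,
                 te = te$counts, te_reference = te$reference,
                 ancestor_report = ancestor_report, truth = truth, cfg = cfg),
            class = "hexmeth_panel")
}

# Poisson coverage, binomial methylated-read sampling.
sample_counts <- function(n, mean_coverage, p) {
  cov <- stats::rpois(n, mean_coverage)
  nm <- stats::rbinom(n, cov, p)
  list(n_meth = nm, n_unmeth = cov - nm)
}

# Segregating-site table: baseline rate everywhere, deamination_fold times
# higher at ancestrally methylated cytosine positions, with C->T (G->A)
# mutant alleles at ct_bias probability there.
make_panel_snps <- function(cfg, seqs, lens, sites, anc_meth, subs, K) {
  bases <- c("A", "C", "G", "T")
  out <- lapply(subs, function(s) {
    chrom <- paste0("chr", s)
    L <- lens[[s]]
    rate <- rep(cfg$panel_snp_rate, L)
    meth_sites <- sites[sites$chrom == chrom, ][
      anc_meth[sites$chrom == chrom] == 1, ]
    rate[unique(meth_sites$pos)] <- cfg$panel_snp_rate * cfg$deamination_fold
    seg <- which(stats::runif(L) < pmin(rate, 1))
    if (!length(seg)) return(NULL)
    b <- strsplit(seqs[[chrom]], "")[[1]]
    ref <- b[seg]
    is_deam <- seg %in% meth_sites$pos & ref %in% c("C", "G")
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    deam_target <- ifelse(ref == "C", "T", "A")
    use_ct <- is_deam & stats::runif(length(seg)) < K$ct_bias
    alt[use_ct] <- deam_target[use_ct]
    data.frame(chrom = chrom, pos = seg, ref = ref, alt = alt,
               anc_methylated = seg %in% meth_sites$pos,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

# Balding-Nichols population frequencies; genotypes 0 (ref), 1 (het),
# 2 (hom alt) for predominantly selfing accessions.
draw_genotypes <- function(snp_tab, pop, cfg, K) {
  m <- nrow(snp_tab)
  n <- length(pop)
  f0 <- stats::rbeta(m, 1.2, 3)
  fst <- K$fst
  fpop <- matrix(stats::rbeta(m * cfg$n_populations,
                              rep(f0, cfg$n_populations) * (1 - fst) / fst,
                              rep(1 - f0, cfg$n_populations) * (1 - fst) / fst),
                 m, cfg$n_populations)
  carrier <- matrix(stats::runif(m * n), m, n) < fpop[, pop, drop = FALSE]
  het <- carrier & matrix(stats::runif(m * n), m, n) < K$het_rate
  geno <- matrix(0L, m, n)
  geno[carrier] <- 2L
  geno[het] <- 1L
  geno
}

# TE families with per-accession copy-number multipliers (panel-wide SINE
# expansion planted at 1.5x) and per-accession sequencing-depth factors.
simulate_te <- function(cfg, accessions, K) {
  n <- nrow(accessions)
  subclasses <- c("DNA;TIR;CACTA", "retro;LTR;Gypsy", "retro;SINE",
                  "retro;LTR;Copia", "DNA;TIR;Mariner", "DNA;Helitron")
  fam <- data.frame(
    family = sprintf("TE%02d", seq_len(cfg$te_families)),
    subclass = rep_len(subclasses, cfg$te_families),
    stringsAsFactors = FALSE)
  fam$class <- ifelse(startsWith(fam$subclass, "DNA"),
                      "DNA-transposon", "retrotransposon")
  ref_bases <- stats::rlnorm(cfg$te_families, log(2e6), 0.8)
  ref_bases <- ref_bases / sum(ref_bases) * 5e7
  mult <- matrix(stats::rlnorm(n * cfg$te_families, 0, 0.05),
                 n, cfg$te_families, dimnames = list(accessions$id, fam$family))
  sine <- fam$subclass == "retro;SINE"
  mult[, sine] <- stats::rlnorm(n * sum(sine), log(1.5), 0.05)
  depth <- stats::rlnorm(n, 0, 0.3)
  counts <- lapply(seq_len(n), function(i)
    data.frame(family = fam$family, class = fam$class,
               subclass = fam$subclass,
               bases = round(ref_bases * mult[i, ] * depth[i]),
               stringsAsFactors = FALSE))
  names(counts) <- accessions$id
  reference <- data.frame(family = fam$family, class = fam$class,
                          subclass = fam$subclass, bases = round(ref_bases),
                          stringsAsFactors = FALSE)
  list(counts = counts, reference = reference, multipliers = mult,
       depth_factors = stats::setNames(depth, accessions$id))
}

#' Simulate triad expression with promoter-methylation imbalance
#'
#' Homoeolog triads whose promoter is methylated on exactly one subgenome
#' express that homoeolog at a reduced normalised share (default 28.82%
#' against 35.59% for each of the other two); balanced and tri-methylated
#' triads are symmetric at one third each. Two accessions are simulated
#' with `n_reps` replicates; a planted fraction of triads is differentially
#' expressed between them with a `de_fold` total-expression shift.
#' Replicate noise is lognormal.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground-truth list from [simulate_panel()] (uses `$triads`).
#' @param n_reps Replicates per accession (default 3).
#' @param noise_sd Lognormal replicate noise SD on the log scale
#'   (default 0.15); 0 gives exact shares.
#' @param de_fraction Fraction of triads planted as differentially
#'   expressed (default 0.1).
#' @param de_fold Total-expression fold change of planted DE triads
#'   (default 2).
#' @param uni_shares Normalised percentage shares (methylated genome first)
#'   for uni-methylated triads; default `c(28.82, 35.59, 35.59)`.
#' @return List with `expr` (gene x sample matrix, genes named
#'   `g<triad>_<subgenome>`), `samples` (sample, accession, replicate),
#'   `triads` (class annotation), `true_de` (DE triad ids).
#' @export
simulate_expression <- function(cfg, truth, n_reps = 3, noise_sd = 0.15,
                                de_fraction = 0.1, de_fold = 2,
                                uni_shares = c(28.82, 35.59, 35.59)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  triads <- truth$triads
  nt <- nrow(triads)
  subs <- c("A", "B", "D")
  shares <- matrix(1 / 3, nt, 3, dimnames = list(NULL, subs))
  uni <- which(triads$class == "uni")
  for (i in uni) {
    mg <- triads$meth_genome[i]
    shares[i, ] <- uni_shares[c(2, 2, 2)] / 100
    shares[i, mg] <- uni_shares[1] / 100
    shares[i, ] <- shares[i, ] / sum(shares[i, ])
  }
  n_de <- round(de_fraction * nt)
  true_de <- if (n_de > 0) sort(sample.int(nt, n_de)) else integer()
  base_total <- stats::rlnorm(nt, log(300), 0.4)
  samples <- data.frame(
    sample = c(sprintf("acc1_rep%d", seq_len(n_reps)),
               sprintf("acc2_rep%d", seq_len(n_reps))),
    accession = rep(c("acc1", "acc2"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2), stringsAsFactors = FALSE)
  genes <- as.vector(t(outer(seq_len(nt), subs,
                             function(i, s) sprintf("g%d_%s", i, s))))
  expr <- matrix(0, nt * 3, nrow(samples),
                 dimnames = list(genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    total <- base_total
    if (samples$accession[j] == "acc2") total[true_de] <- total[true_de] * de_fold
    mu <- as.vector(t(shares * total))
    expr[, j] <- mu * exp(stats::rnorm(nt * 3, 0, noise_sd))
  }
  list(expr = expr, samples = samples, triads = triads,
       true_de = triads$triad[true_de])
}
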