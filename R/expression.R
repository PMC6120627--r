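#' Replicate-based differential expression between two accessions
#'
#' A Welch two-sample t-test on log2(x + 1) per gene, with the additional
#' requirement that the fold-change direction is consistent in every
#' replicate-versus-replicate comparison between the two accessions (the
#' "taking into account all replicates" rule). Genes with zero variance in
#' both groups and equal means get p = 1; with unequal means they are
#' called on the mean difference alone and flagged.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param groups Character/factor vector along columns with exactly two
#'   levels (the two accessions); at least 2 replicates each.
#' @param alpha Significance threshold (default 0.05).
#' @return Data.frame with `gene`, `p`, `lfc` (log2 fold change,
#'   group2 over group1), `consistent`, `de`, `flagged`.
#' @export
de_test <- function(expr, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two accessions required")
  ia <- which(groups == lev[1]); ib <- which(groups == lev[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("at least 2 replicates per accession required")
  lx <- log2(expr + 1)
  n_genes <- nrow(expr)
  p <- numeric(n_genes); flagged <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    a <- lx[g, ia]; b <- lx[g, ib]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) p[g] <- 1
      else { p[g] <- 0; flagged[g] <- TRUE }
    } else {
      p[g] <- stats::t.test(a, b)$p.value
    }
  }
  diffs <- apply(lx, 1, function(z) {
    d <- outer(z[ib], z[ia], `-`)
    all(d > 0) || all(d < 0)
  })
  lfc <- rowMeans(lx[, ib, drop = FALSE]) - rowMeans(lx[, ia, drop = FALSE])
  genes <- rownames(expr)
  if (is.null(genes)) genes <- as.character(seq_len(n_genes))
  data.frame(gene = genes, p = p, lfc = lfc, consistent = diffs,
             de = p < alpha & diffs, flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Allelic expression balance of homoeolog triads
#'
#' Normalises each triad's per-replicate expression so the A, B and D
#' shares sum to 100%, averages across replicates, stratifies by promoter
#' methylation class, and contrasts - within uni-methylated triads - the
#' methylated genome's share against the other two genomes' shares (Welch
#' two-sided t).
#'
#' @param expr_long Data.frame with `triad`, `subgenome` (`A`/`B`/`D`),
#'   `replicate`, `value` (non-negative expression).
#' @param triads Data.frame with `triad`, `class`
#'   (`balanced`/`uni`/`tri`/...), `meth_genome` (label for uni triads).
#' @return List with `shares` (triad x subgenome mean percentage shares,
#'   each row summing to 100), `class_means` (mean share of the
#'   methylated/other genomes per class), `t`, `p` (uni contrast; `NA`
#'   when fewer than 2 uni triads).
#' @export
allelic_balance <- function(expr_long, triads) {
  if (any(expr_long$value < 0)) stop("negative expression values")
  key <- paste(expr_long$triad, expr_long$replicate)
  tot <- stats::ave(expr_long$value, key, FUN = sum)
  share <- ifelse(tot > 0, 100 * expr_long$value / tot, NA_real_)
  agg <- stats::aggregate(
    list(share = share),
    by = list(triad = expr_long$triad, subgenome = expr_long$subgenome),
    FUN = mean)
  shares <- stats::reshape(agg, idvar = "triad", timevar = "subgenome",
                           direction = "wide")
  names(shares) <- sub("^share\\.", "", names(shares))
  shares <- shares[order(shares$triad), ]
  rownames(shares) <- NULL
  info <- triads[match(shares$triad, triads$triad), ]
  sub_cols <- setdiff(names(shares), "triad")
  uni <- which(info$class == "uni")
  meth_share <- other_share <- numeric(0)
  if (length(uni)) {
    meth_share <- vapply(uni, function(i)
      shares[i, info$meth_genome[i]], 0)
    other_share <- unlist(lapply(uni, function(i)
      unlist(shares[i, setdiff(sub_cols, info$meth_genome[i])])))
  }
  class_means <- do.call(rbind, lapply(split(seq_len(nrow(shares)),
                                             info$class), function(ix)
    data.frame(n = length(ix),
               mean_share_A = mean(shares$A[ix]),
               mean_share_B = mean(shares$B[ix]),
               mean_share_D = mean(shares$D[ix]))))
  class_means$class <- rownames(class_means)
  rownames(class_means) <- NULL
  tt <- if (length(uni) >= 2 &&
            (stats::sd(meth_share) > 0 || stats::sd(other_share) > 0)) {
    stats::t.test(meth_share, other_share)
  } else NULL
  list(shares = shares,
       class_means = class_means[, c("class", "n", "mean_share_A",
                                     "mean_share_B", "mean_share_D")],
       uni_meth_share_mean = if (length(uni)) mean(meth_share) else NA_real_,
       uni_other_share_mean = if (length(uni)) mean(other_share) else NA_real_,
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p = if (is.null(tt)) NA_real_ else tt$p.value)
}

#' Overlap between DMR-associated genes and differentially expressed genes
#'
#' @param dmr_genes Character vector of genes associated with DMRs.
#' @param de_genes Character vector of differentially expressed genes.
#' @param background_genes All analysed genes.
#' @return List with `overlap_fraction` (fraction of DMR genes that are
#'   DE), `background_rate`, `enrichment` (ratio of the two); all `NA`
#'   with a warning when the DMR gene set is empty.
#' @export
dmr_de_overlap <- function(dmr_genes, de_genes, background_genes) {
  dmr_genes <- unique(dmr_genes)
  if (length(dmr_genes) == 0) {
    warning("empty DMR gene set; overlap undefined")
    return(list(overlap_fraction = NA_real_, background_rate = NA_real_,
                enrichment = NA_real_))
  }
  overlap <- mean(dmr_genes %in% de_genes)
  bg <- length(intersect(de_genes, background_genes)) / length(background_genes)
  list(overlap_fraction = overlap, background_rate = bg,
       enrichment = if (bg > 0) overlap / bg else NA_real_)
}

#' Plain two-sample Welch t-test utility
#'
#' Convenience wrapper used for phenotype/element contrasts between
#' accession groups.
#'
#' @param x,y Numeric vectors.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
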