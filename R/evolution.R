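#' Deamination enrichment of SNPs at ancestrally methylated cytosines
#'
#' 5-methylcytosine deaminates to thymine, so cytosines methylated in the
#' D-lineage ancestor should more often carry a different allele in the
#' descendant panel, with a predominance of C-to-T (G-to-A on the minus
#' strand) transitions. For each accession, ancestor cytosines (called with
#' the standard thresholds) are stratified into methylated and
#' unmethylated; the fraction of sites carrying a divergent homozygous
#' allele, and the C-to-T fraction among those, are computed per stratum.
#' Strata are contrasted by paired two-sided t-tests across accessions.
#'
#' A "different allele" is any homozygous descendant allele differing from
#' the ancestor base; heterozygous calls are excluded, consistent with the
#' homozygous-SNP pipeline.
#'
#' @param ancestor_calls Data.frame with `chrom`, `pos`, `strand`, `status`
#'   (`methylated`/`unmethylated`; other values ignored), covering the
#'   descendant-mappable, context-preserved analysis set.
#' @param alleles_by_accession Named list of data.frames (`chrom`, `pos`,
#'   `alt`, `homozygous`) of per-accession variant calls at descendant
#'   coordinates.
#' @return A `deamination_result` list: `per_accession` data.frame
#'   (divergence and C-to-T fractions per stratum, per-accession fold),
#'   `fold` (ratio of the across-accession mean divergence fractions),
#'   `t_divergence`, `t_ct` (paired t statistics and p-values), and site
#'   counts.
#' @export
deamination_enrichment <- function(ancestor_calls, alleles_by_accession) {
  meth <- ancestor_calls$status == "methylated"
  unmeth <- ancestor_calls$status == "unmethylated"
  if (!any(meth)) stop("no methylated ancestor sites")
  key <- paste(ancestor_calls$chrom, ancestor_calls$pos)
  deam_allele <- ifelse(ancestor_calls$strand == "+", "T", "A")
  rows <- lapply(names(alleles_by_accession), function(acc) {
    al <- alleles_by_accession[[acc]]
    al <- al[al$homozygous, , drop = FALSE]
    hit <- match(key, paste(al$chrom, al$pos))
    divergent <- !is.na(hit)
    is_ct <- divergent & al$alt[hit] == deam_allele
    n_m <- sum(meth); n_u <- sum(unmeth)
    if (n_m == 0 || n_u == 0) return(NULL)
    div_m <- sum(divergent & meth); div_u <- sum(divergent & unmeth)
    data.frame(
      accession = acc,
      n_methylated = n_m, n_unmethylated = n_u,
      p_divergent_methylated = div_m / n_m,
      p_divergent_unmethylated = div_u / n_u,
      frac_ct_methylated = if (div_m > 0) sum(is_ct & meth) / div_m else NA_real_,
      frac_ct_unmethylated = if (div_u > 0) sum(is_ct & unmeth) / div_u else NA_real_,
      stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped) log_info("deamination_enrichment: %d accession(s) excluded",
                        dropped)
  per <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  per$fold <- ifelse(per$p_divergent_unmethylated > 0,
                     per$p_divergent_methylated / per$p_divergent_unmethylated,
                     NA_real_)
  mean_u <- mean(per$p_divergent_unmethylated)
  fold <- if (mean_u > 0) mean(per$p_divergent_methylated) / mean_u else NA_real_
  paired_t <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || stats::sd(x[ok] - y[ok]) == 0)
      return(list(statistic = NA_real_, p.value = NA_real_))
    tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
    list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  structure(list(
    per_accession = per, fold = fold,
    degenerate = all(per$p_divergent_methylated == 0) &
      all(per$p_divergent_unmethylated == 0),
    t_divergence = paired_t(per$p_divergent_methylated,
                            per$p_divergent_unmethylated),
    t_ct = paired_t(per$frac_ct_methylated, per$frac_ct_unmethylated)),
    class = "deamination_result")
}

#' Ancestor-descendant methylation conservation
#'
#' Joins ancestor and descendant methylation calls on shared covered
#' positions and reports: the fraction of ancestor-methylated sites still
#' methylated (conserved) or unmethylated (lost) in the descendant, and
#' the fraction of ancestor-unmethylated sites methylated in the
#' descendant (gained) or still unmethylated.
#'
#' @param ancestor_calls,descendant_calls Data.frames with `chrom`, `pos`,
#'   `strand`, `status`; only rows called `methylated` or `unmethylated`
#'   on both sides enter.
#' @return List of fractions `conserved_methylated`, `lost`, `gained`,
#'   `conserved_unmethylated` plus the stratum site counts.
#'   `conserved_methylated + lost = 1` over ancestor-methylated sites.
#' @export
ancestral_conservation <- function(ancestor_calls, descendant_calls) {
  called <- c("methylated", "unmethylated")
  a <- ancestor_calls[ancestor_calls$status %in% called, ]
  d <- descendant_calls[descendant_calls$status %in% called, ]
  hit <- match(paste(a$chrom, a$pos, a$strand), paste(d$chrom, d$pos, d$strand))
  ok <- !is.na(hit)
  if (!any(ok)) stop("no shared called positions")
  a_meth <- a$status[ok] == "methylated"
  d_meth <- d$status[hit[ok]] == "methylated"
  n_am <- sum(a_meth); n_au <- sum(!a_meth)
  list(conserved_methylated = if (n_am) sum(a_meth & d_meth) / n_am else NA_real_,
       lost = if (n_am) sum(a_meth & !d_meth) / n_am else NA_real_,
       gained = if (n_au) sum(!a_meth & d_meth) / n_au else NA_real_,
       conserved_unmethylated = if (n_au) sum(!a_meth & !d_meth) / n_au else NA_real_,
       n_ancestor_methylated = n_am, n_ancestor_unmethylated = n_au)
}
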