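#' Identify single methylation polymorphisms across a panel
#'
#' An SMP is a cytosine site that is covered by at least `min_cov` reads in
#' every accession, carries the same sequence context in every accession
#' (no homozygous SNP inside the context window), and is called methylated
#' (epiallele code 100) in at least two accessions and unmethylated
#' (level < 1%, code 0) in at least two. Intermediate-level accessions are
#' coded 50 ("heterozygous" epiallele) and do not count towards either
#' requirement.
#'
#' @param reports Named list (>= 4 accessions) of cytosine report
#'   data.frames sharing a site universe.
#' @param min_cov Minimum coverage in every accession (default 10).
#' @param excluded_sites Optional data.frame (`chrom`, `pos`, `strand`) of
#'   sites whose context is broken by a panel SNP (see
#'   [context_broken_sites()]).
#' @return An `smp_matrix`: list with `sites` (chrom, pos, strand, context)
#'   and `codes` (sites x accessions integer matrix over \{0, 50, 100\}).
#' @export
identify_smps <- function(reports, min_cov = 10, excluded_sites = NULL) {
  if (length(reports) < 4)
    stop("SMP identification requires at least 4 accessions")
  if (is.null(names(reports)))
    names(reports) <- paste0("acc", seq_along(reports))
  keys <- lapply(reports, function(r) paste(r$chrom, r$pos, r$strand))
  common <- Reduce(intersect, keys)
  r1 <- reports[[1]]
  ix1 <- match(common, keys[[1]])
  sites <- data.frame(chrom = r1$chrom[ix1], pos = r1$pos[ix1],
                      strand = r1$strand[ix1], context = r1$context[ix1],
                      stringsAsFactors = FALSE)
  n_acc <- length(reports)
  codes <- matrix(NA_integer_, nrow(sites), n_acc,
                  dimnames = list(NULL, names(reports)))
  covered <- matrix(FALSE, nrow(sites), n_acc)
  for (j in seq_len(n_acc)) {
    r <- reports[[j]][match(common, keys[[j]]), ]
    cov <- r$n_meth + r$n_unmeth
    lev <- ifelse(cov > 0, 100 * r$n_meth / cov, NA_real_)
    st <- call_status(lev, r$context, cov, min_cov)
    covered[, j] <- st != "uncovered"
    codes[, j] <- c(methylated = 100L, unmethylated = 0L,
                    intermediate = 50L, uncovered = NA_integer_)[st]
  }
  keep <- rowSums(covered) == n_acc
  if (!is.null(excluded_sites) && nrow(excluded_sites)) {
    bad <- paste(sites$chrom, sites$pos, sites$strand) %in%
      paste(excluded_sites$chrom, excluded_sites$pos, excluded_sites$strand)
    keep <- keep & !bad
  }
  keep <- keep & rowSums(codes == 100L, na.rm = TRUE) >= 2 &
    rowSums(codes == 0L, na.rm = TRUE) >= 2
  sites <- sites[keep, , drop = FALSE]
  codes <- codes[keep, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  codes <- codes[ord, , drop = FALSE]
  log_info("identify_smps: %d SMPs across %d accessions", nrow(sites), n_acc)
  structure(list(sites = sites, codes = codes), class = "smp_matrix")
}

#' Sites methylated in one accession
#'
#' An individual accession's SMPs: the sites from the general SMP list
#' where that accession is coded 100.
#'
#' @param m An `smp_matrix`.
#' @param accession Accession id (column name of the code matrix).
#' @return Data.frame of sites (subset of `m$sites`).
#' @export
accession_smps <- function(m, accession) {
  stopifnot(inherits(m, "smp_matrix"))
  if (!accession %in% colnames(m$codes))
    stop("unknown accession: ", accession)
  m$sites[m$codes[, accession] == 100L, , drop = FALSE]
}

#' Per-site methylation conservation profile
#'
#' For every SMP, the fraction of accessions methylated there, plus binned
#' summaries per context: highly conserved (methylated in >= 90% of
#' accessions) and rare (< 10%).
#'
#' @param m An `smp_matrix`.
#' @return List with `profile` (per-site data.frame including
#'   `frac_methylated` as a percentage) and `bins` (per-context counts and
#'   fractions in the >= 90% and < 10% bins).
#' @export
conservation_profile <- function(m) {
  stopifnot(inherits(m, "smp_matrix"))
  if (nrow(m$sites) == 0) stop("empty SMP matrix")
  frac <- 100 * rowMeans(m$codes == 100L)
  profile <- cbind(m$sites, frac_methylated = frac)
  bins <- do.call(rbind, lapply(split(frac, m$sites$context), function(f)
    data.frame(n = length(f), n_high = sum(f >= 90), n_low = sum(f < 10),
               frac_high = mean(f >= 90), frac_low = mean(f < 10))))
  bins$context <- rownames(bins)
  rownames(bins) <- NULL
  list(profile = profile, bins = bins)
}

#' Partition methylated genes into high / medium / low conservation groups
#'
#' Genes targeted by CpG methylation in at least one accession are split by
#' how many accessions show them methylated: the high group appears in at
#' least 90 accessions of a 105-accession panel, the medium group in 40 to
#' 89, the low group in fewer than 40; both cut points scale
#' proportionally with panel size.
#'
#' @param presence Logical (or 0/1) matrix, genes x accessions: gene
#'   methylated in that accession.
#' @param high_frac,low_frac Cut points as fractions of the panel
#'   (defaults 90/105 and 40/105).
#' @return List of character vectors `high`, `medium`, `low`; their union
#'   is every gene present in >= 1 accession.
#' @export
gene_methylation_groups <- function(presence, high_frac = 90 / 105,
                                    low_frac = 40 / 105) {
  counts <- rowSums(presence > 0)
  n <- ncol(presence)
  hi <- ceiling(high_frac * n)
  lo <- ceiling(low_frac * n)
  genes <- rownames(presence)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(presence)))
  list(high = genes[counts >= hi],
       medium = genes[counts >= lo & counts < hi],
       low = genes[counts >= 1 & counts < lo])
}

#' Gene-family methylation representation profile
#'
#' For every family and accession, the fraction of member genes methylated;
#' families whose across-accession mean representation is at least 25% are
#' flagged.
#'
#' @param families Named list of character vectors (family -> member gene
#'   ids); families partition a subset of the genes.
#' @param presence Logical matrix, genes x accessions (rownames are gene
#'   ids).
#' @param min_mean Flagging threshold on the across-accession mean fraction
#'   (default 0.25).
#' @return List with `fractions` (family x accession matrix in \[0, 1\]),
#'   `mean_fraction`, `flagged` (logical per family).
#' @export
family_methylation_profile <- function(families, presence, min_mean = 0.25) {
  if (any(lengths(families) == 0))
    stop("family with zero member genes")
  frac <- t(vapply(families, function(genes) {
    miss <- setdiff(genes, rownames(presence))
    if (length(miss)) stop("unknown gene(s) in family: ", miss[1])
    colMeans(presence[genes, , drop = FALSE] > 0)
  }, numeric(ncol(presence))))
  mean_frac <- rowMeans(frac)
  list(fractions = frac, mean_fraction = mean_frac,
       flagged = mean_frac >= min_mean)
}
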