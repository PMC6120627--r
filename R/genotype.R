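#' Select homozygous SNPs
#'
#' Applies the variant filters used before accession-specific reference
#' correction: minimum call quality 30, minimum coverage 5, and alternate
#' allele supported by at least 80% of reads (homozygous calls only).
#'
#' @param snps Data.frame of variant records with columns `chrom`, `pos`,
#'   `ref`, `alt`, `qual`, `depth`, `alt_count` (as from [read_vcf()]).
#' @param min_depth Minimum read depth (default 5).
#' @param min_alt_frac Minimum alternate-allele read fraction (default 0.8).
#' @param min_qual Minimum variant quality (default 30).
#' @return The retained records with `alt_fraction` computed and
#'   `homozygous = TRUE`. May be empty.
#' @export
filter_homozygous <- function(snps, min_depth = 5, min_alt_frac = 0.8,
                              min_qual = 30) {
  stopifnot(all(c("depth", "alt_count", "qual") %in% names(snps)))
  snps$alt_fraction <- ifelse(snps$depth > 0, snps$alt_count / snps$depth, 0)
  keep <- snps$depth >= min_depth &
    snps$alt_fraction >= min_alt_frac &
    snps$qual >= min_qual
  out <- snps[keep, , drop = FALSE]
  out$homozygous <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Correct a reference with homozygous SNP alleles
#'
#' Substitutes homozygous alternate alleles into the reference to produce an
#' accession-specific reference sequence. Substitutions only; indels are not
#' applied, so coordinates remain stable across accessions.
#'
#' @param reference Named [Biostrings::DNAStringSet].
#' @param snps Data.frame with `chrom`, `pos`, `ref`, `alt` (single-base
#'   substitutions).
#' @return A [Biostrings::DNAStringSet] differing from `reference` at
#'   exactly the SNP positions.
#' @export
correct_reference <- function(reference, snps) {
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  if (nrow(snps) == 0) return(reference)
  if (anyDuplicated(paste(snps$chrom, snps$pos)))
    stop("two SNPs at the same position")
  if (any(nchar(snps$ref) != 1 | nchar(snps$alt) != 1))
    stop("only single-base substitutions can be applied")
  out <- as.character(reference)
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, ]
    if (!ch %in% names(out)) stop("unknown chromosome ", ch)
    if (any(s$pos < 1 | s$pos > nchar(out[[ch]])))
      stop("SNP position outside reference length on ", ch)
    seqchars <- strsplit(out[[ch]], "")[[1]]
    mism <- which(seqchars[s$pos] != s$ref)
    if (length(mism))
      stop("reference allele mismatch at ", ch, ":", s$pos[mism[1]],
           " (reference has ", seqchars[s$pos[mism[1]]],
           ", SNP record says ", s$ref[mism[1]], ")")
    seqchars[s$pos] <- s$alt
    out[[ch]] <- paste(seqchars, collapse = "")
  }
  Biostrings::DNAStringSet(out)
}

#' Derive strand-aware cytosine contexts
#'
#' Assigns every cytosine its methylation context. On the plus strand a `C`
#' at position i is `CpG` if position i+1 is `G`, `CHG` if position i+2 is
#' `G`, otherwise `CHH`. A `G` at position i is a cytosine on the minus
#' strand; reading the reverse complement, it is `CpG` if position i-1 is
#' `C`, `CHG` if position i-2 is `C`, otherwise `CHH`. Cytosines whose
#' two-base lookahead runs past the sequence end get no context and are
#' omitted. Ambiguity codes are tolerated: any base other than `G` (plus) or
#' `C` (minus) counts as `H`.
#'
#' @param sequence A [Biostrings::DNAStringSet], single sequence, or named
#'   character vector.
#' @return Data.frame with `chrom`, `pos` (1-based), `strand`, `context`.
#' @export
derive_contexts <- function(sequence) {
  if (methods::is(sequence, "DNAString"))
    sequence <- Biostrings::DNAStringSet(list(seq = sequence))
  if (methods::is(sequence, "DNAStringSet")) sequence <- as.character(sequence)
  if (is.null(names(sequence))) names(sequence) <- paste0("seq", seq_along(sequence))
  out <- lapply(names(sequence), function(ch) {
    b <- strsplit(toupper(sequence[[ch]]), "")[[1]]
    L <- length(b)
    plus <- which(b == "C")
    plus <- plus[plus + 2 <= L]
    ctx_p <- ifelse(b[plus + 1] == "G", "CpG",
                    ifelse(b[plus + 2] == "G", "CHG", "CHH"))
    minus <- which(b == "G")
    minus <- minus[minus - 2 >= 1]
    ctx_m <- ifelse(b[minus - 1] == "C", "CpG",
                    ifelse(b[minus - 2] == "C", "CHG", "CHH"))
    df <- data.frame(
      chrom = rep(ch, length(plus) + length(minus)),
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      context = c(ctx_p, ctx_m),
      stringsAsFactors = FALSE)
    df[order(df$pos, df$strand), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Does an accession's local haplotype shift a cytosine's context?
#'
#' Applies the accession's homozygous SNPs inside the context window of one
#' reference cytosine and re-derives the context. Reports whether the
#' cytosine is abolished (a SNP at the C itself) or its context class
#' changes.
#'
#' @param reference Named [Biostrings::DNAStringSet] or character vector.
#' @param snps Homozygous SNP data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param chrom,pos,strand Site coordinates (1-based) and strand.
#' @return List with `abolished`, `changed`, `ref_context`, `new_context`
#'   (`new_context` is `NA` when the cytosine is abolished).
#' @export
context_shift <- function(reference, snps, chrom, pos, strand) {
  if (methods::is(reference, "DNAStringSet")) reference <- as.character(reference)
  seqchars <- strsplit(toupper(reference[[chrom]]), "")[[1]]
  win <- if (strand == "+") pos:(pos + 2) else (pos - 2):pos
  if (min(win) < 1 || max(win) > length(seqchars))
    stop("context window extends past sequence end at ", chrom, ":", pos)
  ref_ctx <- context_of(seqchars, pos, strand)
  s <- snps[snps$chrom == chrom & snps$pos %in% win, , drop = FALSE]
  if (nrow(s)) seqchars[s$pos] <- s$alt
  cbase <- if (strand == "+") "C" else "G"
  if (seqchars[pos] != cbase) {
    return(list(abolished = TRUE, changed = TRUE,
                ref_context = ref_ctx, new_context = NA_character_))
  }
  new_ctx <- context_of(seqchars, pos, strand)
  list(abolished = FALSE, changed = !identical(new_ctx, ref_ctx),
       ref_context = ref_ctx, new_context = new_ctx)
}

# Context of the cytosine at pos/strand in a character vector of bases;
# NA when there is no cytosine there or the lookahead is incomplete.
context_of <- function(b, pos, strand) {
  L <- length(b)
  if (strand == "+") {
    if (b[pos] != "C" || pos + 2 > L) return(NA_character_)
    if (b[pos + 1] == "G") "CpG" else if (b[pos + 2] == "G") "CHG" else "CHH"
  } else {
    if (b[pos] != "G" || pos - 2 < 1) return(NA_character_)
    if (b[pos - 1] == "C") "CpG" else if (b[pos - 2] == "C") "CHG" else "CHH"
  }
}

#' Sites whose sequence context is broken by a panel SNP
#'
#' Implements the "same sequence in all accessions" filter for SMP
#' identification: a cytosine site is excluded when any accession carries a
#' homozygous SNP inside its strand-aware context window (the C itself plus
#' two bases downstream on its strand).
#'
#' @param sites Data.frame with `chrom`, `pos`, `strand`.
#' @param snps_by_accession List (one element per accession) of homozygous
#'   SNP data.frames with `chrom`, `pos`.
#' @return Logical vector along `sites`: `TRUE` where the site must be
#'   excluded.
#' @export
context_broken_sites <- function(sites, snps_by_accession) {
  snp_keys <- unique(unlist(lapply(snps_by_accession, function(s)
    if (nrow(s)) paste(s$chrom, s$pos) else character())))
  if (!length(snp_keys)) return(rep(FALSE, nrow(sites)))
  hit <- rep(FALSE, nrow(sites))
  for (k in 0:2) {
    off <- ifelse(sites$strand == "+", k, -k)
    hit <- hit | paste(sites$chrom, sites$pos + off) %in% snp_keys
  }
  hit
}
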