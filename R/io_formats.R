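#' Read a per-cytosine report table
#'
#' Reads the Bismark CX-style cytosine report dialect used throughout the
#' pipeline: a headerless TSV with columns `chrom`, `pos` (1-based), `strand`
#' (`+`/`-`), `count_methylated`, `count_unmethylated`, `context`
#' (`CpG`/`CHG`/`CHH`). One row per cytosine per strand; CpG sites are not
#' merged across strands, since every analysis scores cytosine residues
#' individually.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, `context`. An empty file yields a zero-row data.frame.
#' @export
read_cytosine_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_report())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6)
  if (length(bad))
    stop("malformed cytosine report row at line ", bad[1], " of ", path)
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  nm  <- suppressWarnings(as.integer(m[, 4]))
  nu  <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos) | is.na(nm) | is.na(nu) | pos < 1 | nm < 0 | nu < 0)
  if (length(bad))
    stop("invalid position or count at line ", bad[1], " of ", path)
  if (!all(m[, 3] %in% c("+", "-")))
    stop("strand must be '+' or '-' in ", path)
  bad <- which(!m[, 6] %in% c("CpG", "CHG", "CHH"))
  if (length(bad))
    stop("unknown context token '", m[bad[1], 6], "' at line ", bad[1],
         " of ", path)
  data.frame(chrom = m[, 1], pos = pos, strand = m[, 3],
             n_meth = nm, n_unmeth = nu, context = m[, 6],
             stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             n_meth = integer(), n_unmeth = integer(), context = character(),
             stringsAsFactors = FALSE)
}

#' Write a per-cytosine report table
#'
#' @param x Data.frame as returned by [read_cytosine_report()].
#' @param path Output path.
#' @export
write_cytosine_report <- function(x, path) {
  utils::write.table(
    x[, c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' FASTA IO through Biostrings; lowercase bases are normalised to uppercase
#' on read.
#'
#' @param path File path.
#' @return `read_fasta`: a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a single-sample VCF
#'
#' Parses the minimal VCF v4.2 dialect emitted by [write_vcf()]: biallelic
#' substitution records with a `GT:DP:AD` FORMAT for one sample. Depth,
#' allele counts and genotype class are extracted per record.
#'
#' @param path Path to an uncompressed VCF.
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `gt`, `depth`, `ref_count`, `alt_count`, `alt_fraction`, `homozygous`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(empty_vcf())
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 10))
    stop("VCF record with fewer than 10 fields in ", path)
  m <- matrix(unlist(lapply(parts, `[`, 1:10)), ncol = 10, byrow = TRUE)
  sam <- strsplit(m[, 10], ":", fixed = TRUE)
  gt <- vapply(sam, `[`, "", 1)
  dp <- as.integer(vapply(sam, `[`, "", 2))
  ad <- strsplit(vapply(sam, `[`, "", 3), ",", fixed = TRUE)
  refc <- as.integer(vapply(ad, `[`, "", 1))
  altc <- as.integer(vapply(ad, `[`, "", 2))
  out <- data.frame(
    chrom = m[, 1], pos = as.integer(m[, 2]), ref = m[, 4], alt = m[, 5],
    qual = as.numeric(m[, 6]), gt = gt, depth = dp,
    ref_count = refc, alt_count = altc, stringsAsFactors = FALSE)
  out$alt_fraction <- ifelse(out$depth > 0, out$alt_count / out$depth, NA_real_)
  out$homozygous <- gt %in% c("1/1", "1|1")
  out
}

empty_vcf <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), gt = character(),
             depth = integer(), ref_count = integer(), alt_count = integer(),
             alt_fraction = numeric(), homozygous = logical(),
             stringsAsFactors = FALSE)
}

#' Write a single-sample VCF
#'
#' @param x Data.frame as returned by [read_vcf()].
#' @param path Output path.
#' @param sample Sample name for the header column.
#' @param contigs Optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @export
write_vcf <- function(x, path, sample = "sample", contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  recs <- if (nrow(x)) {
    ord <- order(x$chrom, x$pos)
    x <- x[ord, ]
    sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.\tGT:DP:AD\t%s:%d:%d,%d",
            x$chrom, x$pos, x$ref, x$alt, format(x$qual, trim = TRUE),
            x$gt, x$depth, x$ref_count, x$alt_count)
  } else character()
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read / write BED6 annotation intervals
#'
#' BED is 0-based, half-open: an interval `start..end` covers 1-based
#' positions `start+1 .. end`. Feature type (gene/promoter) is carried in
#' the name field as `type|id` and split into a `type` column on read.
#'
#' @param path File path.
#' @return `read_bed`: data.frame with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `type`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"))
  if (any(x$start < 0) || any(x$end < x$start))
    stop("invalid BED interval in ", path)
  x$type <- sub("\\|.*$", "", x$name)
  x
}

#' @rdname read_bed
#' @param x Data.frame with BED6 columns (a `type` column is dropped).
#' @export
write_bed <- function(x, path) {
  utils::write.table(
    x[, c("chrom", "start", "end", "name", "score", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a homoeolog coordinate map
#'
#' The on-disk format is a tab-delimited block file in the spirit of NUCmer
#' `show-coords` output: one row per gap-free aligned segment with columns
#' `from`, `from_start`, `from_end`, `to`, `to_start`, `to_end` (1-based,
#' inclusive, plus strand), preceded by `#length <subgenome> <bp>` header
#' lines. Segments are emitted for the A-B, A-D and B-D pairs.
#'
#' @param map A `homoeolog_map` (see [homoeolog_map()]).
#' @param path File path.
#' @export
write_homoeolog_map <- function(map, path) {
  stopifnot(inherits(map, "homoeolog_map"))
  hdr <- sprintf("#length\t%s\t%d", names(map$lengths),
                 as.integer(map$lengths))
  segs <- do.call(rbind, lapply(
    list(c("A", "B"), c("A", "D"), c("B", "D")),
    function(pr) map_segments(map, pr[1], pr[2])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(segs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_homoeolog_map
#' @return `read_homoeolog_map`: a `homoeolog_map` equivalent to the one
#'   written (translations agree at every position).
#' @export
read_homoeolog_map <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#length")]
  body <- lines[!startsWith(lines, "#")]
  hp <- strsplit(hdr, "\t", fixed = TRUE)
  lengths <- stats::setNames(
    vapply(hp, function(z) as.integer(z[3]), 0L),
    vapply(hp, `[`, "", 2))
  pairs <- list()
  for (s in names(lengths))
    for (t in names(lengths))
      if (s != t) pairs[[paste0(s, t)]] <- rep(NA_integer_, lengths[[s]])
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    for (p in parts) {
      from <- p[1]; to <- p[4]
      fs <- as.integer(p[2]); fe <- as.integer(p[3])
      ts <- as.integer(p[5])
      pairs[[paste0(from, to)]][fs:fe] <- ts + 0:(fe - fs)
      pairs[[paste0(to, from)]][ts + 0:(fe - fs)] <- fs:fe
    }
  }
  structure(list(pairs = pairs, lengths = lengths), class = "homoeolog_map")
}

# Contiguous constant-offset runs of the forward map, as 1-based segments.
map_segments <- function(map, from, to) {
  v <- map$pairs[[paste0(from, to)]]
  pos <- which(!is.na(v))
  if (!length(pos)) {
    return(data.frame(from = character(), from_start = integer(),
                      from_end = integer(), to = character(),
                      to_start = integer(), to_end = integer()))
  }
  off <- v[pos] - pos
  brk <- c(TRUE, diff(pos) != 1 | diff(off) != 0)
  grp <- cumsum(brk)
  fs <- tapply(pos, grp, min); fe <- tapply(pos, grp, max)
  data.frame(from = from, from_start = as.integer(fs),
             from_end = as.integer(fe), to = to,
             to_start = as.integer(fs + off[brk]),
             to_end = as.integer(fe + off[brk]),
             stringsAsFactors = FALSE)
}

#' Panel manifest
#'
#' Bundles the per-accession file paths and optional origin metadata for a
#' diversity panel. All referenced paths must exist and accession ids must
#' be unique.
#'
#' @param accessions Data.frame with columns `id`, `vcf`, `cytosine_report`
#'   and optionally `te_counts`, `country`, `latitude`, `longitude`.
#' @param reference Path to the reference FASTA.
#' @param annotation Path to the BED annotation.
#' @return A `panel_manifest` object (validated list).
#' @export
panel_manifest <- function(accessions, reference, annotation) {
  stopifnot(is.data.frame(accessions),
            all(c("id", "vcf", "cytosine_report") %in% names(accessions)))
  if (anyDuplicated(accessions$id))
    stop("accession ids must be unique")
  paths <- c(reference, annotation, accessions$vcf, accessions$cytosine_report,
             if ("te_counts" %in% names(accessions)) accessions$te_counts)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("manifest references missing file(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  structure(list(accessions = accessions, reference = reference,
                 annotation = annotation),
            class = "panel_manifest")
}

# Per-stage INFO logging; silenced via options(hexmeth.verbose = FALSE).
log_info <- function(...) {
  if (isTRUE(getOption("hexmeth.verbose", TRUE)))
    message("[hexmeth] ", sprintf(...))
  invisible(NULL)
}
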