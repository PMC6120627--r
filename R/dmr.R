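#' Aggregate cytosine counts into non-overlapping 100-bp windows
#'
#' Methylation for each context is pooled independently across
#' non-overlapping fixed windows anchored at coordinate 0 of every
#' chromosome. Only cytosines covered by at least `min_cov` reads in both
#' compared samples contribute, and a window is only considered if at
#' least `min_cytosines` qualifying cytosines fall in it (the trailing
#' partial window is retained when it qualifies).
#'
#' @param report_a,report_b Cytosine report data.frames for the two
#'   compared samples.
#' @param window Window width in bp (default 100).
#' @param min_cov Per-site coverage floor in both samples (default 10).
#' @param min_cytosines Minimum qualifying cytosines per window
#'   (default 5).
#' @return Data.frame with `chrom`, `start` (0-based), `end`, `context`,
#'   `n_cytosines`, pooled counts `a_meth`, `a_unmeth`, `b_meth`,
#'   `b_unmeth`, and pooled percentage levels `level_a`, `level_b`.
#' @export
build_windows <- function(report_a, report_b, window = 100, min_cov = 10,
                          min_cytosines = 5) {
  key_a <- paste(report_a$chrom, report_a$pos, report_a$strand)
  key_b <- paste(report_b$chrom, report_b$pos, report_b$strand)
  common <- intersect(key_a, key_b)
  a <- report_a[match(common, key_a), ]
  b <- report_b[match(common, key_b), ]
  ok <- (a$n_meth + a$n_unmeth) >= min_cov & (b$n_meth + b$n_unmeth) >= min_cov
  a <- a[ok, ]; b <- b[ok, ]
  if (nrow(a) == 0) return(empty_windows())
  win <- (a$pos - 1) %/% window
  grp <- paste(a$chrom, win, a$context, sep = "\r")
  agg <- function(x) as.vector(tapply(x, grp, sum))
  # tapply orders by sorted group key; rebuild descriptors in that order
  lev <- sort(unique(grp))
  parts <- strsplit(lev, "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)) * window,
    context = vapply(parts, `[`, "", 3),
    n_cytosines = as.vector(table(grp)[lev]),
    a_meth = agg(a$n_meth), a_unmeth = agg(a$n_unmeth),
    b_meth = agg(b$n_meth), b_unmeth = agg(b$n_unmeth),
    stringsAsFactors = FALSE)
  out$end <- out$start + window
  out <- out[out$n_cytosines >= min_cytosines, , drop = FALSE]
  out$level_a <- 100 * out$a_meth / (out$a_meth + out$a_unmeth)
  out$level_b <- 100 * out$b_meth / (out$b_meth + out$b_unmeth)
  out <- out[order(out$chrom, out$start, out$context),
             c("chrom", "start", "end", "context", "n_cytosines",
               "a_meth", "a_unmeth", "b_meth", "b_unmeth",
               "level_a", "level_b")]
  rownames(out) <- NULL
  out
}

empty_windows <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             context = character(), n_cytosines = integer(),
             a_meth = integer(), a_unmeth = integer(), b_meth = integer(),
             b_unmeth = integer(), level_a = numeric(), level_b = numeric(),
             stringsAsFactors = FALSE)
}

#' Fisher exact test on one window's pooled counts
#'
#' Two-sided exact p from the 2x2 table (methylated/unmethylated x sample).
#'
#' @param a_meth,a_unmeth Pooled counts for sample A.
#' @param b_meth,b_unmeth Pooled counts for sample B.
#' @return Two-sided p-value(s); vectorised.
#' @export
test_window <- function(a_meth, a_unmeth, b_meth, b_unmeth) {
  if (any(a_meth + a_unmeth == 0) || any(b_meth + b_unmeth == 0))
    stop("zero-total sample in window test")
  fisher_p(a_meth, a_unmeth, b_meth, b_unmeth)
}

#' Test windows and call DMRs
#'
#' Adds Fisher p and Benjamini-Hochberg q-values (corrected across all
#' tested windows in the batch), then applies the context-specific calling
#' rules: CpG and CHG windows are DMRs at an absolute methylation
#' difference of at least 50 percentage points with q < 0.01; CHH windows
#' at a difference of at least 15 points, the lower sample at or below 5%
#' methylation, and q < 0.01.
#'
#' @param windows Output of [build_windows()].
#' @param q_max Significance ceiling (default 0.01).
#' @param cg_min_diff Minimum difference for CpG/CHG windows (default 50).
#' @param chh_min_diff Minimum difference for CHH windows (default 15).
#' @param chh_low_max CHH low-side ceiling in percent (default 5).
#' @return `windows` with appended `p`, `q`, `diff` (level_a - level_b)
#'   and `is_dmr` columns. The multiple-testing method is recorded in the
#'   `"correction"` attribute.
#' @export
call_dmrs <- function(windows, q_max = 0.01, cg_min_diff = 50,
                      chh_min_diff = 15, chh_low_max = 5) {
  if (nrow(windows) == 0) {
    windows$p <- windows$q <- windows$diff <- numeric()
    windows$is_dmr <- logical()
    return(windows)
  }
  windows$p <- test_window(windows$a_meth, windows$a_unmeth,
                           windows$b_meth, windows$b_unmeth)
  windows$q <- bh_adjust(windows$p)
  windows$diff <- windows$level_a - windows$level_b
  lo <- pmin(windows$level_a, windows$level_b)
  windows$is_dmr <- ifelse(
    windows$context == "CHH",
    abs(windows$diff) >= chh_min_diff & lo <= chh_low_max & windows$q < q_max,
    abs(windows$diff) >= cg_min_diff & windows$q < q_max)
  attr(windows, "correction") <- "BH"
  log_info("call_dmrs: %d/%d windows called", sum(windows$is_dmr),
           nrow(windows))
  windows
}

#' Associate DMRs with genes and promoters
#'
#' Overlap under half-open interval semantics (both DMR windows and BED
#' annotation are 0-based half-open). A DMR may hit several features; the
#' summary reports association counts and the number of distinct features
#' per type. When the annotation has no promoter entries, promoters default
#' to `promoter_width` bp upstream of each gene's annotated start (strand
#' aware).
#'
#' @param dmrs Data.frame of called DMRs (rows of [call_dmrs()] output with
#'   `is_dmr`, or any windows to associate).
#' @param annotation BED-style data.frame with `chrom`, `start`, `end`,
#'   `name`, `strand`, `type` (`gene`/`promoter`).
#' @param promoter_width Width of default promoters when none are annotated
#'   (default 2000).
#' @return List with `associations` (dmr index, feature name, type) and
#'   `summary` (per-type association and distinct-feature counts).
#' @export
associate_features <- function(dmrs, annotation, promoter_width = 2000) {
  if (!"promoter" %in% annotation$type) {
    genes <- annotation[annotation$type == "gene", ]
    prom <- genes
    fwd <- genes$strand != "-"
    prom$start <- ifelse(fwd, pmax(0L, genes$start - promoter_width), genes$end)
    prom$end <- ifelse(fwd, genes$start, genes$end + promoter_width)
    prom$type <- "promoter"
    prom$name <- sub("^gene", "promoter", genes$name)
    annotation <- rbind(annotation, prom)
  }
  if (nrow(dmrs) == 0 || nrow(annotation) == 0) {
    return(list(associations = data.frame(dmr = integer(), feature = character(),
                                          type = character()),
                summary = data.frame(type = c("gene", "promoter"),
                                     n_associations = 0L,
                                     n_distinct_features = 0L)))
  }
  gr_d <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  gr_a <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start + 1L, annotation$end))
  hits <- GenomicRanges::findOverlaps(gr_d, gr_a)
  assoc <- data.frame(
    dmr = S4Vectors::queryHits(hits),
    feature = annotation$name[S4Vectors::subjectHits(hits)],
    type = annotation$type[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(c("gene", "promoter"), function(tp) {
    a <- assoc[assoc$type == tp, ]
    data.frame(type = tp, n_associations = nrow(a),
               n_distinct_features = length(unique(a$feature)),
               n_dmrs_hit = length(unique(a$dmr)),
               stringsAsFactors = FALSE)
  }))
  list(associations = assoc, summary = summary)
}
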