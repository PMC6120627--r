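#' Per-cytosine methylation level
#'
#' The percentage of reads that were methylated at a cytosine residue:
#' `100 * n_meth / (n_meth + n_unmeth)`.
#'
#' @param n_meth,n_unmeth Non-negative integer read counts (vectorised).
#' @return Numeric vector of percentages in \[0, 100\].
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  cov <- n_meth + n_unmeth
  if (any(cov == 0))
    stop("methylation level undefined at zero coverage")
  100 * n_meth / cov
}

#' Three-way methylation status call
#'
#' Context-specific thresholds: CpG sites are methylated at a level of 75%
#' or more, CHG and CHH sites at 10% or more; any context below 1% is
#' unmethylated; everything else (tissue-specific, intermediate-level
#' methylation) is `intermediate`. Sites under the coverage floor are
#' `uncovered`.
#'
#' @param level Methylation percentage in \[0, 100\] (may be `NA` when
#'   uncovered).
#' @param context `"CpG"`, `"CHG"` or `"CHH"` (vectorised).
#' @param coverage Read coverage per site.
#' @param min_cov Coverage floor (default 10, the panel-analysis setting;
#'   use 5 for genotype-supporting summaries).
#' @return Character vector: `"methylated"`, `"unmethylated"`,
#'   `"intermediate"` or `"uncovered"`.
#' @export
call_status <- function(level, context, coverage, min_cov = 10) {
  n <- max(length(level), length(context), length(coverage))
  level <- rep_len(level, n)
  context <- rep_len(context, n)
  coverage <- rep_len(coverage, n)
  if (!all(context %in% c("CpG", "CHG", "CHH")))
    stop("unknown context")
  meth_thr <- ifelse(context == "CpG", 75, 10)
  out <- rep("intermediate", n)
  out[level < 1] <- "unmethylated"
  out[level >= meth_thr] <- "methylated"
  out[coverage < min_cov | is.na(level)] <- "uncovered"
  out
}

#' Add level and status columns to a cytosine report
#'
#' @param report Cytosine report data.frame (see [read_cytosine_report()]).
#' @inheritParams call_status
#' @return The report with `coverage`, `level` (NA at zero coverage) and
#'   `status` columns appended.
#' @export
call_sites <- function(report, min_cov = 10) {
  report$coverage <- report$n_meth + report$n_unmeth
  report$level <- ifelse(report$coverage > 0,
                         100 * report$n_meth / report$coverage, NA_real_)
  report$status <- call_status(report$level, report$context,
                               report$coverage, min_cov)
  report
}

#' Bisulfite conversion rate from chloroplast cytosines
#'
#' The chloroplast genome is unmethylated, so every chloroplast cytosine
#' read reporting methylation is a conversion failure. The conversion rate
#' is the pooled percentage of successfully converted (unmethylated-called)
#' reads across all covered chloroplast cytosines.
#'
#' @param chloroplast_sites Cytosine report rows restricted to the
#'   chloroplast.
#' @return Conversion rate as a percentage.
#' @export
conversion_rate <- function(chloroplast_sites) {
  tot <- sum(chloroplast_sites$n_meth) + sum(chloroplast_sites$n_unmeth)
  if (nrow(chloroplast_sites) == 0 || tot == 0)
    stop("no covered chloroplast cytosines")
  100 * sum(chloroplast_sites$n_unmeth) / tot
}
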