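#' Normalise TE-family base-space to a fixed total
#'
#' Cumulative aligned base counts per transposable-element family are
#' scaled so that each accession's total equals `total_target`
#' (50,000,000 bp by default), removing sequencing-depth differences
#' before comparison against the reference accession.
#'
#' @param counts Data.frame with `family`, `class`, `bases` (and
#'   optionally `subclass`).
#' @param total_target Target total base-space (default 5e7).
#' @return `counts` with a `normalized` column; the column sums to
#'   `total_target`.
#' @export
normalize_te <- function(counts, total_target = 5e7) {
  tot <- sum(counts$bases)
  if (any(counts$bases < 0)) stop("negative base counts")
  if (tot <= 0) stop("zero total base-space")
  counts$normalized <- counts$bases * (total_target / tot)
  counts
}

#' Compare a TE profile against the reference accession
#'
#' Per family, the signed difference `accession normalized - reference
#' normalized`: negative means the family shows higher coverage in the
#' reference, positive that the accession has more. Class aggregates
#' (DNA-transposon vs retrotransposon) sum the family differences.
#'
#' @param profile,reference Normalised profiles from [normalize_te()];
#'   families aligned by id (a family missing on one side is treated as 0
#'   with a warning).
#' @return List with `per_family` (family, class, difference) and
#'   `per_class` (class, difference).
#' @export
compare_to_reference <- function(profile, reference) {
  fams <- union(profile$family, reference$family)
  miss <- setdiff(fams, intersect(profile$family, reference$family))
  if (length(miss))
    warning("family missing in one profile treated as 0: ",
            paste(miss, collapse = ", "))
  get <- function(df, col) {
    v <- df[[col]][match(fams, df$family)]
    if (is.numeric(v)) ifelse(is.na(v), 0, v) else v
  }
  cls <- profile$class[match(fams, profile$family)]
  cls[is.na(cls)] <- reference$class[match(fams, reference$family)][is.na(cls)]
  per_family <- data.frame(
    family = fams, class = cls,
    difference = get(profile, "normalized") - get(reference, "normalized"),
    stringsAsFactors = FALSE)
  per_class <- stats::aggregate(difference ~ class, per_family, sum)
  list(per_family = per_family, per_class = per_class)
}

#' TE methylation summary per family and context
#'
#' Pools TE-aligned cytosine read counts per family and context into
#' methylation percentages; families with zero coverage are excluded.
#'
#' @param te_counts Data.frame with `family`, `context`, `n_meth`,
#'   `n_unmeth`.
#' @return Data.frame with `family`, `context`, `coverage`, `level`
#'   (pooled percentage).
#' @export
te_methylation <- function(te_counts) {
  grp <- paste(te_counts$family, te_counts$context, sep = "\r")
  lev <- sort(unique(grp))
  nm <- as.vector(tapply(te_counts$n_meth, grp, sum))
  nu <- as.vector(tapply(te_counts$n_unmeth, grp, sum))
  parts <- strsplit(lev, "\r", fixed = TRUE)
  out <- data.frame(family = vapply(parts, `[`, "", 1),
                    context = vapply(parts, `[`, "", 2),
                    coverage = nm + nu,
                    level = ifelse(nm + nu > 0, 100 * nm / (nm + nu), NA_real_),
                    stringsAsFactors = FALSE)
  excluded <- out$coverage == 0
  if (any(excluded))
    log_info("te_methylation: %d zero-coverage family/context cell(s) excluded",
             sum(excluded))
  out[!excluded, , drop = FALSE]
}
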