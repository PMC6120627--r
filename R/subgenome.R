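#' Homoeolog coordinate map
#'
#' A one-to-one, indel-aware position translation between the A, B and D
#' subgenomes (and, internally, the chloroplast-free anchor frame). The A
#' subgenome is the anchor frame: maps are built A-B and A-D, and B-D
#' translation composes through the shared alignment. Internally the object
#' stores, for every ordered subgenome pair, an integer vector mapping each
#' source position to its target position (`NA` outside aligned blocks), so
#' translation is bijective wherever it is defined.
#'
#' @param pairs Named list of integer vectors; element `"AB"` maps every A
#'   position to its B position or `NA`, and so on for all six ordered
#'   pairs.
#' @param lengths Named integer vector of subgenome lengths.
#' @return A `homoeolog_map` object.
#' @export
homoeolog_map <- function(pairs, lengths) {
  stopifnot(is.list(pairs), !is.null(names(pairs)))
  for (nm in names(pairs)) {
    v <- pairs[[nm]]
    ok <- !is.na(v)
    if (anyDuplicated(v[ok]))
      stop("map is not one-to-one for pair ", nm)
  }
  structure(list(pairs = pairs, lengths = lengths), class = "homoeolog_map")
}

#' Build a homoeolog map from per-subgenome ancestor alignments
#'
#' @param anc2sub Named list (`A`, `B`, `D`) of integer vectors mapping each
#'   ancestor position to the subgenome position (`NA` where deleted).
#' @param lengths Named integer vector of subgenome lengths.
#' @return A `homoeolog_map`.
#' @export
homoeolog_map_from_ancestor <- function(anc2sub, lengths) {
  subs <- names(anc2sub)
  sub2anc <- lapply(subs, function(s) {
    v <- rep(NA_integer_, lengths[[s]])
    ok <- !is.na(anc2sub[[s]])
    v[anc2sub[[s]][ok]] <- which(ok)
    v
  })
  names(sub2anc) <- subs
  pairs <- list()
  for (s in subs) for (t in subs) if (s != t)
    pairs[[paste0(s, t)]] <- anc2sub[[t]][sub2anc[[s]]]
  homoeolog_map(pairs, lengths)
}

#' Translate a position between subgenomes
#'
#' @param map A `homoeolog_map`.
#' @param from,to Subgenome labels (e.g. `"A"`, `"B"`).
#' @param pos Integer vector of 1-based positions in `from`.
#' @return Integer vector of positions in `to`; `NA` outside aligned
#'   blocks.
#' @export
translate <- function(map, from, to, pos) {
  stopifnot(inherits(map, "homoeolog_map"))
  key <- paste0(from, to)
  if (!key %in% names(map$pairs))
    stop("unknown subgenome pair ", from, " -> ", to)
  if (any(pos < 1 | pos > map$lengths[[from]], na.rm = TRUE))
    stop("position outside reference length for subgenome ", from)
  map$pairs[[key]][pos]
}

#' Classify homoeologous cytosine triples as uni/bi/tri-genome methylated
#'
#' For each homoeologous site triple, pairwise two-sided Fisher exact tests
#' on (methylated, unmethylated) read counts discriminate significant
#' differences (q below `q_max` after Benjamini-Hochberg correction across
#' all pairwise tests in the batch, and a methylation difference of at
#' least `min_diff` percentage points). Per-genome methylation status uses
#' the standard context thresholds. The class is:
#' \itemize{
#'   \item `tri` - methylated in all three subgenomes;
#'   \item `uni` - methylated in exactly one, with both contrasts against
#'     the other two significant;
#'   \item `bi` - methylated in exactly two, with both contrasts against
#'     the third significant;
#'   \item `unclassified` - anything else (including inconsistent
#'     contrasts, which are never forced into a class).
#' }
#' Sites with coverage below `min_cov` in any subgenome are skipped
#' (class `NA`) with the reason recorded.
#'
#' @param sites Data.frame with columns `a_meth`, `a_unmeth`, `b_meth`,
#'   `b_unmeth`, `d_meth`, `d_unmeth` and `context`.
#' @param q_max Significance ceiling on the BH q-value (default 0.01).
#' @param min_diff Minimum methylation difference in percentage points
#'   (default 50).
#' @param min_cov Minimum per-genome coverage (default 10).
#' @return `sites` with appended columns `class`, `meth_genomes`
#'   (comma-separated labels), `q_ab`, `q_ad`, `q_bd`, `skip_reason`.
#' @export
classify_sites <- function(sites, q_max = 0.01, min_diff = 50, min_cov = 10) {
  n <- nrow(sites)
  cov <- cbind(sites$a_meth + sites$a_unmeth,
               sites$b_meth + sites$b_unmeth,
               sites$d_meth + sites$d_unmeth)
  covered <- rowSums(cov >= min_cov) == 3
  lev <- cbind(A = 100 * sites$a_meth / pmax(cov[, 1], 1),
               B = 100 * sites$b_meth / pmax(cov[, 2], 1),
               D = 100 * sites$d_meth / pmax(cov[, 3], 1))
  idx <- which(covered)
  p_ab <- p_ad <- p_bd <- rep(NA_real_, n)
  if (length(idx)) {
    p_ab[idx] <- fisher_p(sites$a_meth[idx], sites$a_unmeth[idx],
                          sites$b_meth[idx], sites$b_unmeth[idx])
    p_ad[idx] <- fisher_p(sites$a_meth[idx], sites$a_unmeth[idx],
                          sites$d_meth[idx], sites$d_unmeth[idx])
    p_bd[idx] <- fisher_p(sites$b_meth[idx], sites$b_unmeth[idx],
                          sites$d_meth[idx], sites$d_unmeth[idx])
  }
  q_all <- rep(NA_real_, 3 * n)
  have <- !is.na(c(p_ab, p_ad, p_bd))
  q_all[have] <- bh_adjust(c(p_ab, p_ad, p_bd)[have])
  q_ab <- q_all[seq_len(n)]
  q_ad <- q_all[n + seq_len(n)]
  q_bd <- q_all[2 * n + seq_len(n)]
  sig <- function(q, la, lb) !is.na(q) & q < q_max & abs(la - lb) >= min_diff
  s_ab <- sig(q_ab, lev[, 1], lev[, 2])
  s_ad <- sig(q_ad, lev[, 1], lev[, 3])
  s_bd <- sig(q_bd, lev[, 2], lev[, 3])
  status <- matrix("", n, 3)
  for (j in 1:3)
    status[, j] <- call_status(lev[, j], sites$context, cov[, j], min_cov)
  meth <- status == "methylated"
  nmeth <- rowSums(meth)
  cls <- rep("unclassified", n)
  cls[nmeth == 3] <- "tri"
  # uni: the lone methylated genome must differ significantly from both others
  uni_ok <- nmeth == 1 &
    ((meth[, 1] & s_ab & s_ad) |
     (meth[, 2] & s_ab & s_bd) |
     (meth[, 3] & s_ad & s_bd))
  cls[uni_ok] <- "uni"
  # bi: both methylated genomes must differ significantly from the third
  bi_ok <- nmeth == 2 &
    ((!meth[, 1] & s_ab & s_ad) |
     (!meth[, 2] & s_ab & s_bd) |
     (!meth[, 3] & s_ad & s_bd))
  cls[bi_ok] <- "bi"
  cls[!covered] <- NA_character_
  genomes <- c("A", "B", "D")
  sites$class <- cls
  sites$meth_genomes <- apply(meth, 1, function(z)
    paste(genomes[z], collapse = ","))
  sites$p_ab <- p_ab; sites$p_ad <- p_ad; sites$p_bd <- p_bd
  sites$q_ab <- q_ab; sites$q_ad <- q_ad; sites$q_bd <- q_bd
  sites$skip_reason <- ifelse(covered, NA_character_, "coverage")
  n_skip <- sum(!covered)
  if (n_skip) log_info("classify_sites: %d site(s) skipped for coverage", n_skip)
  sites
}

#' Homoeologous SNP context at uni-genome methylated sites
#'
#' For each uni-genome methylated site, compares the cytosine context class
#' at the three homoeologous positions. A site is flagged when the
#' methylated genome's context class differs from both other subgenomes
#' (including the case where the homoeologous base is not a cytosine at
#' all); the sub-flag records the typical pattern in which the
#' differentiating SNP infers a CpG site from a non-CpG site.
#'
#' @param uni_sites Data.frame with columns `genome` (label of the site's
#'   frame), `pos`, `strand`, `meth_genome` (the methylated subgenome).
#' @param sequences Named [Biostrings::DNAStringSet] with the three
#'   subgenome sequences (`chrA`, `chrB`, `chrD` or `A`, `B`, `D`).
#' @param map A `homoeolog_map`.
#' @return `uni_sites` with appended logical columns `translatable`,
#'   `snp_differentiates`, `cpg_from_non_cpg` and character columns
#'   `ctx_A`, `ctx_B`, `ctx_D`.
#' @export
homoeolog_snp_context <- function(uni_sites, sequences, map) {
  seqs <- as.character(sequences)
  names(seqs) <- sub("^chr", "", names(seqs))
  chars <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
  genomes <- c("A", "B", "D")
  n <- nrow(uni_sites)
  ctx <- matrix(NA_character_, n, 3, dimnames = list(NULL, genomes))
  translatable <- rep(TRUE, n)
  for (g in genomes) {
    pos_g <- ifelse(uni_sites$genome == g, uni_sites$pos,
                    translate(map, uni_sites$genome[1], g, uni_sites$pos))
    # translate() is vectorised but frames can be mixed; redo mixed rows
    mixed <- uni_sites$genome != uni_sites$genome[1] & uni_sites$genome != g
    if (any(mixed))
      pos_g[mixed] <- mapply(function(fr, p) translate(map, fr, g, p),
                             uni_sites$genome[mixed], uni_sites$pos[mixed])
    translatable <- translatable & !is.na(pos_g)
    ok <- which(!is.na(pos_g))
    ctx[ok, g] <- vapply(ok, function(i) {
      context_class(chars[[g]], pos_g[i], uni_sites$strand[i])
    }, "")
  }
  mg <- match(uni_sites$meth_genome, genomes)
  others <- lapply(seq_len(n), function(i) setdiff(1:3, mg[i]))
  ctx_m <- ctx[cbind(seq_len(n), mg)]
  ctx_o1 <- ctx[cbind(seq_len(n), vapply(others, `[`, 0L, 1))]
  ctx_o2 <- ctx[cbind(seq_len(n), vapply(others, `[`, 0L, 2))]
  flagged <- translatable & ctx_m != ctx_o1 & ctx_m != ctx_o2
  uni_sites$translatable <- translatable
  uni_sites$snp_differentiates <- ifelse(translatable, flagged, NA)
  uni_sites$cpg_from_non_cpg <- ifelse(
    translatable, flagged & ctx_m == "CpG" & ctx_o1 != "CpG" & ctx_o2 != "CpG",
    NA)
  uni_sites$ctx_A <- ctx[, "A"]; uni_sites$ctx_B <- ctx[, "B"]
  uni_sites$ctx_D <- ctx[, "D"]
  n_skip <- sum(!translatable)
  if (n_skip) log_info("homoeolog_snp_context: %d untranslatable site(s) skipped",
                       n_skip)
  uni_sites
}

# Context class including "none" when the base at pos/strand is not a
# cytosine (or lookahead is incomplete).
context_class <- function(b, pos, strand) {
  ctx <- context_of(b, pos, strand)
  if (is.na(ctx)) "none" else ctx
}

#' Conservation of uni/bi/tri-genome methylation across a panel
#'
#' A site is assigned to a stratum (`tri`, `bi`, `uni`) when at least one
#' accession carries that class there; its conservation value in the
#' stratum is the fraction of accessions with that class. Strata are
#' contrasted by Welch two-sample t-tests (tri vs uni, tri vs bi).
#'
#' @param class_matrix Character matrix, sites x accessions, of per-site
#'   classes (`tri`/`bi`/`uni`/`unclassified`, `NA` allowed).
#' @return List with per-stratum conservation vectors, medians, quantiles,
#'   and the Welch t statistics/p-values for tri vs uni and tri vs bi.
#' @export
class_conservation <- function(class_matrix) {
  n_acc <- ncol(class_matrix)
  strata <- c("tri", "bi", "uni")
  values <- lapply(strata, function(s) {
    in_stratum <- rowSums(class_matrix == s, na.rm = TRUE) > 0
    if (!any(in_stratum)) stop("empty stratum: ", s)
    100 * rowSums(class_matrix[in_stratum, , drop = FALSE] == s,
                  na.rm = TRUE) / n_acc
  })
  names(values) <- strata
  welch <- function(x, y) {
    sdx <- if (length(x) > 1) stats::sd(x) else 0
    sdy <- if (length(y) > 1) stats::sd(y) else 0
    if (sdx == 0 && sdy == 0) {
      if (mean(x) == mean(y)) return(list(statistic = 0, p.value = 1))
      return(list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0))
    }
    if (length(x) < 2 || length(y) < 2)
      return(list(statistic = NA_real_, p.value = NA_real_))
    tt <- stats::t.test(x, y)
    list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  list(values = values,
       medians = vapply(values, stats::median, 0),
       quantiles = lapply(values, stats::quantile,
                          probs = c(0.05, 0.25, 0.5, 0.75, 0.95)),
       t_tri_vs_uni = welch(values$tri, values$uni),
       t_tri_vs_bi = welch(values$tri, values$bi))
}
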