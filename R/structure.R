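#' Euclidean distance matrix over accession feature profiles
#'
#' @param m Numeric matrix, accessions x features (SMP epiallele codes
#'   \{0, 50, 100\} or SNP alternate-allele frequencies); no missing
#'   values.
#' @return A [stats::dist] object.
#' @export
distance_matrix <- function(m) {
  if (any(is.na(m)))
    stop("missing values in feature matrix; filter sites before clustering")
  stats::dist(m, method = "euclidean")
}

#' Complete-linkage hierarchical clustering and tree cutting
#'
#' @param d A [stats::dist] object.
#' @param method Agglomeration method (default `"complete"`).
#' @return `hcluster`: an [stats::hclust] tree.
#' @export
hcluster <- function(d, method = "complete") {
  stats::hclust(d, method = method)
}

#' @rdname hcluster
#' @param tree An [stats::hclust] tree.
#' @param k Number of groups; must not exceed the number of leaves.
#' @return `cut_tree`: integer cluster labels named by leaf.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k > n) stop("k exceeds the number of accessions")
  stats::cutree(tree, k = k)
}

#' Approximately unbiased (AU) cluster support by multiscale bootstrap
#'
#' Reimplements the multiscale bootstrap: sites (columns) are resampled at
#' scales r x p for r in `scales`, trees are rebuilt, and each original
#' clade's bootstrap proportion BP(r) is recorded. Per clade, the
#' z-regression `qnorm(1 - BP) = v * sqrt(r) + c / sqrt(r)` is fitted by
#' weighted least squares and AU = 1 - pnorm(v - c) (the plain corrected
#' BP is 1 - pnorm(v + c)). Clades recovered in (almost) every replicate
#' at every scale get AU 1; never-recovered clades get AU 0.
#'
#' @param m Numeric matrix, accessions x sites (>= 3 accessions).
#' @param n_boot Total bootstrap replicates across scales (default 10000,
#'   the customary minimum).
#' @param scales Relative resampling sizes (default 0.5 to 1.4 by 0.1).
#' @param method Linkage method (default `"complete"`).
#' @param seed Optional integer seed.
#' @return List with `tree` (the full-data [stats::hclust]) and `support`:
#'   one row per internal node with `bp` (proportion at the scale nearest
#'   1) and `au`.
#' @export
au_support <- function(m, n_boot = 10000, scales = seq(0.5, 1.4, by = 0.1),
                       method = "complete", seed = NULL) {
  if (nrow(m) < 3) stop("need at least 3 accessions")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(m)
  tree <- hcluster(distance_matrix(m), method = method)
  clades <- tree_clades(tree)
  B <- ceiling(n_boot / length(scales))
  bp <- matrix(0, length(clades), length(scales))
  for (si in seq_along(scales)) {
    psz <- max(2L, round(scales[si] * p))
    for (b in seq_len(B)) {
      cols <- sample.int(p, psz, replace = TRUE)
      bt <- hcluster(distance_matrix(m[, cols, drop = FALSE]), method = method)
      bset <- clade_keys(bt)
      bp[, si] <- bp[, si] + (names(clades) %in% bset)
    }
  }
  bp <- bp / B
  near1 <- which.min(abs(scales - 1))
  au <- vapply(seq_along(clades), function(i) {
    b <- bp[i, ]
    usable <- b > 0 & b < 1
    if (sum(usable) < 2) return(if (mean(b) >= 0.5) 1 else 0)
    z <- stats::qnorm(1 - b[usable])
    sr <- sqrt(scales[usable])
    w <- B * stats::dnorm(z)^2 / (b[usable] * (1 - b[usable]))
    fit <- stats::lm.wfit(cbind(sr, 1 / sr), z, w)
    v <- fit$coefficients[1]; cc <- fit$coefficients[2]
    min(1, max(0, 1 - stats::pnorm(v - cc)))
  }, 0)
  support <- data.frame(node = seq_along(clades),
                        leaves = names(clades),
                        bp = bp[, near1], au = au,
                        stringsAsFactors = FALSE)
  degenerate <- all(bp[, near1] == 1)
  if (degenerate)
    log_info("au_support: all splits recovered in every replicate")
  list(tree = tree, support = support, degenerate = degenerate)
}

# Leaf sets of each internal node, keyed by sorted leaf labels.
tree_clades <- function(tree) {
  n <- length(tree$order)
  labs <- if (is.null(tree$labels)) as.character(seq_len(n)) else tree$labels
  sets <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[i, ]
    sets[[i]] <- c(if (kids[1] < 0) labs[-kids[1]] else sets[[kids[1]]],
                   if (kids[2] < 0) labs[-kids[2]] else sets[[kids[2]]])
  }
  names(sets) <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
  sets
}

clade_keys <- function(tree) names(tree_clades(tree))

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with a one-sided
#' permutation p-value, `p = (1 + #\{perm r >= observed\}) / (n_perm + 1)`,
#' computed through [vegan::mantel()].
#'
#' @param d1,d2 [stats::dist] objects over the same accessions in the same
#'   order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return List with `r` (Mantel statistic) and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices have different sizes")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrix labels do not match")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif)
}

#' Wald-Wolfowitz one-sample runs test
#'
#' For a two-label sequence with `n1` and `n2` occurrences and `R` observed
#' runs, `mu = 2 n1 n2 / (n1 + n2) + 1`,
#' `sigma^2 = 2 n1 n2 (2 n1 n2 - n) / (n^2 (n - 1))`, `Z = (R - mu)/sigma`,
#' with a two-sided normal p-value. Sequence reversal preserves the run
#' count, so Z is invariant under it.
#'
#' @param x Vector (character/factor/logical) with exactly two distinct
#'   values present.
#' @return List with `runs`, `n1`, `n2`, `mu`, `sigma`, `Z`, `p`.
#' @export
runs_test <- function(x) {
  x <- as.character(x)
  tab <- table(x)
  if (length(tab) != 2)
    stop("runs test needs a sequence containing exactly two labels")
  n1 <- unname(tab[1]); n2 <- unname(tab[2])
  n <- n1 + n2
  R <- 1L + sum(x[-1] != x[-length(x)])
  mu <- 2 * n1 * n2 / n + 1
  sigma <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
  Z <- (R - mu) / sigma
  list(runs = R, n1 = n1, n2 = n2, mu = mu, sigma = sigma, Z = Z,
       p = 2 * stats::pnorm(-abs(Z)))
}

#' Geographic concordance of cluster labels
#'
#' Per region of origin, the share of accessions belonging to the region's
#' modal cluster; overall, the fraction of regions whose modal share is at
#' least 0.5 (a "majority" region).
#'
#' @param labels Cluster labels per accession.
#' @param regions Region of origin per accession (same order).
#' @return List with `per_region` data.frame (`region`, `n`,
#'   `modal_share`) and `majority_fraction`.
#' @export
geography_concordance <- function(labels, regions) {
  stopifnot(length(labels) == length(regions))
  per <- do.call(rbind, lapply(split(labels, regions), function(l)
    data.frame(n = length(l), modal_share = max(table(l)) / length(l))))
  per$region <- rownames(per)
  rownames(per) <- NULL
  list(per_region = per[, c("region", "n", "modal_share")],
       majority_fraction = mean(per$modal_share >= 0.5))
}

#' Permutation test for geography-cluster concordance
#'
#' Compares the observed mean modal share against the distribution under
#' random reassignment of cluster labels to accessions.
#'
#' @inheritParams geography_concordance
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return List with `observed` (mean modal share), `p` (one-sided,
#'   `(1 + #\{perm >= obs\}) / (n_perm + 1)`).
#' @export
geography_concordance_test <- function(labels, regions, n_perm = 999,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stat <- function(l) mean(vapply(split(l, regions), function(z)
    max(table(z)) / length(z), 0))
  obs <- stat(labels)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(labels)), 0)
  list(observed = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster labelings; 1 for identical
#' partitions (up to label permutation), ~0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
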