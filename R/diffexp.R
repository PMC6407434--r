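#' Log2 transform with the panel's pseudocount
#'
#' Expression values are transformed as `log2(x + 0.01)`; the 0.01
#' pseudocount prevents log(0) on transcripts absent from a sample.
#'
#' @param m non-negative numeric matrix (transcript x sample).
#' @return matrix of the same shape on the log2 scale.
#' @export
log_transform <- function(m) {
  if (any(m < 0)) stop("expression values must be non-negative")
  log2(m + 0.01)
}

#' UPGMA clustering of samples on Manhattan distances
#'
#' Pairwise Manhattan distances between sample expression profiles
#' (columns), agglomerated with average linkage (UPGMA). The result is an
#' ultrametric tree: merge heights are non-decreasing toward the root.
#'
#' @param m numeric matrix, features x samples, typically log2 mean FPM from
#'   [log_transform]; no missing values.
#' @return an object of class `hclust` over the samples.
#' @export
cluster_samples <- function(m) {
  if (ncol(m) < 2L) stop("clustering needs at least 2 samples")
  if (anyNA(m)) stop("expression matrix contains missing values")
  d <- stats::dist(t(m), method = "manhattan")
  stats::hclust(d, method = "average")
}

#' Cut the sample tree into its two head clusters
#'
#' Splits at the root merge. When tissue labels are supplied, cluster "a" is
#' the side holding the larger share of healthy samples (the convention of a
#' healthy-versus-tumor design); otherwise the side containing the first
#' leaf.
#'
#' @param tree `hclust` from [cluster_samples].
#' @param tissue optional character vector of tissue labels named by sample
#'   id (values "healthy"/"tumor").
#' @return list with character vectors `cluster_a` and `cluster_b` of sample
#'   ids.
#' @export
cut_two <- function(tree, tissue = NULL) {
  k <- stats::cutree(tree, k = 2L)
  g1 <- names(k)[k == 1L]; g2 <- names(k)[k == 2L]
  if (!is.null(tissue)) {
    h1 <- mean(tissue[g1] == "healthy"); h2 <- mean(tissue[g2] == "healthy")
    if (h2 > h1) { tmp <- g1; g1 <- g2; g2 <- tmp }
  } else if (!(tree$labels[1L] %in% g1)) {
    tmp <- g1; g1 <- g2; g2 <- tmp
  }
  list(cluster_a = g1, cluster_b = g2)
}

#' Export a sample tree as Newick
#'
#' Branch lengths derive from the UPGMA merge heights.
#'
#' @param tree `hclust` from [cluster_samples].
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Two-sided Wilcoxon Mann-Whitney U test
#'
#' Exact enumeration when both groups have at most 8 observations and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @return two-sided p-value.
#' @export
wilcoxon_test <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty")
  if (all(values_a == values_a[1L]) && all(values_b == values_b[1L]) &&
      values_a[1L] == values_b[1L])
    return(1)
  exact <- length(values_a) <= 8L && length(values_b) <= 8L &&
    !anyDuplicated(c(values_a, values_b))
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values (FDR), same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Signed fold change between cluster means
#'
#' The ratio `mean_b / mean_a` when it is at least 1, else the negative
#' reciprocal `-mean_a / mean_b`, so magnitudes are always >= 1 and the sign
#' encodes direction (positive: higher in cluster b). A zero mean on one
#' side yields a signed infinity.
#'
#' @param mean_a,mean_b non-negative cluster means (not both zero).
#' @return signed fold change.
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  if (mean_a < 0 || mean_b < 0) stop("means must be non-negative")
  if (mean_a == 0 && mean_b == 0) stop("fold change undefined: both means zero")
  if (mean_a == mean_b) return(1)
  if (mean_a == 0) return(Inf)
  if (mean_b == 0) return(-Inf)
  r <- mean_b / mean_a
  if (r >= 1) r else -1 / r
}

#' Differential expression between the two head clusters
#'
#' Per transcript: cluster mean FPMs (untransformed scale), a two-sided
#' Wilcoxon Mann-Whitney test on the FPM values (rank tests are invariant to
#' the monotone log transform), Benjamini-Hochberg adjustment across all
#' tested transcripts, the signed fold change of the means, and a
#' significance flag requiring both `p < alpha_p` and `fdr < alpha_fdr`.
#' Constant transcripts (identical values in all samples) get p = 1 and fold
#' change 1.
#'
#' @param m transcript x sample matrix of mean FPM (untransformed).
#' @param partition list with `cluster_a`, `cluster_b` sample-id vectors
#'   (from [cut_two]).
#' @param alpha_p raw p-value threshold (default 0.05).
#' @param alpha_fdr FDR threshold (default 0.05).
#' @return data.frame, one row per transcript, sorted by (fdr, p_value):
#'   columns `gene`, `mean_fpm_a`, `mean_fpm_b`, `p_value`, `fdr`,
#'   `fold_change`, `significant`.
#' @export
differential_expression <- function(m, partition, alpha_p = 0.05,
                                    alpha_fdr = 0.05) {
  a <- partition$cluster_a; b <- partition$cluster_b
  if (length(a) == 0L || length(b) == 0L)
    stop("both clusters must be non-empty")
  stopifnot(all(c(a, b) %in% colnames(m)))
  ma <- rowMeans(m[, a, drop = FALSE])
  mb <- rowMeans(m[, b, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(i)
    wilcoxon_test(m[i, a], m[i, b]), 0)
  fdr <- bh_adjust(p)
  fc <- vapply(seq_len(nrow(m)), function(i) {
    if (ma[i] == 0 && mb[i] == 0) 1 else signed_fold_change(ma[i], mb[i])
  }, 0)
  out <- data.frame(gene = rownames(m), mean_fpm_a = as.numeric(ma),
                    mean_fpm_b = as.numeric(mb), p_value = p, fdr = fdr,
                    fold_change = fc,
                    significant = p < alpha_p & fdr < alpha_fdr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
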