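#' @title Methylome PCA and gene--PC association
#' @name pca-assoc
#' @description
#' Principal components of the tumor methylome (whole array or any probe
#' stratum), rank-sum association of driver-gene mutations with PC
#' coordinates, mean-over-feature-list sample indices (mitotic-index
#' style), and the decorrelate-then-reassociate re-analysis that removes
#' probes correlated with such an index before refitting.
NULL

#' Fit PCA on the tumor methylome
#'
#' Tumor samples only are analyzed (normals excluded). Probes are centered
#' but not scaled (beta values share a scale); missing values are imputed
#' per probe — by the probe's tumor mean (default) or by an iterative
#' EM-style PCA refinement (`impute = "em"`) that alternates low-rank
#' reconstruction and re-imputation. Each component's sign is fixed so its
#' largest-magnitude loading is positive, making score signs reproducible.
#'
#' @param beta a [beta_matrix]
#' @param n_components number of PCs (default 5)
#' @param stratum optional character vector of probe ids to restrict to
#' @param impute `"mean"` or `"em"`
#' @param em_iter iterations for the EM mode
#' @return A `pca_result`: list with `scores` (tumors x components),
#'   `loadings` (probes x components, orthonormal), `explained_variance`
#'   (fraction per component), `center`, `probe_ids`, `stratum_label`.
#' @export
fit_methylation_pca <- function(beta, n_components = 5, stratum = NULL,
                                impute = c("mean", "em"), em_iter = 10) {
  impute <- match.arg(impute)
  tum <- tumor_samples(beta)
  v <- beta$values[, tum, drop = FALSE]
  lab <- "all"
  if (!is.null(stratum)) {
    stratum <- intersect(rownames(v), stratum)
    if (length(stratum) == 0) stop("empty probe stratum")
    v <- v[stratum, , drop = FALSE]
    lab <- "stratum"
  }
  if (nrow(v) < n_components)
    stop("stratum smaller than the number of components requested")
  if (length(tum) < n_components + 1)
    stop("need at least n_components + 1 tumor samples")
  # drop probes with no observed values, impute the rest per probe
  obs <- rowSums(!is.na(v)) > 0
  v <- v[obs, , drop = FALSE]
  pm <- rowMeans(v, na.rm = TRUE)
  na_idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(na_idx) > 0) v[na_idx] <- pm[na_idx[, 1]]
  if (impute == "em" && nrow(na_idx) > 0) {
    for (it in seq_len(em_iter)) {
      ctr <- rowMeans(v)
      x <- v - ctr
      sv <- La.svd(x, nu = min(n_components, nrow(x)), nv = min(n_components, ncol(x)))
      recon <- sv$u %*% (sv$d[seq_len(ncol(sv$u))] * sv$vt) + ctr
      v[na_idx] <- recon[na_idx]
    }
  }
  if (all(matrixStats::rowVars(v) == 0))
    stop("zero variance everywhere: PCA undefined")
  x <- t(v - rowMeans(v))                        # samples x probes, centered
  k <- min(n_components, nrow(x) - 1, ncol(x))
  sv <- La.svd(x, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  loadings <- t(sv$vt[seq_len(k), , drop = FALSE])
  scores <- sv$u %*% diag(d, k)
  # sign convention: the largest-|loading| entry of each PC is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(sv$d^2)
  dimnames(scores) <- list(tum, paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(v), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = d^2 / total_var,
                 center = rowMeans(v), probe_ids = rownames(v),
                 n_components = k, stratum_label = lab),
            class = "pca_result")
}

#' Associate driver-gene mutations with PC coordinates
#'
#' For each eligible gene (at least `min_mutated` mutated samples among the
#' scored tumors, and at least one non-mutated) and each PC, the mutated
#' samples' coordinates are compared with the non-mutated samples' by
#' two-sided rank-sum test. BH correction spans all gene x PC tests
#' jointly. Direction records which extreme of the PC the mutated samples
#' occupy (+ / -), as the sign of the median score difference.
#'
#' @param pca a `pca_result`
#' @param mut a [mutation_matrix] sharing samples with the PCA scores
#' @param min_mutated eligibility threshold (default 5)
#' @param alpha significance threshold on q (default 0.05)
#' @return data.frame (gene, pc, p, q, direction, median_diff, n_mutated,
#'   significant), one row per tested pair.
#' @export
associate_genes_with_pcs <- function(pca, mut, min_mutated = 5, alpha = 0.05) {
  samples <- intersect(rownames(pca$scores), colnames(mut$status))
  if (length(samples) == 0) stop("no shared samples between PCA and mutations")
  st <- mut$status[, samples, drop = FALSE]
  nmut <- rowSums(st)
  eligible <- rownames(st)[nmut >= min_mutated & nmut < length(samples)]
  if (length(eligible) == 0) {
    warning("no eligible genes (min_mutated = ", min_mutated, ")")
    return(empty_assoc_table(c("gene", "pc")))
  }
  sc <- pca$scores[samples, , drop = FALSE]
  res <- expand.grid(gene = eligible, pc = colnames(sc),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_list <- mapply(function(g, pc) {
    m <- st[g, ] == 1
    r <- rank_sum_test(sc[m, pc], sc[!m, pc])
    c(r$p_value, r$effect, sum(m))
  }, res$gene, res$pc)
  res$p <- stats_list[1, ]
  res$median_diff <- stats_list[2, ]
  res$n_mutated <- as.integer(stats_list[3, ])
  res$q <- bh_qvalues(res$p)
  res$direction <- sign(res$median_diff)
  res$significant <- res$q < alpha
  res[order(res$q, res$p, res$gene, res$pc), ]
}

empty_assoc_table <- function(keys) {
  out <- as.data.frame(setNames(rep(list(character(0)), length(keys)), keys))
  out$p <- numeric(0); out$q <- numeric(0); out$direction <- numeric(0)
  out$median_diff <- numeric(0); out$n_mutated <- integer(0)
  out$significant <- logical(0)
  out
}

#' Per-sample mean index over a feature list
#'
#' The mitotic-index form: the arithmetic mean of the listed features'
#' values per sample, ignoring missing entries — e.g. the mean beta over a
#' fixed CpG list (DNAm mitotic index) or the mean log2 expression over a
#' mitotic gene list.
#'
#' @param mat a [beta_matrix] or [expression_matrix]
#' @param feature_list feature ids (rows); at least one must be present
#' @param kind free-text label stored with the index
#' @return A `feature_index`: named numeric vector (per sample) with
#'   attributes `features` and `kind`.
#' @export
compute_feature_index <- function(mat, feature_list, kind = "dnam_mitotic") {
  v <- mat$values
  present <- intersect(feature_list, rownames(v))
  if (length(present) == 0) stop("no listed feature present in the matrix")
  idx <- colMeans(v[present, , drop = FALSE], na.rm = TRUE)
  idx[is.nan(idx)] <- NA
  structure(idx, features = present, kind = kind, class = "feature_index")
}

#' Remove index-correlated probes, refit PCA, re-run associations
#'
#' Drops every probe whose Pearson correlation with the index across tumor
#' samples has p < `p_cut`, refits the PCA on the surviving probes, and
#' re-runs the gene--PC association scan — the re-analysis that asks
#' whether mutation--methylation associations persist once
#' proliferation-tracking probes are excluded.
#'
#' @param beta a [beta_matrix]
#' @param mut a [mutation_matrix]
#' @param index a `feature_index` defined on the tumor samples
#' @param p_cut Pearson p-value threshold for probe removal (default 0.05)
#' @param n_components,min_mutated,alpha passed through
#' @return list: `pca` (refit), `associations`, `removed_probes`
#' @export
decorrelate_and_reassociate <- function(beta, mut, index, p_cut = 0.05,
                                        n_components = 5, min_mutated = 5,
                                        alpha = 0.05) {
  tum <- tumor_samples(beta)
  idx <- index[tum]
  if (all(is.na(idx))) stop("index undefined on tumor samples")
  v <- beta$values[, tum, drop = FALSE]
  pvals <- row_cor_pvalues(v, idx)
  removed <- rownames(v)[!is.na(pvals) & pvals < p_cut]
  keep <- setdiff(rownames(v), removed)
  if (length(keep) < n_components)
    stop("all (or nearly all) probes removed by decorrelation")
  pca <- fit_methylation_pca(beta, n_components = n_components, stratum = keep)
  assoc <- associate_genes_with_pcs(pca, mut, min_mutated = min_mutated,
                                    alpha = alpha)
  list(pca = pca, associations = assoc, removed_probes = removed)
}

# vectorized Pearson correlation p-values of matrix rows against a vector
row_cor_pvalues <- function(v, y) {
  ok <- !is.na(y)
  y <- y[ok]; v <- v[, ok, drop = FALSE]
  n_i <- rowSums(!is.na(v))
  vy <- matrix(rep(y, each = nrow(v)), nrow(v))
  vy[is.na(v)] <- NA
  vc <- v - rowMeans(v, na.rm = TRUE)
  yc <- vy - rowMeans(vy, na.rm = TRUE)
  vc[is.na(vc)] <- 0; yc[is.na(yc)] <- 0
  num <- rowSums(vc * yc)
  den <- sqrt(rowSums(vc^2) * rowSums(yc^2))
  r <- ifelse(den > 0, num / den, NA)
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(r))
  ok2 <- !is.na(r) & n_i >= 3
  tstat <- r[ok2] * sqrt((n_i[ok2] - 2) / pmax(1 - r[ok2]^2, 1e-300))
  p[ok2] <- 2 * pt(-abs(tstat), df = n_i[ok2] - 2)
  p
}
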