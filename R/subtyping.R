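#' @title Mutation-anchored methylation subtyping
#' @name subtyping
#' @description
#' Subtype discovery from the methylation footprint of dominant driver
#' genes: take the union of each gene's top-k most significantly
#' associated probes (or, as a variant, the top fraction of most variable
#' probes), hierarchically cluster the tumors on that panel, and cut the
#' tree into subtypes. Recovery is scored against planted truth with the
#' adjusted Rand index.
NULL

#' Union of each gene's top-k associated probes
#'
#' Per gene, the k probes with the smallest p (ties broken by larger
#' |median_diff|, then probe id); the deduplicated union over genes is
#' returned. A gene with fewer than k associated probes contributes all of
#' them, with a warning.
#'
#' @param table a `site_association_table`
#' @param genes genes to draw panels from
#' @param k probes per gene (default 500)
#' @return character vector of probe ids (sorted, unique)
#' @export
select_top_associated_probes <- function(table, genes, k = 500) {
  missing <- setdiff(genes, unique(table$gene))
  if (length(missing) > 0)
    stop("no associations in table for gene(s): ", paste(missing, collapse = ", "))
  panel <- unlist(lapply(genes, function(g) {
    tb <- table[table$gene == g, ]
    tb <- tb[order(tb$p, -abs(tb$median_diff), tb$probe), ]
    if (nrow(tb) < k)
      warning(sprintf("gene %s has only %d associated probes (k = %d)",
                      g, nrow(tb), k))
    head(tb$probe, k)
  }))
  sort(unique(panel))
}

#' Top-variance probe panel
#'
#' Probes ranked by variance across tumor samples; the top
#' `ceiling(fraction * n_probes)` are returned. Ties break by probe id for
#' determinism.
#'
#' @param beta a [beta_matrix] with >= 2 tumor samples
#' @param fraction fraction of probes to keep (default 0.01)
#' @return character vector of probe ids
#' @export
select_top_variance_probes <- function(beta, fraction = 0.01) {
  tum <- tumor_samples(beta)
  if (length(tum) < 2) stop("need >= 2 tumor samples for variances")
  v <- beta$values[, tum, drop = FALSE]
  vars <- matrixStats::rowVars(v, na.rm = TRUE)
  names(vars) <- rownames(v)
  n_keep <- ceiling(fraction * length(vars))
  ord <- order(-vars, names(vars))
  sort(names(vars)[ord[seq_len(n_keep)]])
}

#' Hierarchically cluster tumors on a probe panel
#'
#' Agglomerative clustering of the tumor samples restricted to the panel:
#' Euclidean distance with Ward linkage by default, or one minus Pearson
#' correlation with average linkage. Missing betas are mean-imputed per
#' probe before distances. The tree is cut at `k_clusters`.
#'
#' @param beta a [beta_matrix]
#' @param probes panel probe ids (must exist in the matrix)
#' @param k_clusters number of subtypes (default 2)
#' @param method `"ward_euclidean"` (default) or `"average_pearson"`
#' @return A `subtype_assignment`: list with `labels` (named integer
#'   vector per tumor), `tree` (hclust), `probe_panel`, `method`, `k`.
#' @export
cluster_samples <- function(beta, probes, k_clusters = 2,
                            method = c("ward_euclidean", "average_pearson")) {
  method <- match.arg(method)
  missing <- setdiff(probes, rownames(beta$values))
  if (length(missing) > 0) stop("panel probe not in matrix: ", missing[1])
  tum <- tumor_samples(beta)
  if (k_clusters > length(tum)) stop("more clusters than samples")
  v <- beta$values[probes, tum, drop = FALSE]
  pm <- rowMeans(v, na.rm = TRUE)
  na_idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(na_idx) > 0) v[na_idx] <- pm[na_idx[, 1]]
  if (method == "ward_euclidean") {
    d <- dist(t(v))
    tree <- hclust(d, method = "ward.D2")
  } else {
    cc <- suppressWarnings(cor(v))
    cc[is.na(cc)] <- 0
    tree <- hclust(as.dist(1 - cc), method = "average")
  }
  labels <- cutree(tree, k = k_clusters)
  structure(list(labels = labels, tree = tree, probe_panel = probes,
                 method = method, k = k_clusters),
            class = "subtype_assignment")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples
#' (1 = identical partitions, ~0 = chance).
#'
#' @param a,b label vectors of equal length (any label type)
#' @return numeric ARI
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
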