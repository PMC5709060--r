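#' @title Driver-gene by probe association scan
#' @name site-assoc
#' @description
#' The exhaustive scan: every eligible driver gene against every probe by
#' two-sided rank-sum test on tumor beta values, with a single BH family
#' spanning all gene x probe tests in the cohort. Companions: a
#' permutation-based empirical FDR estimate (shuffling each gene's
#' mutation labels), per-gene dominance summaries, cross-cohort probe
#' sharing, and single-gene re-correction with a BH family restricted to
#' one gene's tests.
NULL

scan_groups <- function(beta, mut, min_mutated) {
  tum <- intersect(tumor_samples(beta), colnames(mut$status))
  if (length(tum) == 0) stop("no shared tumor samples")
  st <- mut$status[, tum, drop = FALSE]
  nmut <- rowSums(st)
  eligible <- rownames(st)[nmut >= min_mutated & nmut < length(tum)]
  if (length(eligible) == 0) stop("no eligible genes for the scan")
  list(tum = tum, groups = t(st[eligible, , drop = FALSE]))
}

#' Gene-by-probe association scan
#'
#' For every eligible gene (>= `min_mutated` mutated tumors, >= 1
#' non-mutated) and every probe, tumors are compared between the mutated
#' and non-mutated cohorts on their beta values (two-sided rank-sum,
#' normal approximation with tie and continuity correction). q-values come
#' from one BH family over all gene x probe tests jointly. Records passing
#' `alpha` are returned with direction (+ = higher methylation in mutated
#' samples) and median beta difference.
#'
#' @param beta a [beta_matrix]
#' @param mut a [mutation_matrix]
#' @param ann optional [probe_annotation] to attach `cpg_subset`
#' @param min_mutated gene eligibility threshold (default 5)
#' @param alpha q threshold (default 0.05)
#' @param keep_all return all records, not only the significant ones
#' @return A `site_association_table`: data.frame (gene, probe, p, q,
#'   direction, median_diff, cpg_subset) with attributes `n_tests`,
#'   `tested_genes`, `n_probes`, `alpha`.
#' @export
associate_genes_with_probes <- function(beta, mut, ann = NULL, min_mutated = 5,
                                        alpha = 0.05, keep_all = FALSE) {
  sg <- scan_groups(beta, mut, min_mutated)
  v <- beta$values[, sg$tum, drop = FALSE]
  sc <- rank_sum_scan(v, sg$groups)
  p <- sc$p
  q <- matrix(bh_qvalues(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  keep <- if (keep_all) !is.na(q) else (!is.na(q) & q < alpha)
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(gene = colnames(p)[idx[, 2]],
                    probe = rownames(p)[idx[, 1]],
                    p = p[keep], q = q[keep],
                    direction = sc$direction[keep],
                    median_diff = sc$median_diff[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(ann))
    out$cpg_subset <- ann$cpg_subset[match(out$probe, ann$probe_id)]
  out <- out[order(out$q, out$p, out$gene, out$probe), ]
  rownames(out) <- NULL
  attr(out, "n_tests") <- sum(!is.na(p))
  attr(out, "tested_genes") <- colnames(p)
  attr(out, "n_probes") <- nrow(p)
  attr(out, "alpha") <- alpha
  class(out) <- c("site_association_table", "data.frame")
  out
}

#' Permutation-based empirical FDR of the scan
#'
#' Each permutation independently shuffles every gene's mutation labels
#' across tumors (preserving per-gene mutation counts, breaking any
#' gene--probe linkage; `mode = "joint"` instead permutes whole sample
#' columns, preserving co-mutation structure), re-runs the full scan with
#' its own BH correction, and counts q < `alpha` discoveries. The estimate
#' is mean null discoveries / max(observed discoveries, 1), capped at 1.
#'
#' @param beta,mut,min_mutated,alpha as [associate_genes_with_probes]
#' @param n_permutations number of full-scan permutations (default 10)
#' @param seed integer seed for the permutation stream
#' @param mode `"per_gene"` (default) or `"joint"`
#' @return list: `nominal_q`, `n_observed`, `mean_null_discoveries`,
#'   `empirical_fdr`, `n_permutations`, `null_counts`
#' @export
estimate_empirical_fdr <- function(beta, mut, min_mutated = 5, alpha = 0.05,
                                   n_permutations = 10, seed = 1,
                                   mode = c("per_gene", "joint")) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  obs <- associate_genes_with_probes(beta, mut, min_mutated = min_mutated,
                                     alpha = alpha)
  n_obs <- nrow(obs)
  sg <- scan_groups(beta, mut, min_mutated)
  v <- beta$values[, sg$tum, drop = FALSE]
  set.seed(as.integer(seed))
  null_counts <- integer(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sg$groups
    if (mode == "per_gene") {
      for (g in seq_len(ncol(perm))) perm[, g] <- sample(perm[, g])
    } else {
      perm <- perm[sample(nrow(perm)), , drop = FALSE]
    }
    sc <- rank_sum_scan(v, perm)
    qb <- bh_qvalues(as.vector(sc$p))
    null_counts[b] <- sum(qb < alpha, na.rm = TRUE)
  }
  list(nominal_q = alpha, n_observed = n_obs,
       mean_null_discoveries = mean(null_counts),
       empirical_fdr = min(1, mean(null_counts) / max(n_obs, 1)),
       n_permutations = n_permutations, null_counts = null_counts)
}

#' Per-gene dominance summary of a scan
#'
#' Counts each gene's associated probes, its fraction of all probes
#' associated with any gene (the dominance measure; genes above
#' `dominance_cut` are flagged dominant), splits by direction x CpG
#' subset, and — when an aberrant-call table is supplied — the joint
#' (direction, aberrant-call) counts such as positively-associated
#' hypermethylated probes.
#'
#' @param table a `site_association_table` (significant records)
#' @param aberrant optional `aberrant_call_table`
#' @param dominance_cut dominance threshold as a fraction of all
#'   associated probes (default 0.1)
#' @return data.frame, one row per gene, ordered by `n_assoc` descending;
#'   attribute `n_total_probes` = number of unique probes associated with
#'   any gene.
#' @export
summarize_dominance <- function(table, aberrant = NULL, dominance_cut = 0.1) {
  if (nrow(table) == 0) stop("empty association table")
  total <- length(unique(table$probe))
  if (!is.null(aberrant))
    table$call <- aberrant$call[match(table$probe, aberrant$probe_id)]
  rows <- lapply(split(table, table$gene), function(tb) {
    out <- data.frame(gene = tb$gene[1], n_assoc = nrow(tb),
                      frac_of_total = nrow(tb) / total,
                      stringsAsFactors = FALSE)
    for (s in CPG_SUBSETS) {
      if (!is.null(tb$cpg_subset)) {
        out[[paste0("pos_", s)]] <- sum(tb$direction > 0 & tb$cpg_subset == s)
        out[[paste0("neg_", s)]] <- sum(tb$direction < 0 & tb$cpg_subset == s)
      }
    }
    if (!is.null(aberrant)) {
      out$pos_hyper <- sum(tb$direction > 0 & !is.na(tb$call) & tb$call == "hyper")
      out$neg_hypo <- sum(tb$direction < 0 & !is.na(tb$call) & tb$call == "hypo")
    }
    out
  })
  res <- do.call(rbind, rows)
  res$dominant <- res$frac_of_total > dominance_cut
  res <- res[order(-res$n_assoc, res$gene), ]
  rownames(res) <- NULL
  attr(res, "n_total_probes") <- total
  res
}

#' Cross-cohort sharing of a gene's associated probes
#'
#' For a gene and direction, counts how many probes are associated in at
#' least k of the supplied cohort tables, for k = 1..K.
#'
#' @param tables list of `site_association_table`s (one per cohort)
#' @param gene gene id
#' @param direction `+1` or `-1`
#' @return named integer vector: element `">=k"` is the number of probes
#'   associated (with that direction) in at least k cohorts; empty when
#'   the gene appears in no table.
#' @export
count_shared_probes <- function(tables, gene, direction) {
  if (length(tables) < 2) stop("need at least 2 cohort tables")
  per <- lapply(tables, function(tb)
    unique(tb$probe[tb$gene == gene & tb$direction == direction]))
  if (all(lengths(per) == 0)) return(setNames(integer(0), character(0)))
  counts <- table(unlist(per))
  k <- seq_along(tables)
  setNames(vapply(k, function(kk) sum(counts >= kk), integer(1)),
           paste0(">=", k))
}

#' Re-correct a single gene's probe associations
#'
#' Identical to the scan restricted to one gene, with the BH family
#' spanning only that gene's probe tests — the per-gene re-correction used
#' when focusing on a single driver's methylation footprint. Its q-values
#' are never larger than the joint scan's for the same records.
#'
#' @param beta,mut,ann,alpha,keep_all as [associate_genes_with_probes]
#' @param gene the gene to test (must be eligible)
#' @param min_mutated eligibility threshold (default 5)
#' @return A `site_association_table` for that gene.
#' @export
reassociate_single_gene <- function(beta, mut, gene, ann = NULL,
                                    min_mutated = 5, alpha = 0.05,
                                    keep_all = FALSE) {
  if (!gene %in% rownames(mut$status)) stop("unknown gene: ", gene)
  sub <- mutation_matrix(mut$status[gene, , drop = FALSE])
  nm <- sum(sub$status)
  if (nm < min_mutated || nm == ncol(sub$status))
    stop("gene not eligible: ", gene, " (", nm, " mutated samples)")
  associate_genes_with_probes(beta, sub, ann = ann, min_mutated = min_mutated,
                              alpha = alpha, keep_all = keep_all)
}
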