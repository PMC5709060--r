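#' @title Genome-wide methylation-alteration indices (HyperZ / HypoZ)
#' @name genome-indices
#' @description
#' Per-tumor-sample summaries of genome-wide aberrant methylation relative
#' to matched normals: HyperZ measures how widely normally-unmethylated
#' CGI probes are hypermethylated (CIMP-like behavior), HypoZ how widely
#' normally-methylated open-sea probes are hypomethylated. Each index is
#' the fraction of eligible probes whose z-score against the normal
#' distribution exceeds a cutoff, so both live in \[0,1\].
NULL

#' Compute per-sample HyperZ and HypoZ indices
#'
#' Probe eligibility restricts each index to probes where aberration is
#' detectable: hyper-eligible probes are CGI probes unmethylated in
#' normals (normal mean below `unmeth_cut`); hypo-eligible probes are
#' open-sea probes methylated in normals (normal mean above `meth_cut`).
#' With z standardized by the normal-sample mean and (floored) SD,
#' HyperZ of a tumor sample is the fraction of hyper-eligible probes with
#' z > `z_cut`, HypoZ the fraction of hypo-eligible probes with
#' z < -`z_cut`.
#'
#' @param beta a [beta_matrix] with at least 2 normal samples
#' @param ann a [probe_annotation]
#' @param z_cut z-score cutoff (default 2)
#' @param unmeth_cut,meth_cut normal-mean eligibility cutoffs (0.3 / 0.7)
#' @param sigma_floor lower bound on the normal SD (default 0.01)
#' @return A `sample_index_table`: data.frame (sample, hyperz, hypoz) with
#'   attributes `eligible_cgi_count`, `eligible_opensea_count`, and
#'   `params`. Indices are NA when no probe is eligible. With fewer than 2
#'   normals the table is returned with `computable = FALSE` and all NA.
#' @export
compute_hyperz_hypoz <- function(beta, ann, z_cut = 2.0, unmeth_cut = 0.3,
                                 meth_cut = 0.7, sigma_floor = 0.01) {
  tum <- tumor_samples(beta); nor <- normal_samples(beta)
  out <- data.frame(sample = tum, hyperz = NA_real_, hypoz = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(nor) < 2) {
    attr(out, "computable") <- FALSE
    attr(out, "eligible_cgi_count") <- NA_integer_
    attr(out, "eligible_opensea_count") <- NA_integer_
    class(out) <- c("sample_index_table", "data.frame")
    return(out)
  }
  probes <- rownames(beta$values)
  ann <- ann[match(probes, ann$probe_id), ]
  nv <- beta$values[, nor, drop = FALSE]
  mu <- rowMeans(nv, na.rm = TRUE)
  sg <- pmax(matrixStats::rowSds(nv, na.rm = TRUE), sigma_floor)
  hyper_elig <- !is.na(mu) & ann$cpg_subset == "CGI" & mu < unmeth_cut
  hypo_elig <- !is.na(mu) & ann$cpg_subset == "open_sea" & mu > meth_cut
  tv <- beta$values[, tum, drop = FALSE]
  z <- (tv - mu) / sg
  if (any(hyper_elig))
    out$hyperz <- colMeans(z[hyper_elig, , drop = FALSE] > z_cut, na.rm = TRUE)
  if (any(hypo_elig))
    out$hypoz <- colMeans(z[hypo_elig, , drop = FALSE] < -z_cut, na.rm = TRUE)
  out$hyperz[is.nan(out$hyperz)] <- NA
  out$hypoz[is.nan(out$hypoz)] <- NA
  attr(out, "computable") <- TRUE
  attr(out, "eligible_cgi_count") <- sum(hyper_elig)
  attr(out, "eligible_opensea_count") <- sum(hypo_elig)
  attr(out, "params") <- list(z_cut = z_cut, unmeth_cut = unmeth_cut,
                              meth_cut = meth_cut, sigma_floor = sigma_floor)
  class(out) <- c("sample_index_table", "data.frame")
  out
}

#' Associate driver-gene mutations with HyperZ or HypoZ
#'
#' Two-sided rank-sum comparison of the chosen index between mutated and
#' non-mutated tumors per eligible gene, BH-corrected across genes.
#' Direction +1 means the index is higher in mutated samples. Genes
#' mutated in every sample (or none) are skipped with a warning.
#'
#' @param idx a `sample_index_table` (computable)
#' @param mut a [mutation_matrix]
#' @param which `"hyperz"` or `"hypoz"`
#' @param min_mutated eligibility threshold (default 5)
#' @param alpha q threshold (default 0.05)
#' @return data.frame (gene, p, q, direction, median_diff, n_mutated,
#'   significant)
#' @export
associate_genes_with_index <- function(idx, mut, which = c("hyperz", "hypoz"),
                                       min_mutated = 5, alpha = 0.05) {
  which <- match.arg(which)
  if (!isTRUE(attr(idx, "computable")) || all(is.na(idx[[which]])))
    stop("index not computable (insufficient normals or no eligible probes)")
  vals <- setNames(idx[[which]], idx$sample)
  samples <- intersect(names(vals)[!is.na(vals)], colnames(mut$status))
  st <- mut$status[, samples, drop = FALSE]
  nmut <- rowSums(st)
  skip <- rownames(st)[nmut == length(samples)]
  if (length(skip) > 0)
    warning("gene(s) mutated in all samples skipped: ",
            paste(skip, collapse = ", "))
  eligible <- rownames(st)[nmut >= min_mutated & nmut < length(samples)]
  if (length(eligible) == 0) {
    warning("no eligible genes")
    return(empty_assoc_table("gene"))
  }
  rows <- lapply(eligible, function(g) {
    m <- st[g, ] == 1
    r <- rank_sum_test(vals[samples][m], vals[samples][!m])
    data.frame(gene = g, p = r$p_value, median_diff = r$effect,
               n_mutated = sum(m), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_qvalues(res$p)
  res$direction <- sign(res$median_diff)
  res$significant <- res$q < alpha
  res[order(res$q, res$p, res$gene), ]
}
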