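#' @title Probe filtering and hyper/hypomethylation calling
#' @name preprocess
#' @description
#' Mirrors the standard 450K exclusion rules — sex-chromosome probes,
#' cross-reactive probes, SNP-adjacent probes (all injected via annotation
#' flags), and probes missing in at least 90% of samples — followed by
#' per-probe hyper/hypomethylation calls against matched normals using
#' one-sided rank-sum tests, one per direction, BH-corrected within each
#' direction.
NULL

FILTER_REASONS <- c("sex_chromosome", "cross_reactive", "snp_adjacent",
                    "high_missingness")

#' Filter probes by annotation flags and missingness
#'
#' A probe matching several reasons is reported once, under the first
#' matching reason in the fixed priority order sex_chromosome >
#' cross_reactive > snp_adjacent > high_missingness. The missingness rule
#' is inclusive: a probe missing in at least `missing_threshold` of all
#' samples (tumors and normals jointly) is removed.
#'
#' @param beta a [beta_matrix]
#' @param ann a [probe_annotation] covering every probe
#' @param missing_threshold missing-fraction cutoff (default 0.9)
#' @return list: `beta` (filtered, row order preserved) and `report`
#'   (`kept` ids and `removed`, a reason-to-ids list)
#' @export
filter_probes <- function(beta, ann, missing_threshold = 0.9) {
  probes <- rownames(beta$values)
  miss_ann <- setdiff(probes, ann$probe_id)
  if (length(miss_ann) > 0)
    stop("probe absent from annotation: ", miss_ann[1])
  ann <- ann[match(probes, ann$probe_id), ]
  miss_frac <- rowMeans(is.na(beta$values))
  reason <- rep(NA_character_, length(probes))
  reason[miss_frac >= missing_threshold] <- "high_missingness"
  reason[has_flag(ann, "snp_adjacent")] <- "snp_adjacent"
  reason[has_flag(ann, "cross_reactive")] <- "cross_reactive"
  reason[has_flag(ann, "sex_chromosome")] <- "sex_chromosome"
  kept <- probes[is.na(reason)]
  removed <- lapply(setNames(FILTER_REASONS, FILTER_REASONS),
                    function(r) probes[!is.na(reason) & reason == r])
  out <- beta
  out$values <- beta$values[is.na(reason), , drop = FALSE]
  list(beta = out, report = list(kept = kept, removed = removed))
}

#' Call hyper- and hypomethylated probes against matched normals
#'
#' One-sided rank-sum tests per probe (tumors vs. normals), one per
#' direction, with BH correction applied within each direction across all
#' probes. A probe is called hyper when its hyper-direction q-value passes
#' `alpha` and the tumor median exceeds the normal median; hypo
#' symmetrically; the two calls are mutually exclusive (ties in q resolve
#' to the direction with the larger absolute median difference).
#'
#' Without any normal sample the calls are undefined — the table is
#' returned with `callable = FALSE` and every call `NA`, mirroring cohorts
#' lacking adjacent-normal tissue.
#'
#' @param beta a [beta_matrix]
#' @param alpha q-value threshold (default 0.05)
#' @return An `aberrant_call_table`: data.frame (probe_id, p_hyper, p_hypo,
#'   q_hyper, q_hypo, median_tumor, median_normal, call) with attribute
#'   `callable`.
#' @export
call_aberrant_probes <- function(beta, alpha = 0.05) {
  probes <- rownames(beta$values)
  tum <- tumor_samples(beta); nor <- normal_samples(beta)
  if (length(nor) == 0) {
    out <- data.frame(probe_id = probes, p_hyper = NA_real_, p_hypo = NA_real_,
                      q_hyper = NA_real_, q_hypo = NA_real_,
                      median_tumor = NA_real_, median_normal = NA_real_,
                      call = NA_character_, stringsAsFactors = FALSE)
    attr(out, "callable") <- FALSE
    class(out) <- c("aberrant_call_table", "data.frame")
    return(out)
  }
  tv <- beta$values[, tum, drop = FALSE]
  nv <- beta$values[, nor, drop = FALSE]
  n_all <- length(tum) + length(nor)
  if (n_all <= 20) {
    # small cohorts take the scalar path so that tie-free probes get the
    # exact rank-sum tail, matching rank_sum_test's branch rule
    p_hyper <- rep(NA_real_, length(probes)); p_hypo <- p_hyper
    med_t <- p_hyper; med_n <- p_hyper
    for (i in seq_along(probes)) {
      x <- tv[i, ]; y <- nv[i, ]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) == 0 || length(y) == 0) next
      p_hyper[i] <- rank_sum_test(x, y, "greater")$p_value
      p_hypo[i] <- rank_sum_test(x, y, "less")$p_value
      med_t[i] <- median(x); med_n[i] <- median(y)
    }
  } else {
    grp <- matrix(as.numeric(beta$sample_group[c(tum, nor)] == "tumor"),
                  ncol = 1, dimnames = list(NULL, "tumor"))
    vals <- beta$values[, c(tum, nor), drop = FALSE]
    p_hyper <- rank_sum_scan(vals, grp, "greater")$p[, 1]
    p_hypo <- rank_sum_scan(vals, grp, "less")$p[, 1]
    med_t <- apply(tv, 1, median, na.rm = TRUE)
    med_n <- apply(nv, 1, median, na.rm = TRUE)
    med_t[is.nan(med_t)] <- NA; med_n[is.nan(med_n)] <- NA
  }
  q_hyper <- bh_qvalues(p_hyper)
  q_hypo <- bh_qvalues(p_hypo)
  call <- rep("none", length(probes))
  hy <- !is.na(q_hyper) & q_hyper < alpha & med_t > med_n
  ho <- !is.na(q_hypo) & q_hypo < alpha & med_t < med_n
  call[hy] <- "hyper"
  call[ho & !hy] <- "hypo"
  call[is.na(p_hyper)] <- NA
  out <- data.frame(probe_id = probes, p_hyper = p_hyper, p_hypo = p_hypo,
                    q_hyper = q_hyper, q_hypo = q_hypo,
                    median_tumor = med_t, median_normal = med_n,
                    call = call, stringsAsFactors = FALSE)
  attr(out, "callable") <- TRUE
  class(out) <- c("aberrant_call_table", "data.frame")
  out
}
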