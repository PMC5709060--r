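#' @title Mutation -> methylation -> expression integration
#' @name integration
#' @description
#' The four-step procedure linking a driver-defined sample grouping to
#' direction-consistent expression changes: (1) link probes to genes
#' (promoter = within 1,500 bp of the TSS, body = inside the gene span)
#' and keep links whose methylation correlates with expression (Spearman,
#' BH); (2) call each probe hyper/hypo per mutation group relative to
#' normals; (3) test group expression against normals; (4) classify genes
#' into the four group-exclusive categories, requiring a supporting link
#' whose methylation call and correlation sign are consistent with the
#' expression change. Plus highly-transcribed filtering, hypergeometric
#' gene-set enrichment, and cross-cohort sharing.
NULL

#' Map probes to genes by promoter / gene-body location
#'
#' In coordinate mode (a `genes` table with columns `gene`, `chromosome`,
#' `start`, `end`, `strand` is supplied), the TSS is the 5' end on the
#' annotated strand; a probe within `tss_window` bp of the TSS
#' (inclusive) is a promoter probe of that gene, and a probe inside the
#' gene span but outside the promoter window is a body probe. A probe may
#' link to several genes. Without `genes`, the annotation's own
#' `linked_gene`/`link_region` columns are passed through.
#'
#' @param ann a [probe_annotation]
#' @param genes optional gene coordinate table (coordinate mode)
#' @param tss_window promoter half-window in bp (default 1500)
#' @return data.frame (probe, gene, region) with region promoter/body
#' @export
map_probes_to_genes <- function(ann, genes = NULL, tss_window = 1500) {
  if (is.null(genes)) {
    keep <- ann$linked_gene != "" & ann$link_region %in% c("promoter", "body")
    return(data.frame(probe = ann$probe_id[keep], gene = ann$linked_gene[keep],
                      region = ann$link_region[keep], stringsAsFactors = FALSE))
  }
  need <- c("gene", "chromosome", "start", "end", "strand")
  if (!all(need %in% names(genes))) stop("gene table needs columns: ",
                                         paste(need, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (is.na(g$start) || is.na(g$end)) {
      warning("gene without coordinates skipped: ", g$gene)
      next
    }
    tss <- if (g$strand == "-") g$end else g$start
    on_chr <- ann$chromosome == g$chromosome
    promoter <- on_chr & abs(ann$position - tss) <= tss_window
    body <- on_chr & ann$position >= g$start & ann$position <= g$end & !promoter
    if (any(promoter))
      rows[[length(rows) + 1]] <- data.frame(probe = ann$probe_id[promoter],
                                             gene = g$gene, region = "promoter",
                                             stringsAsFactors = FALSE)
    if (any(body))
      rows[[length(rows) + 1]] <- data.frame(probe = ann$probe_id[body],
                                             gene = g$gene, region = "body",
                                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(probe = character(0), gene = character(0),
                      region = character(0), stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Spearman correlation of linked probes with their genes' expression
#'
#' Per link, methylation and expression are paired across shared tumor
#' samples and Spearman-correlated; links with fewer than 3 complete pairs
#' or a constant vector are skipped (recorded with NA). BH spans all
#' computed links.
#'
#' @param beta a [beta_matrix]
#' @param expr an [expression_matrix]
#' @param links data.frame (probe, gene, region) from
#'   [map_probes_to_genes]
#' @param alpha q threshold marking `significant` (default 0.05)
#' @return links with added `rho`, `p`, `q`, `n`, `significant`
#' @export
correlate_methylation_expression <- function(beta, expr, links, alpha = 0.05) {
  tum <- intersect(tumor_samples(beta), colnames(expr$values))
  if (length(tum) == 0) stop("no shared tumor samples")
  links <- links[links$probe %in% rownames(beta$values) &
                   links$gene %in% rownames(expr$values), , drop = FALSE]
  links$rho <- NA_real_; links$p <- NA_real_; links$n <- NA_integer_
  for (i in seq_len(nrow(links))) {
    b <- beta$values[links$probe[i], tum]
    e <- expr$values[links$gene[i], tum]
    keep <- !is.na(b) & !is.na(e)
    if (sum(keep) < 3) next
    rb <- rank(b[keep]); re <- rank(e[keep])
    if (var(rb) == 0 || var(re) == 0) next
    links$rho[i] <- cor(rb, re)
    links$p[i] <- cor_t_pvalue(links$rho[i], sum(keep))
    links$n[i] <- sum(keep)
  }
  links$q <- bh_qvalues(links$p)
  links$significant <- !is.na(links$q) & links$q < alpha
  links
}

#' Call hyper/hypomethylated probes per mutation group
#'
#' Each group's tumor samples are compared with the normal samples probe
#' by probe (two-sided rank-sum); BH spans all probes within a group. A
#' probe is hyper in a group when q < `alpha` and the median beta
#' difference against normals exceeds `min_abs_median_diff` with positive
#' sign; hypo symmetrically.
#'
#' @param beta a [beta_matrix] with normals
#' @param groups named list of tumor sample-id vectors (the mutation
#'   groups, e.g. A = BRAF-mutated, B = NRAS/HRAS-mutated)
#' @param alpha q threshold (default 0.05)
#' @param min_abs_median_diff effect-size floor in beta units (default 0;
#'   the per-gene re-correction variant uses 0.1)
#' @return data.frame (group, probe, p, q, median_diff, call)
#' @export
call_group_aberrant_probes <- function(beta, groups, alpha = 0.05,
                                       min_abs_median_diff = 0) {
  nor <- normal_samples(beta)
  if (length(nor) == 0) stop("group aberrant calls are defined relative to normals")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of sample ids")
  out <- list()
  for (gname in names(groups)) {
    gs <- intersect(groups[[gname]], colnames(beta$values))
    if (length(gs) == 0) stop("empty group: ", gname)
    cols <- c(gs, nor)
    ind <- matrix(as.numeric(cols %in% gs), ncol = 1,
                  dimnames = list(NULL, gname))
    sc <- rank_sum_scan(beta$values[, cols, drop = FALSE], ind)
    q <- bh_qvalues(sc$p[, 1])
    call <- rep("none", nrow(beta$values))
    sig <- !is.na(q) & q < alpha & abs(sc$median_diff[, 1]) >= min_abs_median_diff &
      sc$median_diff[, 1] != 0
    call[sig & sc$median_diff[, 1] > 0] <- "hyper"
    call[sig & sc$median_diff[, 1] < 0] <- "hypo"
    call[is.na(sc$p[, 1])] <- NA
    out[[gname]] <- data.frame(group = gname, probe = rownames(beta$values),
                               p = sc$p[, 1], q = q,
                               median_diff = sc$median_diff[, 1],
                               call = call, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# expression status of every gene in every group vs normals:
# one BH family over all gene x group tests
group_expression_status <- function(expr, groups, genes, alpha, min_expr_diff) {
  nor_all <- colnames(expr$values)
  rows <- expand.grid(gene = genes, group = names(groups),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$p <- NA_real_; rows$median_diff <- NA_real_
  for (i in seq_len(nrow(rows))) {
    gs <- groups[[rows$group[i]]]
    ev <- expr$values[rows$gene[i], ]
    x <- ev[intersect(gs, names(ev))]
    y <- ev[attr(groups, "normals")]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) next
    r <- rank_sum_test(x, y)
    rows$p[i] <- r$p_value
    rows$median_diff[i] <- r$effect
  }
  rows$q <- bh_qvalues(rows$p)
  rows$status <- "none"
  up <- !is.na(rows$q) & rows$q < alpha & rows$median_diff >= min_expr_diff &
    rows$median_diff > 0
  dn <- !is.na(rows$q) & rows$q < alpha & rows$median_diff <= -min_expr_diff &
    rows$median_diff < 0
  rows$status[up] <- "up"
  rows$status[dn] <- "down"
  rows
}

#' Classify genes into group-exclusive expression categories
#'
#' Implements the four-category logic over two mutation groups A and B: a
#' gene is `up_in_A_only` when it is upregulated against normals in A
#' (q < `alpha` and median log2 difference >= `min_expr_diff`), not
#' upregulated in B, and supported by at least one significant
#' methylation--expression link whose probe (a) carries an aberrant call
#' in A whose sign is consistent with the expression change through the
#' link's rho (hyper with rho > 0 or hypo with rho < 0 supports up;
#' the mirror supports down) and (b) is called none or the opposite
#' direction in B. The other three categories are symmetric. A gene
#' matching two categories (e.g. up in A and down in B) is assigned the
#' one with the larger absolute expression difference.
#'
#' @param links output of [correlate_methylation_expression]
#' @param aberrant output of [call_group_aberrant_probes] for the same
#'   two groups
#' @param expr an [expression_matrix] including normal samples
#' @param beta the [beta_matrix] (supplies the normal sample ids)
#' @param groups named list of exactly two tumor sample-id vectors
#' @param alpha q threshold for the expression tests (default 0.05)
#' @param min_expr_diff expression effect floor, log2 units (default 0;
#'   the per-gene re-correction variant uses 0.5)
#' @param tumor_reference also require the same-direction median
#'   difference (>= `min_expr_diff`) against tumors outside the group
#' @return data.frame (gene, category, group, expr_median_diff, q_expr,
#'   n_support) for categorized genes; attribute `expression_status` holds
#'   the full per-gene, per-group test table.
#' @export
classify_group_specific_genes <- function(links, aberrant, expr, beta, groups,
                                          alpha = 0.05, min_expr_diff = 0,
                                          tumor_reference = FALSE) {
  if (length(groups) != 2) stop("exactly two groups required")
  gnames <- names(groups)
  nor <- intersect(normal_samples(beta), colnames(expr$values))
  if (length(nor) == 0) stop("no normal samples with expression")
  attr(groups, "normals") <- nor
  cand <- unique(links$gene[links$significant])
  if (length(cand) == 0)
    return(structure(data.frame(gene = character(0), category = character(0),
                                group = character(0),
                                expr_median_diff = numeric(0),
                                q_expr = numeric(0), n_support = integer(0)),
                     expression_status = NULL))
  est <- group_expression_status(expr, groups, cand, alpha, min_expr_diff)
  ab <- split(aberrant, aberrant$group)
  res <- list()
  for (g in cand) {
    glinks <- links[links$gene == g & links$significant, , drop = FALSE]
    hits <- list()
    for (gi in 1:2) {
      a <- gnames[gi]; b <- gnames[3 - gi]
      st_a <- est[est$gene == g & est$group == a, ]
      st_b <- est[est$gene == g & est$group == b, ]
      for (want in c("up", "down")) {
        if (st_a$status != want || st_b$status == want) next
        if (tumor_reference) {
          others <- setdiff(tumor_samples(beta), groups[[a]])
          ev <- expr$values[g, ]
          d2 <- median(ev[intersect(groups[[a]], names(ev))], na.rm = TRUE) -
            median(ev[others], na.rm = TRUE)
          if (want == "up" && !(d2 >= min_expr_diff && d2 > 0)) next
          if (want == "down" && !(d2 <= -min_expr_diff && d2 < 0)) next
        }
        # supporting links: aberrant in A, direction-consistent, none/opposite in B
        need_call <- function(rho, want)
          if ((want == "up") == (rho > 0)) "hyper" else "hypo"
        n_sup <- 0L
        for (j in seq_len(nrow(glinks))) {
          pr <- glinks$probe[j]; rho <- glinks$rho[j]
          ca <- ab[[a]]$call[match(pr, ab[[a]]$probe)]
          cb <- ab[[b]]$call[match(pr, ab[[b]]$probe)]
          if (is.na(ca) || ca == "none") next
          if (ca != need_call(rho, want)) next
          if (!is.na(cb) && cb == ca) next       # must be none or opposite in B
          n_sup <- n_sup + 1L
        }
        if (n_sup == 0L) next
        hits[[length(hits) + 1]] <- data.frame(
          gene = g, category = paste0(want, "_in_", a, "_only"), group = a,
          expr_median_diff = st_a$median_diff, q_expr = st_a$q,
          n_support = n_sup, stringsAsFactors = FALSE)
      }
    }
    if (length(hits) == 1) res[[g]] <- hits[[1]]
    else if (length(hits) > 1) {
      strongest <- which.max(vapply(hits, function(h) abs(h$expr_median_diff), 0))
      res[[g]] <- hits[[strongest]]
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(gene = character(0), category = character(0),
               group = character(0), expr_median_diff = numeric(0),
               q_expr = numeric(0), n_support = integer(0))
  rownames(out) <- NULL
  attr(out, "expression_status") <- est
  out
}

#' Filter categorized genes to the highly transcribed
#'
#' Keeps genes whose median expression in their category's group exceeds
#' `level_cut` (log2 RSEM) and whose median difference against normals
#' exceeds `diff_cut` (1.0 = at least doubled on the linear scale).
#'
#' @param table output of [classify_group_specific_genes]
#' @param expr an [expression_matrix]
#' @param beta the [beta_matrix] (normal sample ids)
#' @param groups the same named group list
#' @param level_cut minimum group median expression (default 10)
#' @param diff_cut minimum median difference vs normals (default 1)
#' @return character vector of gene ids
#' @export
filter_highly_transcribed <- function(table, expr, beta, groups,
                                      level_cut = 10, diff_cut = 1) {
  nor <- intersect(normal_samples(beta), colnames(expr$values))
  keep <- vapply(seq_len(nrow(table)), function(i) {
    ev <- expr$values[table$gene[i], ]
    mg <- median(ev[intersect(groups[[table$group[i]]], names(ev))], na.rm = TRUE)
    mn <- median(ev[nor], na.rm = TRUE)
    !is.na(mg) && !is.na(mn) && mg > level_cut && (mg - mn) > diff_cut
  }, logical(1))
  table$gene[keep]
}

#' Hypergeometric gene-set enrichment of a gene list
#'
#' Upper-tail hypergeometric test per set on the overlap between the gene
#' list and the set, both restricted to the universe; BH across sets.
#'
#' @param genes gene list (must lie within `universe`)
#' @param sets a [gene_set_collection]
#' @param universe background gene list
#' @param alpha q threshold marking `significant` (default 0.05)
#' @return data.frame (set, hits, draw, set_size, universe_size, p, q,
#'   significant), ordered by p
#' @export
enrich_gene_sets <- function(genes, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  genes <- unique(intersect(genes, universe))
  rows <- lapply(names(sets$sets), function(nm) {
    s <- intersect(sets$sets[[nm]], universe)
    hits <- length(intersect(genes, s))
    p <- if (length(s) == 0) NA_real_ else
      hypergeometric_enrichment(hits, length(genes), length(s), length(universe))
    data.frame(set = nm, hits = hits, draw = length(genes),
               set_size = length(s), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_qvalues(res$p)
  res$significant <- !is.na(res$q) & res$q < alpha
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  res
}

#' Genes sharing a regulation direction across cohorts
#'
#' @param per_cohort_tables list of [classify_group_specific_genes]
#'   outputs (one per cohort)
#' @param min_cohorts minimum number of cohorts (default 2)
#' @return list: `up_shared`, `down_shared` gene vectors
#' @export
cross_cancer_shared_genes <- function(per_cohort_tables, min_cohorts = 2) {
  if (length(per_cohort_tables) < 2) stop("need >= 2 cohorts")
  dir_of <- function(tb, d) unique(tb$gene[startsWith(tb$category, d)])
  up <- table(unlist(lapply(per_cohort_tables, dir_of, "up")))
  dn <- table(unlist(lapply(per_cohort_tables, dir_of, "down")))
  list(up_shared = sort(names(up)[up >= min_cohorts]),
       down_shared = sort(names(dn)[dn >= min_cohorts]))
}
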