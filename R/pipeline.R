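#' @title End-to-end pipeline orchestration
#' @name pipeline
#' @description
#' A configuration-driven run over one cohort: probe filtering,
#' hyper/hypo calling, PCA association, HyperZ/HypoZ association, the
#' gene-by-probe scan with empirical FDR, subtype clustering, and (when
#' expression and a two-group definition are present) the
#' methylation--expression integration. Stages execute in dependency
#' order; all tabular outputs are TSVs under the output directory and the
#' run manifest records files, counts, and the seed.
NULL

#' Build and validate a pipeline configuration
#'
#' @param cohort a [cohort_dataset] (alternatively supply `paths`, a named
#'   list with beta/groups/mutations/annotation and optional expression
#'   TSV paths)
#' @param out_dir output directory
#' @param paths named list of input TSV paths (used when `cohort` is NULL)
#' @param stages character vector of stages to run (default all
#'   applicable): filter, diffmeth, pca_assoc, indices, site_assoc,
#'   subtype, integrate
#' @param alpha q threshold, in (0, 1)
#' @param min_mutated gene eligibility (>= 1)
#' @param n_pcs number of PCs
#' @param k_top_probes per-gene panel size for subtyping
#' @param n_subtype_genes dominant genes used for the subtype panel
#' @param k_clusters subtypes to cut
#' @param tss_window promoter window, bp
#' @param min_beta_diff,min_expr_diff integration effect floors
#' @param z_cut HyperZ/HypoZ z cutoff
#' @param permutations empirical-FDR permutations (0 disables)
#' @param integration_groups named list of two driver-gene vectors
#'   defining the mutation groups for integration (e.g. `list(BRAF =
#'   "BRAF", RAS = c("NRAS", "HRAS"))`); NULL skips integration
#' @param seed integer seed
#' @return validated `pipeline_config` list
#' @export
pipeline_config <- function(cohort = NULL, out_dir = tempfile("run"),
                            paths = NULL,
                            stages = c("filter", "diffmeth", "pca_assoc",
                                       "indices", "site_assoc", "subtype",
                                       "integrate"),
                            alpha = 0.05, min_mutated = 5, n_pcs = 5,
                            k_top_probes = 500, n_subtype_genes = 3,
                            k_clusters = 2, tss_window = 1500,
                            min_beta_diff = 0, min_expr_diff = 0,
                            z_cut = 2, permutations = 10,
                            integration_groups = NULL, seed = 1L) {
  if (is.null(cohort) && is.null(paths)) stop("supply a cohort or input paths")
  if (!is.null(paths)) {
    need <- c("beta", "groups", "mutations", "annotation")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0) stop("paths missing: ", paste(miss, collapse = ", "))
    gone <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(gone) > 0) stop("input file not found: ", gone[1])
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0,1)")
  if (min_mutated < 1) stop("min_mutated must be >= 1")
  if (n_pcs < 1 || k_top_probes < 1 || k_clusters < 1 || tss_window < 0 ||
      permutations < 0 || z_cut <= 0)
    stop("threshold outside its documented range")
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(cohort = cohort, paths = paths, out_dir = out_dir,
                 stages = stages, alpha = alpha, min_mutated = min_mutated,
                 n_pcs = n_pcs, k_top_probes = k_top_probes,
                 n_subtype_genes = n_subtype_genes, k_clusters = k_clusters,
                 tss_window = tss_window, min_beta_diff = min_beta_diff,
                 min_expr_diff = min_expr_diff, z_cut = z_cut,
                 permutations = permutations,
                 integration_groups = integration_groups,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the configured pipeline
#'
#' @param config a [pipeline_config]
#' @param verbose print per-stage tallies
#' @return the run manifest (invisibly written as `manifest.json`):
#'   stage -> list(files, counts), plus `seed` and `config_hash`
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  ch <- config$cohort
  if (is.null(ch)) {
    beta <- load_beta_matrix(config$paths$beta, config$paths$groups)
    mut <- load_mutations(config$paths$mutations, "binary")
    ann <- load_probe_annotation(config$paths$annotation)
    expr <- if (!is.null(config$paths$expression))
      load_expression(config$paths$expression) else NULL
    ch <- cohort_dataset(beta, mut, ann, expr)
  }
  manifest <- list(seed = config$seed, stages = list())
  out <- function(name) file.path(config$out_dir, name)
  add <- function(stage, files, counts) {
    manifest$stages[[stage]] <<- list(files = files, counts = counts)
  }
  beta <- ch$beta
  if ("filter" %in% config$stages) {
    fl <- filter_probes(beta, ch$annotation)
    beta <- fl$beta
    rm_df <- data.frame(
      probe_id = unlist(fl$report$removed, use.names = FALSE),
      reason = rep(names(fl$report$removed), lengths(fl$report$removed)))
    write.table(rm_df, out("filter_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add("filter", "filter_report.tsv",
        list(kept = length(fl$report$kept), removed = nrow(rm_df)))
    say("filter: kept %d probes, removed %d", length(fl$report$kept), nrow(rm_df))
  }
  aberrant <- NULL
  if ("diffmeth" %in% config$stages) {
    aberrant <- call_aberrant_probes(beta, alpha = config$alpha)
    write.table(aberrant, out("aberrant_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    n_hyper <- sum(aberrant$call == "hyper", na.rm = TRUE)
    n_hypo <- sum(aberrant$call == "hypo", na.rm = TRUE)
    add("diffmeth", "aberrant_calls.tsv",
        list(hyper = n_hyper, hypo = n_hypo,
             callable = isTRUE(attr(aberrant, "callable"))))
    say("diffmeth: %d hyper, %d hypo", n_hyper, n_hypo)
  }
  if ("pca_assoc" %in% config$stages) {
    pca <- fit_methylation_pca(beta, n_components = config$n_pcs)
    pa <- associate_genes_with_pcs(pca, ch$mutations,
                                   min_mutated = config$min_mutated,
                                   alpha = config$alpha)
    write.table(pa, out("pc_associations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_matrix_tsv(pca$scores, out("pc_scores.tsv"), "sample_id")
    add("pca_assoc", c("pc_associations.tsv", "pc_scores.tsv"),
        list(tests = nrow(pa), significant = sum(pa$significant)))
    say("pca_assoc: %d tests, %d significant", nrow(pa), sum(pa$significant))
  }
  if ("indices" %in% config$stages) {
    idx <- compute_hyperz_hypoz(beta, ch$annotation, z_cut = config$z_cut)
    write.table(idx, out("sample_indices.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts <- list(computable = isTRUE(attr(idx, "computable")))
    if (counts$computable) {
      for (w in c("hyperz", "hypoz")) {
        ia <- tryCatch(
          associate_genes_with_index(idx, ch$mutations, w,
                                     min_mutated = config$min_mutated,
                                     alpha = config$alpha),
          error = function(e) NULL)
        if (!is.null(ia)) {
          write.table(ia, out(paste0(w, "_associations.tsv")), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          counts[[paste0(w, "_significant")]] <- sum(ia$significant)
        }
      }
    }
    add("indices", "sample_indices.tsv", counts)
  }
  site <- NULL
  if ("site_assoc" %in% config$stages) {
    site <- associate_genes_with_probes(beta, ch$mutations, ann = ch$annotation,
                                        min_mutated = config$min_mutated,
                                        alpha = config$alpha)
    write.table(site, out("site_associations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts <- list(tests = attr(site, "n_tests"), discoveries = nrow(site))
    files <- "site_associations.tsv"
    if (nrow(site) > 0) {
      dom <- summarize_dominance(site, aberrant)
      write.table(dom, out("dominance.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, "dominance.tsv")
      counts$dominant_genes <- sum(dom$dominant)
    }
    if (config$permutations > 0) {
      fdr <- estimate_empirical_fdr(beta, ch$mutations,
                                    min_mutated = config$min_mutated,
                                    alpha = config$alpha,
                                    n_permutations = config$permutations,
                                    seed = config$seed)
      counts$empirical_fdr <- fdr$empirical_fdr
    }
    add("site_assoc", files, counts)
    say("site_assoc: %d discoveries of %d tests", nrow(site), counts$tests)
  }
  if ("subtype" %in% config$stages && !is.null(site) && nrow(site) > 0) {
    dom <- summarize_dominance(site)
    genes <- head(dom$gene, config$n_subtype_genes)
    panel <- suppressWarnings(
      select_top_associated_probes(site, genes, k = config$k_top_probes))
    st <- cluster_samples(beta, panel, k_clusters = config$k_clusters)
    write.table(data.frame(sample = names(st$labels), cluster = st$labels),
                out("subtypes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    add("subtype", "subtypes.tsv",
        list(panel_size = length(panel), k = config$k_clusters))
    say("subtype: panel of %d probes, %d clusters", length(panel),
        config$k_clusters)
  } else if ("subtype" %in% config$stages && "site_assoc" %in% config$stages) {
    add("subtype", character(0), list(skipped = "no site associations"))
  } else if ("subtype" %in% config$stages) {
    stop("subtype stage requires site_assoc output")
  }
  if ("integrate" %in% config$stages && !is.null(config$integration_groups)) {
    if (is.null(ch$expression)) stop("integrate stage requires expression data")
    st <- ch$mutations$status
    groups <- lapply(config$integration_groups, function(gs)
      colnames(st)[colSums(st[gs, , drop = FALSE]) > 0])
    links <- map_probes_to_genes(ch$annotation, tss_window = config$tss_window)
    links <- correlate_methylation_expression(beta, ch$expression, links,
                                              alpha = config$alpha)
    ab <- call_group_aberrant_probes(beta, groups, alpha = config$alpha,
                                     min_abs_median_diff = config$min_beta_diff)
    cls <- classify_group_specific_genes(links, ab, ch$expression, beta, groups,
                                         alpha = config$alpha,
                                         min_expr_diff = config$min_expr_diff)
    write.table(cls, out("gene_categories.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add("integrate", "gene_categories.tsv",
        list(links = sum(links$significant, na.rm = TRUE),
             categorized = nrow(cls)))
    say("integrate: %d significant links, %d categorized genes",
        sum(links$significant, na.rm = TRUE), nrow(cls))
  }
  cfg_for_hash <- config[setdiff(names(config), "cohort")]
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
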