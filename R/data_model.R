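#' @title Cohort data containers
#' @name data-model
#' @description
#' Lightweight S3 containers shared by every analysis stage: a beta-value
#' matrix with tumor/normal labels (`beta_matrix`), a binary driver-gene
#' mutation matrix (`mutation_matrix`), a probe annotation table
#' (`probe_annotation`), a log2-scale expression matrix
#' (`expression_matrix`), and a named gene-set collection
#' (`gene_set_collection`). All matrix containers keep probes/genes as rows
#' and samples as columns, preserve input order, and treat missing values
#' as first-class (`NA`, never silently zero).
NULL

CPG_SUBSETS <- c("CGI", "SS", "open_sea")
LINK_REGIONS <- c("promoter", "body", "none")
PROBE_FLAGS <- c("sex_chromosome", "cross_reactive", "snp_adjacent")

#' Construct a beta-value matrix container
#'
#' @param values numeric matrix, probes x samples, values in \[0,1\] or `NA`.
#'   Must carry rownames (probe ids) and colnames (sample ids).
#' @param sample_group named character vector mapping every sample id to
#'   `"tumor"` or `"normal"`.
#' @return A `beta_matrix` object.
#' @export
beta_matrix <- function(values, sample_group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ", colnames(values)[duplicated(colnames(values))][1])
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value outside [0,1] at probe '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  sample_group <- sample_group[colnames(values)]
  if (any(is.na(sample_group)))
    stop("sample_group missing for: ",
         paste(colnames(values)[is.na(sample_group)], collapse = ", "))
  if (!all(sample_group %in% c("tumor", "normal")))
    stop("sample_group values must be 'tumor' or 'normal'")
  if (!any(sample_group == "tumor")) stop("at least one tumor sample required")
  structure(list(values = values, sample_group = sample_group),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d tumor, %d normal), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_group == "tumor"), sum(x$sample_group == "normal"),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Tumor / normal sample ids of a beta matrix
#' @param beta a `beta_matrix`
#' @return character vector of sample ids
#' @export
tumor_samples <- function(beta) names(beta$sample_group)[beta$sample_group == "tumor"]

#' @rdname tumor_samples
#' @export
normal_samples <- function(beta) names(beta$sample_group)[beta$sample_group == "normal"]

#' Construct a binary mutation matrix container
#'
#' @param status integer/numeric matrix, genes x samples, entries in \{0,1\},
#'   with gene rownames and sample colnames.
#' @return A `mutation_matrix` object.
#' @export
mutation_matrix <- function(status) {
  status <- as.matrix(status)
  if (is.null(rownames(status)) || is.null(colnames(status)))
    stop("mutation matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(status))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(status))) stop("duplicate sample ids")
  if (any(is.na(status)) || !all(status %in% c(0, 1)))
    stop("mutation status must be binary 0/1 with no missing values")
  storage.mode(status) <- "integer"
  structure(list(status = status), class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d genes x %d samples, %d mutated cells\n",
              nrow(x$status), ncol(x$status), sum(x$status)))
  invisible(x)
}

#' Per-gene mutated-sample counts
#' @param mut a `mutation_matrix`
#' @return named integer vector
#' @export
mutated_counts <- function(mut) rowSums(mut$status)

#' Construct a probe annotation table
#'
#' @param df data.frame with columns `probe_id`, `chromosome`, `position`
#'   (1-based bp), `cpg_subset` (one of CGI, SS, open_sea), `linked_gene`
#'   ("" when unlinked), `link_region` (promoter, body, none), `flags`
#'   (comma-separated subset of sex_chromosome, cross_reactive,
#'   snp_adjacent; "" for none).
#' @return A `probe_annotation` object (validated data.frame).
#' @export
probe_annotation <- function(df) {
  need <- c("probe_id", "chromosome", "position", "cpg_subset",
            "linked_gene", "link_region", "flags")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  bad <- setdiff(unique(df$cpg_subset), CPG_SUBSETS)
  if (length(bad) > 0)
    stop("unknown cpg_subset label(s): ", paste(bad, collapse = ", "),
         " (expected CGI, SS, open_sea; shores/shelves must be pre-collapsed to SS)")
  bad <- setdiff(unique(df$link_region), LINK_REGIONS)
  if (length(bad) > 0) stop("unknown link_region label(s): ", paste(bad, collapse = ", "))
  df$linked_gene[is.na(df$linked_gene)] <- ""
  df$flags[is.na(df$flags)] <- ""
  fl <- setdiff(unique(unlist(strsplit(df$flags[df$flags != ""], ","))), PROBE_FLAGS)
  if (length(fl) > 0) stop("unknown probe flag(s): ", paste(fl, collapse = ", "))
  df$position <- as.integer(df$position)
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Test whether annotated probes carry a given flag
#' @param ann a `probe_annotation`
#' @param flag one of `"sex_chromosome"`, `"cross_reactive"`, `"snp_adjacent"`
#' @return logical vector aligned to `ann$probe_id`
#' @export
has_flag <- function(ann, flag) {
  flag <- match.arg(flag, PROBE_FLAGS)
  vapply(strsplit(ann$flags, ","), function(f) flag %in% f, logical(1))
}

#' Construct an expression matrix container (log2 scale)
#'
#' @param values numeric matrix, genes x samples, log2 RSEM scale (negative
#'   values allowed), gene rownames and sample colnames.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(is.infinite(values))) stop("expression values must be finite or NA")
  structure(list(values = values), class = "expression_matrix")
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members; deduplicated).
#' @param description optional named character vector per set.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty gene set not allowed")
  if (is.null(description)) description <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, description = description[names(sets)]),
            class = "gene_set_collection")
}

#' Bundle cohort components
#'
#' @param beta `beta_matrix`
#' @param mutations `mutation_matrix`; its samples must be a subset of the
#'   beta matrix's tumor samples.
#' @param annotation `probe_annotation` covering the beta probes
#' @param expression optional `expression_matrix`
#' @param driver_genes optional character vector (defaults to all genes in
#'   the mutation matrix)
#' @return A `cohort_dataset` object.
#' @export
cohort_dataset <- function(beta, mutations, annotation, expression = NULL,
                           driver_genes = NULL) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(mutations, "mutation_matrix"),
            inherits(annotation, "probe_annotation"))
  if (!all(colnames(mutations$status) %in% tumor_samples(beta)))
    stop("mutation samples must be tumor samples of the beta matrix")
  if (!all(rownames(beta$values) %in% annotation$probe_id))
    stop("annotation does not cover all beta probes")
  if (is.null(driver_genes)) driver_genes <- rownames(mutations$status)
  if (!all(driver_genes %in% rownames(mutations$status)))
    stop("driver gene absent from mutation matrix")
  structure(list(beta = beta, mutations = mutations, annotation = annotation,
                 expression = expression, driver_genes = driver_genes),
            class = "cohort_dataset")
}

# ---- readers / writers (TSV, GMT) -----------------------------------------

read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m) &
                   m != "NA", arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]], path))
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- ids
  m
}

#' Read a beta-value matrix with its sample-group file
#'
#' `path` is a TSV with a header row of sample ids and probe ids in the
#' first column; missing cells are written as `NA`. `groups_path` is a
#' two-column TSV (`sample_id`, `group`) with group tumor/normal.
#'
#' @param path beta TSV path
#' @param groups_path sample-group TSV path
#' @return A `beta_matrix`.
#' @export
load_beta_matrix <- function(path, groups_path) {
  m <- read_tsv_matrix(path)
  g <- read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(g)))
    stop("groups file needs columns sample_id, group")
  beta_matrix(m, setNames(g$group, g$sample_id))
}

#' Write a beta matrix and its groups file
#' @param beta a `beta_matrix`
#' @param path,groups_path output TSV paths
#' @export
write_beta_matrix <- function(beta, path, groups_path) {
  write_matrix_tsv(beta$values, path, id_col = "probe_id")
  write.table(data.frame(sample_id = names(beta$sample_group),
                         group = unname(beta$sample_group)),
              groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col) {
  # %.17g keeps doubles bit-identical across a write/load round trip
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  chr[is.na(m)] <- "NA"
  df <- data.frame(rownames(m), chr, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read mutation calls as a binary gene-by-sample matrix
#'
#' In `"binary"` mode the file is a gene x sample TSV of 0/1. In
#' `"records"` mode each row is one reported mutation (columns `gene`,
#' `sample`, anything else ignored); records collapse to gene-level binary
#' status — any reported mutation marks the gene mutated in that sample,
#' regardless of variant class or multiplicity.
#'
#' @param path input TSV path
#' @param mode `"binary"` or `"records"`
#' @param samples in records mode, optional full sample universe so that
#'   samples without any mutation appear as all-zero columns.
#' @return A `mutation_matrix`.
#' @export
load_mutations <- function(path, mode = c("binary", "records"), samples = NULL) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    m <- read_tsv_matrix(path)
    return(mutation_matrix(m))
  }
  rec <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "sample") %in% names(rec)))
    stop("records file needs columns gene, sample")
  genes <- unique(rec$gene)
  if (is.null(samples)) samples <- unique(rec$sample)
  status <- matrix(0L, length(genes), length(samples),
                   dimnames = list(genes, samples))
  status[cbind(match(rec$gene, genes), match(rec$sample, samples))] <- 1L
  mutation_matrix(status)
}

#' Write a mutation matrix as a binary TSV
#' @param mut a `mutation_matrix`
#' @param path output path
#' @export
write_mutations <- function(mut, path) write_matrix_tsv(mut$status, path, "gene_id")

#' Read a probe annotation TSV
#' @param path TSV with the `probe_annotation` columns
#' @return A `probe_annotation`.
#' @export
load_probe_annotation <- function(path) {
  probe_annotation(read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character", na.strings = NULL))
}

#' Write a probe annotation TSV
#' @param ann a `probe_annotation`
#' @param path output path
#' @export
write_probe_annotation <- function(ann, path) {
  write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log2-scale expression matrix TSV
#' @param path genes x samples TSV, log2 scale already applied
#' @return An `expression_matrix`.
#' @export
load_expression <- function(path) expression_matrix(read_tsv_matrix(path))

#' Write an expression matrix TSV
#' @param expr an `expression_matrix`
#' @param path output path
#' @export
write_expression <- function(expr, path) write_matrix_tsv(expr$values, path, "gene_id")

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' members. Duplicate members within a line are dropped.
#'
#' @param path GMT path
#' @return A `gene_set_collection`.
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0)
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  desc <- setNames(vapply(parts, `[[`, "", 2), names(sets))
  gene_set_collection(sets, desc)
}
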