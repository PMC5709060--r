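#' @title Synthetic cohorts with planted ground truth
#' @name synthetic-data
#' @description
#' Generates tumor/normal cohorts with the statistical structure the
#' analysis assumes: logit-normal beta values around CpG-subset-specific
#' baselines, matched normals drawn from the same baselines, binary driver
#' mutations with optional mutual-exclusivity structure, planted
#' mutation-to-methylation shifts expressed directly in beta units, and
#' expression coupled (positively or negatively) to planted probes. Every
#' planted feature is returned as ground truth for recovery testing.
NULL

logit <- function(p) log(p / (1 - p))

# Gauss-type quadrature nodes for E over N(0,1); fixed grid keeps the
# mean-matching Newton solve fully vectorized over probes.
.zq <- seq(-6, 6, length.out = 61)
.wq <- {
  w <- dnorm(.zq); w / sum(w)
}

# expected beta when logit(beta) ~ N(mu, sigma^2); vectorized over mu
expected_beta <- function(mu, sigma) {
  drop(plogis(outer(mu, sigma * .zq, `+`)) %*% .wq)
}

# Solve for mu such that E[plogis(mu + sigma Z)] = target (vectorized
# Newton; the logit-normal mean exceeds plogis(mu) near 0 and undershoots
# near 1, so naive logit(target) would bias planted effect sizes).
match_logit_mean <- function(target, sigma) {
  target <- pmin(pmax(target, 1e-3), 1 - 1e-3)
  mu <- logit(target)
  for (i in 1:8) {
    m <- expected_beta(mu, sigma)
    dm <- drop((plogis(outer(mu, sigma * .zq, `+`)) *
                  (1 - plogis(outer(mu, sigma * .zq, `+`)))) %*% .wq)
    mu <- mu - (m - target) / pmax(dm, 1e-8)
  }
  mu
}

#' Simulation configuration
#'
#' Defaults describe the study-scale regime the pipeline is tested under: a
#' cohort of 100 tumors with 30 matched normals, 5,000 probes split across
#' CpG subsets with the canonical baseline ordering (CGI unmethylated,
#' open sea methylated, shores/shelves intermediate), beta-scale noise of
#' 0.1, and drivers mutated at realistic frequencies.
#'
#' @param n_tumors,n_normals sample counts
#' @param probes_per_subset named counts for CGI, SS, open_sea probes
#' @param baseline_means named mean beta per subset
#' @param probe_baseline_sd logit-scale spread of per-probe baselines
#'   around the subset mean
#' @param noise_sd beta-scale sample-to-sample noise at the probe baseline
#'   (converted to a logit-scale sigma by the delta method)
#' @param driver_genes data.frame with columns `gene`, `frequency` in
#'   (0,1), and optional `exclusivity_group` (NA = independent); genes
#'   sharing a group are never co-mutated in one sample
#' @param planted_effects list of `list(gene=, probes=, delta_beta=)`:
#'   in tumors mutated for `gene`, each listed probe's expected beta is
#'   shifted by `delta_beta` (signed, |delta_beta| <= 0.8)
#' @param coupled_genes data.frame with columns `gene`, `probe`, `sign`
#'   (+1/-1), `slope` (log2 units per beta unit): expression of `gene` is a
#'   linear function of the probe's beta, plus noise
#' @param expr_baseline,expr_noise_sd log2-RSEM expression baseline and
#'   Gaussian noise sd
#' @param n_background_genes uncoupled expression genes (noise only)
#' @param seed integer master seed; stage substreams derive from it
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tumors = 100, n_normals = 30,
                              probes_per_subset = c(CGI = 2000, SS = 1500, open_sea = 1500),
                              baseline_means = c(CGI = 0.15, SS = 0.5, open_sea = 0.85),
                              probe_baseline_sd = 0.3,
                              noise_sd = 0.1,
                              driver_genes = default_driver_table(),
                              planted_effects = list(),
                              coupled_genes = NULL,
                              expr_baseline = 8, expr_noise_sd = 0.5,
                              n_background_genes = 20,
                              seed = 1L) {
  stopifnot(n_tumors >= 1, n_normals >= 0)
  if (!all(CPG_SUBSETS %in% names(probes_per_subset)))
    stop("probes_per_subset needs CGI, SS, open_sea")
  if (!all(CPG_SUBSETS %in% names(baseline_means)))
    stop("baseline_means needs CGI, SS, open_sea")
  stopifnot(all(baseline_means > 0 & baseline_means < 1))
  if (anyDuplicated(driver_genes$gene)) stop("duplicate driver gene")
  if (any(driver_genes$frequency <= 0 | driver_genes$frequency >= 1))
    stop("mutation frequencies must lie in (0,1)")
  if (is.null(driver_genes$exclusivity_group))
    driver_genes$exclusivity_group <- NA_character_
  grp_sum <- tapply(driver_genes$frequency, driver_genes$exclusivity_group, sum)
  if (any(grp_sum > 1, na.rm = TRUE))
    stop("summed frequencies of an exclusivity group exceed 1")
  cfg <- list(n_tumors = as.integer(n_tumors), n_normals = as.integer(n_normals),
              probes_per_subset = probes_per_subset[CPG_SUBSETS],
              baseline_means = baseline_means[CPG_SUBSETS],
              probe_baseline_sd = probe_baseline_sd, noise_sd = noise_sd,
              driver_genes = driver_genes, planted_effects = planted_effects,
              coupled_genes = coupled_genes,
              expr_baseline = expr_baseline, expr_noise_sd = expr_noise_sd,
              n_background_genes = as.integer(n_background_genes),
              seed = as.integer(seed))
  ids <- config_probe_ids(cfg)
  for (pe in planted_effects) {
    if (!all(c("gene", "probes", "delta_beta") %in% names(pe)))
      stop("planted effect needs gene, probes, delta_beta")
    if (!pe$gene %in% driver_genes$gene)
      stop("planted-effect gene not a driver: ", pe$gene)
    if (!all(pe$probes %in% ids))
      stop("planted-effect probe not in cohort: ",
           setdiff(pe$probes, ids)[1])
    if (abs(pe$delta_beta) > 0.8) stop("|delta_beta| must be <= 0.8")
  }
  if (!is.null(coupled_genes)) {
    stopifnot(all(c("gene", "probe", "sign", "slope") %in% names(coupled_genes)))
    if (!all(coupled_genes$sign %in% c(-1, 1))) stop("coupling sign must be +1/-1")
    if (any(coupled_genes$slope <= 0)) stop("coupling slope must be positive")
    if (!all(coupled_genes$probe %in% ids)) stop("coupled probe not in cohort")
  }
  structure(cfg, class = "simulation_config")
}

#' Default driver-gene table: 20 genes at frequencies 0.05-0.30
#'
#' Frequencies are evenly spaced over the range typical of recurrently
#' mutated drivers in TCGA cohorts; no exclusivity structure.
#' @return data.frame(gene, frequency, exclusivity_group)
#' @export
default_driver_table <- function() {
  data.frame(gene = sprintf("gene%02d", 1:20),
             frequency = seq(0.05, 0.30, length.out = 20),
             exclusivity_group = NA_character_,
             stringsAsFactors = FALSE)
}

#' Probe identifiers of a configured cohort
#'
#' Ids are deterministic and subset-prefixed (`cgi_00001`, `ss_00001`,
#' `sea_00001`), so configurations can reference planted probes without
#' generating the cohort first.
#'
#' @param config a `simulation_config`
#' @param subset optionally restrict to one CpG subset
#' @return character vector of probe ids in matrix row order
#' @export
config_probe_ids <- function(config, subset = NULL) {
  pref <- c(CGI = "cgi", SS = "ss", open_sea = "sea")
  ids <- unlist(lapply(CPG_SUBSETS, function(s)
    sprintf("%s_%05d", pref[[s]], seq_len(config$probes_per_subset[[s]]))),
    use.names = FALSE)
  if (!is.null(subset)) {
    subset <- match.arg(subset, CPG_SUBSETS)
    ids <- grep(paste0("^", pref[[subset]], "_"), ids, value = TRUE)
  }
  ids
}

stage_seed <- function(seed, k) as.integer((as.double(seed) * 7919 + k) %% 2147483629)

draw_mutations <- function(config, samples) {
  dg <- config$driver_genes
  status <- matrix(0L, nrow(dg), length(samples),
                   dimnames = list(dg$gene, samples))
  groups <- unique(dg$exclusivity_group[!is.na(dg$exclusivity_group)])
  for (g in groups) {
    idx <- which(dg$exclusivity_group %in% g)
    pr <- c(dg$frequency[idx], 1 - sum(dg$frequency[idx]))
    pick <- sample.int(length(idx) + 1, length(samples), replace = TRUE, prob = pr)
    for (j in seq_along(idx))
      status[idx[j], pick == j] <- 1L
  }
  solo <- which(is.na(dg$exclusivity_group))
  for (j in solo)
    status[j, ] <- rbinom(length(samples), 1, dg$frequency[j])
  status
}

#' Generate a synthetic cohort with planted effects
#'
#' Beta values are logit-normal around per-probe baselines whose means are
#' matched to the configured subset baseline (the logit-normal mean is
#' matched numerically, so planted `delta_beta` is the expected
#' mutated-minus-unmutated difference in beta units). Normals share the
#' baselines and never carry planted effects. Mutations are Bernoulli at
#' the configured frequencies with exclusivity-group members never
#' co-mutated. Expression for coupled genes is linear in the planted
#' probe's beta (slope in log2 units per beta unit) plus Gaussian noise.
#' Fully reproducible from `config$seed`.
#'
#' @param config a `simulation_config`
#' @return list with `cohort` (a [cohort_dataset]) and `truth` (a
#'   `planted_truth`: `effect_map`, `subtype_labels`, `coupled_pairs`)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tum <- sprintf("t%04d", seq_len(config$n_tumors))
  nor <- if (config$n_normals > 0) sprintf("n%04d", seq_len(config$n_normals)) else character(0)
  samples <- c(tum, nor)
  probes <- config_probe_ids(config)
  subset_of <- rep(CPG_SUBSETS, times = unlist(config$probes_per_subset))
  names(subset_of) <- probes

  set.seed(stage_seed(config$seed, 1L))
  status <- draw_mutations(config, tum)

  set.seed(stage_seed(config$seed, 2L))
  # per-probe baselines: logit-scale spread, mean-matched back to beta scale
  base_logit_raw <- logit(config$baseline_means[subset_of]) +
    rnorm(length(probes), 0, config$probe_baseline_sd)
  b_target <- plogis(base_logit_raw)              # per-probe expected beta
  sig_logit <- config$noise_sd / pmax(b_target * (1 - b_target), 0.09)
  # group probes by (rounded) sigma for vectorized Newton solves
  sig_key <- round(sig_logit, 3)
  mu0 <- numeric(length(probes))
  for (s in unique(sig_key)) {
    idx <- which(sig_key == s)
    mu0[idx] <- match_logit_mean(b_target[idx], s)
  }
  shift <- matrix(0, length(probes), length(samples),
                  dimnames = list(probes, samples))
  effect_map <- list()
  for (pe in config$planted_effects) {
    carriers <- tum[status[pe$gene, ] == 1L]
    pidx <- match(pe$probes, probes)
    d <- numeric(length(pidx))
    for (s in unique(sig_key[pidx])) {
      k <- which(sig_key[pidx] == s)
      d[k] <- match_logit_mean(b_target[pidx][k] + pe$delta_beta, s) - mu0[pidx][k]
    }
    shift[pidx, carriers] <- shift[pidx, carriers] + d
    em <- effect_map[[pe$gene]]
    add <- setNames(rep(pe$delta_beta, length(pe$probes)), pe$probes)
    effect_map[[pe$gene]] <- if (is.null(em)) add else c(em, add)
  }
  noise <- matrix(rnorm(length(probes) * length(samples), 0, sig_logit),
                  length(probes), length(samples))
  values <- plogis(mu0 + shift + noise)
  dimnames(values) <- list(probes, samples)
  beta <- beta_matrix(values, setNames(rep(c("tumor", "normal"),
                                           c(length(tum), length(nor))), samples))

  ann <- probe_annotation(data.frame(
    probe_id = probes,
    chromosome = paste0("chr", (seq_along(probes) - 1) %% 22 + 1),
    position = 10000L + 1000L * seq_along(probes),
    cpg_subset = unname(subset_of),
    linked_gene = "", link_region = "none", flags = "",
    stringsAsFactors = FALSE))
  expr <- NULL
  coupled_pairs <- NULL
  if (!is.null(config$coupled_genes) || config$n_background_genes > 0) {
    set.seed(stage_seed(config$seed, 3L))
    cg <- config$coupled_genes
    bg <- if (config$n_background_genes > 0)
      sprintf("bg%03d", seq_len(config$n_background_genes)) else character(0)
    genes <- c(if (!is.null(cg)) cg$gene else character(0), bg)
    ev <- matrix(rnorm(length(genes) * length(samples), 0, config$expr_noise_sd),
                 length(genes), length(samples), dimnames = list(genes, samples))
    ev <- ev + config$expr_baseline
    if (!is.null(cg)) {
      for (i in seq_len(nrow(cg))) {
        pb <- values[cg$probe[i], ]
        ev[cg$gene[i], ] <- ev[cg$gene[i], ] +
          cg$slope[i] * cg$sign[i] * (pb - config$baseline_means[[subset_of[cg$probe[i]]]])
      }
      # annotate coupled probes as promoter probes of their coupled gene
      ann$linked_gene[match(cg$probe, ann$probe_id)] <- cg$gene
      ann$link_region[match(cg$probe, ann$probe_id)] <- "promoter"
      coupled_pairs <- cg[, c("gene", "probe", "sign")]
    }
    expr <- expression_matrix(ev)
  }
  planted_genes <- unique(vapply(config$planted_effects, `[[`, "", "gene"))
  subtype_labels <- setNames(rep("none", length(tum)), tum)
  for (g in planted_genes)
    subtype_labels[status[g, ] == 1L] <-
      ifelse(subtype_labels[status[g, ] == 1L] == "none", g,
             paste(subtype_labels[status[g, ] == 1L], g, sep = "+"))
  truth <- structure(list(effect_map = effect_map,
                          subtype_labels = subtype_labels,
                          coupled_pairs = coupled_pairs),
                     class = "planted_truth")
  list(cohort = cohort_dataset(beta, mutation_matrix(status), ann, expr),
       truth = truth)
}

#' Generate a null cohort (no planted effects, no coupling)
#'
#' Identical to [generate_cohort] with `planted_effects` and
#' `coupled_genes` cleared: every downstream discovery on such a cohort is
#' false by construction, which is what the empirical-FDR experiments rely
#' on.
#'
#' @param config a `simulation_config`
#' @return as [generate_cohort]; `truth$effect_map` is empty
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  config$planted_effects <- list()
  config$coupled_genes <- NULL
  generate_cohort(config)
}

#' Write a cohort and its planted truth to a directory
#'
#' Emits the standard TSVs (`beta.tsv`, `groups.tsv`, `mutations.tsv`,
#' `annotation.tsv`, optionally `expression.tsv`) plus `truth.json`.
#'
#' @param sim result of [generate_cohort]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ch <- sim$cohort
  write_beta_matrix(ch$beta, file.path(dir, "beta.tsv"), file.path(dir, "groups.tsv"))
  write_mutations(ch$mutations, file.path(dir, "mutations.tsv"))
  write_probe_annotation(ch$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(ch$expression))
    write_expression(ch$expression, file.path(dir, "expression.tsv"))
  jsonlite::write_json(
    list(effect_map = lapply(sim$truth$effect_map, as.list),
         subtype_labels = as.list(sim$truth$subtype_labels),
         coupled_pairs = sim$truth$coupled_pairs),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
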