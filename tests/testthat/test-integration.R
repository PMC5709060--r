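test_that("probe-gene mapping respects the inclusive TSS window and gene span", {
  ann <- make_annotation(sprintf("cg%d", 1:5),
                         position = c(11500, 11501, 15000, 25000, 9000))
  genes <- data.frame(gene = "G1", chromosome = "chr1", start = 10000,
                      end = 20000, strand = "+", stringsAsFactors = FALSE)
  links <- map_probes_to_genes(ann, genes, tss_window = 1500)
  get <- function(p) links$region[links$probe == p]
  expect_equal(get("cg1"), "promoter")        # TSS + 1500 exactly
  expect_equal(get("cg2"), "body")            # TSS + 1501, inside the span
  expect_equal(get("cg3"), "body")
  expect_length(get("cg4"), 0)                # outside the span
  expect_equal(get("cg5"), "promoter")        # upstream within the window

  # minus strand: TSS at the end coordinate
  genes_m <- transform(genes, strand = "-")
  links_m <- map_probes_to_genes(ann, genes_m, tss_window = 1500)
  expect_equal(links_m$region[links_m$probe == "cg4"], character(0))
  expect_equal(links_m$region[links_m$probe == "cg3"], "body")
})

test_that("probe-gene mapping equals a brute-force interval oracle", {
  set.seed(71)
  ann <- make_annotation(sprintf("cg%02d", 1:20),
                         position = sample(1000:60000, 20))
  genes <- data.frame(gene = sprintf("G%d", 1:5),
                      chromosome = "chr1",
                      start = sample(5000:30000, 5),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(3000:15000, 5)
  genes$strand <- sample(c("+", "-"), 5, replace = TRUE)
  links <- map_probes_to_genes(ann, genes)
  brute <- list()
  for (i in seq_len(nrow(ann))) for (j in seq_len(nrow(genes))) {
    tss <- if (genes$strand[j] == "-") genes$end[j] else genes$start[j]
    pos <- ann$position[i]
    region <- if (abs(pos - tss) <= 1500) "promoter"
      else if (pos >= genes$start[j] && pos <= genes$end[j]) "body"
      else NA
    if (!is.na(region))
      brute[[length(brute) + 1]] <- data.frame(probe = ann$probe_id[i],
                                               gene = genes$gene[j],
                                               region = region)
  }
  brute <- do.call(rbind, brute)
  ord <- function(d) d[order(d$probe, d$gene, d$region), ]
  expect_equal(ord(links), ord(brute), ignore_attr = TRUE)
})

test_that("methylation-expression correlation flags planted couplings", {
  base <- simulation_config(probes_per_subset = c(CGI = 100, SS = 50,
                                                  open_sea = 50))
  cgi <- config_probe_ids(base, "CGI")
  cfg <- simulation_config(seed = 72, n_tumors = 60, n_normals = 10,
                           probes_per_subset = c(CGI = 100, SS = 50,
                                                 open_sea = 50),
                           expr_noise_sd = 0,
                           coupled_genes = data.frame(
                             gene = c("e1", "e2"), probe = cgi[1:2],
                             sign = c(-1, 1), slope = 3))
  sim <- generate_cohort(cfg)
  ch <- sim$cohort
  links <- map_probes_to_genes(ch$annotation)
  res <- correlate_methylation_expression(ch$beta, ch$expression, links)
  expect_equal(res$rho[res$gene == "e1"], -1)
  expect_equal(res$rho[res$gene == "e2"], 1)
  expect_true(all(res$significant))
  # constant expression is skipped, not an error
  ev <- ch$expression$values
  ev["e2", ] <- 5
  res2 <- correlate_methylation_expression(ch$beta, expression_matrix(ev), links)
  expect_true(is.na(res2$rho[res2$gene == "e2"]))
})

test_that("group aberrant calls honour the beta effect-size floor", {
  set.seed(73)
  n <- 30
  ids <- c("big", "small", "null")
  v <- matrix(runif(3 * (2 * n + 20), 0.40, 0.44), 3,
              dimnames = list(ids, c(sprintf("t%02d", 1:(2 * n)),
                                     sprintf("n%02d", 1:20))))
  v["big", 1:n] <- v["big", 1:n] + 0.30
  v["small", 1:n] <- v["small", 1:n] + 0.05
  # identical repeating pattern everywhere: exactly null, immune to chance
  v["null", ] <- rep(c(0.40, 0.41, 0.42, 0.43), length.out = ncol(v))
  groups <- list(A = sprintf("t%02d", 1:n), B = sprintf("t%02d", (n + 1):(2 * n)))
  beta <- beta_matrix(v, setNames(rep(c("tumor", "normal"), c(2 * n, 20)),
                                  colnames(v)))
  ab0 <- call_group_aberrant_probes(beta, groups)
  a0 <- ab0[ab0$group == "A", ]
  expect_equal(a0$call[a0$probe == "big"], "hyper")
  expect_equal(a0$call[a0$probe == "small"], "hyper")   # no floor: q wins
  expect_equal(a0$call[a0$probe == "null"], "none")
  ab1 <- call_group_aberrant_probes(beta, groups, min_abs_median_diff = 0.1)
  a1 <- ab1[ab1$group == "A", ]
  expect_equal(a1$call[a1$probe == "big"], "hyper")
  expect_equal(a1$call[a1$probe == "small"], "none")    # |diff| = 0.05 < 0.1
  b1 <- ab1[ab1$group == "B", ]
  expect_true(all(b1$call == "none"))
  expect_error(call_group_aberrant_probes(
    beta_matrix(v[, 1:(2 * n)], setNames(rep("tumor", 2 * n),
                                         colnames(v)[1:(2 * n)])), groups),
    "normals")
})

integration_fixture <- function(seed = 74, expr_noise = 0.5) {
  base <- simulation_config()
  cgi <- config_probe_ids(base, "CGI")
  coupled <- data.frame(gene = sprintf("cpl%02d", 1:20), probe = cgi[1:20],
                        sign = rep(c(-1, 1), 10), slope = 4)
  cfg <- simulation_config(
    seed = seed, n_tumors = 210, n_normals = 30,
    probes_per_subset = c(CGI = 700, SS = 150, open_sea = 150),
    expr_noise_sd = expr_noise,
    driver_genes = data.frame(gene = c("drvA", "drvB"),
                              frequency = c(0.45, 0.45),
                              exclusivity_group = "x"),
    planted_effects = list(list(gene = "drvA", probes = cgi[1:20],
                                delta_beta = 0.3)),
    coupled_genes = coupled)
  sim <- generate_cohort(cfg)
  st <- sim$cohort$mutations$status
  groups <- list(A = colnames(st)[st["drvA", ] == 1],
                 B = colnames(st)[st["drvB", ] == 1])
  want <- setNames(ifelse(coupled$sign == -1, "down_in_A_only", "up_in_A_only"),
                   coupled$gene)
  list(sim = sim, groups = groups, want = want)
}

test_that("four-category classification recovers planted gene regulation", {
  fx <- integration_fixture()
  ch <- fx$sim$cohort
  links <- correlate_methylation_expression(ch$beta, ch$expression,
                                            map_probes_to_genes(ch$annotation))
  ab <- call_group_aberrant_probes(ch$beta, fx$groups)
  cls <- classify_group_specific_genes(links, ab, ch$expression, ch$beta,
                                       fx$groups)
  got <- setNames(cls$category, cls$gene)[names(fx$want)]
  expect_gte(sum(got == fx$want, na.rm = TRUE), 16)
  expect_equal(sum(!is.na(got) & got != fx$want), 0)
  # categories are mutually exclusive per gene by construction
  expect_false(anyDuplicated(cls$gene) > 0)

  # swapping the group labels mirrors every category
  groups_sw <- list(A = fx$groups$B, B = fx$groups$A)
  ab_sw <- ab
  ab_sw$group <- chartr("AB", "BA", ab_sw$group)
  cls_sw <- classify_group_specific_genes(links, ab_sw, ch$expression,
                                          ch$beta, groups_sw)
  swap <- function(cat) chartr("AB", "BA", cat)
  m <- match(cls$gene, cls_sw$gene)
  expect_equal(cls_sw$category[m], swap(cls$category))
})

test_that("genes without a consistent supporting link stay unclassified", {
  fx <- integration_fixture()
  ch <- fx$sim$cohort
  links <- correlate_methylation_expression(ch$beta, ch$expression,
                                            map_probes_to_genes(ch$annotation))
  ab <- call_group_aberrant_probes(ch$beta, fx$groups)
  # break the links: mark them non-significant
  links0 <- links; links0$significant <- FALSE
  cls0 <- classify_group_specific_genes(links0, ab, ch$expression, ch$beta,
                                        fx$groups)
  expect_equal(nrow(cls0), 0)
  # erase the methylation calls instead: classification also collapses
  ab0 <- ab; ab0$call <- "none"
  cls1 <- classify_group_specific_genes(links, ab0, ch$expression, ch$beta,
                                        fx$groups)
  expect_equal(nrow(cls1), 0)
})

test_that("highly transcribed filtering applies both cutoffs", {
  ev <- rbind(hi_big = c(rep(11, 10), rep(9.5, 5)),
              lo_big = c(rep(9.9, 10), rep(5, 5)),
              hi_small = c(rep(10.5, 10), rep(10, 5)))
  colnames(ev) <- c(sprintf("t%02d", 1:10), sprintf("n%02d", 1:5))
  expr <- expression_matrix(ev)
  bv <- matrix(0.5, 1, 15, dimnames = list("cg1", colnames(ev)))
  beta <- beta_matrix(bv, setNames(rep(c("tumor", "normal"), c(10, 5)),
                                   colnames(ev)))
  tbl <- data.frame(gene = rownames(ev), category = "up_in_A_only",
                    group = "A", stringsAsFactors = FALSE)
  groups <- list(A = sprintf("t%02d", 1:10))
  kept <- filter_highly_transcribed(tbl, expr, beta, groups)
  expect_equal(kept, "hi_big")                # 11 > 10 and diff 1.5 > 1
})

test_that("gene-set enrichment matches the kernel oracle and ranks truly enriched sets first", {
  gs <- gene_set_collection(list(S1 = sprintf("g%d", 1:5),
                                 S2 = sprintf("g%d", 6:10),
                                 S3 = sprintf("g%d", 1:10)))
  universe <- sprintf("g%d", 1:10)
  res <- enrich_gene_sets(sprintf("g%d", 1:4), gs, universe)
  expect_equal(res$set[1], "S1")
  r1 <- res[res$set == "S1", ]
  expect_equal(r1$p, hypergeometric_enrichment(4, 4, 5, 10))
  expect_equal(r1$p, 5 / 210, tolerance = 1e-12)
  r2 <- res[res$set == "S2", ]
  expect_equal(r2$hits, 0)
  expect_equal(r2$p, 1)
  expect_error(enrich_gene_sets("g1", gs, character(0)), "empty universe")
})

test_that("cross-cohort sharing respects direction and the cohort minimum", {
  mk <- function(genes, cat) data.frame(gene = genes, category = cat,
                                        stringsAsFactors = FALSE)
  t1 <- mk(c("a", "b"), c("up_in_A_only", "down_in_A_only"))
  t2 <- mk(c("a", "b"), c("up_in_B_only", "up_in_A_only"))
  t3 <- mk("c", "down_in_B_only")
  res <- cross_cancer_shared_genes(list(t1, t2, t3))
  expect_equal(res$up_shared, "a")            # up in 2 cohorts (any group)
  expect_equal(res$down_shared, character(0)) # b: up once, down once
  res2 <- cross_cancer_shared_genes(list(t1, t2, t3), min_cohorts = 1)
  expect_setequal(res2$down_shared, c("b", "c"))
})
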