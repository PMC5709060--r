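small_cfg <- function(...) {
  simulation_config(n_tumors = 40, n_normals = 10,
                    probes_per_subset = c(CGI = 60, SS = 40, open_sea = 40),
                    ...)
}

test_that("generation is bit-identical for a fixed seed", {
  cfg <- small_cfg(seed = 5)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a$cohort$beta$values, b$cohort$beta$values)
  expect_identical(a$cohort$mutations$status, b$cohort$mutations$status)
  expect_identical(a$truth, b$truth)
})

test_that("beta values stay in (0,1) with subset-ordered baselines", {
  sim <- generate_cohort(small_cfg(seed = 8))
  v <- sim$cohort$beta$values
  expect_true(all(v > 0 & v < 1))
  ann <- sim$cohort$annotation
  m <- tapply(rowMeans(v), ann$cpg_subset[match(rownames(v), ann$probe_id)], mean)
  expect_true(m[["CGI"]] < m[["SS"]], )
  expect_true(m[["SS"]] < m[["open_sea"]])
})

test_that("grand mean beta tracks the configured baseline on a large panel", {
  cfg <- simulation_config(n_tumors = 50, n_normals = 0,
                           probes_per_subset = c(CGI = 10000, SS = 0, open_sea = 0),
                           baseline_means = c(CGI = 0.15, SS = 0.5, open_sea = 0.85),
                           seed = 21)
  sim <- generate_cohort(cfg)
  expect_lt(abs(mean(sim$cohort$beta$values) - 0.15), 0.01)
})

test_that("mutation counts are binomially consistent with frequencies", {
  cfg <- simulation_config(n_tumors = 1000, n_normals = 0,
                           probes_per_subset = c(CGI = 10, SS = 0, open_sea = 0),
                           driver_genes = data.frame(gene = "g1", frequency = 0.3,
                                                     exclusivity_group = NA),
                           seed = 4)
  sim <- generate_cohort(cfg)
  count <- sum(sim$cohort$mutations$status)
  expect_lt(abs(count - 300), 3 * sqrt(1000 * 0.3 * 0.7))
})

test_that("exclusivity groups never co-mutate and reject impossible frequencies", {
  dg <- data.frame(gene = c("gA", "gB"), frequency = c(0.4, 0.4),
                   exclusivity_group = "e")
  sim <- generate_cohort(small_cfg(seed = 6, driver_genes = dg))
  expect_lte(max(colSums(sim$cohort$mutations$status)), 1)
  expect_error(small_cfg(driver_genes = data.frame(
    gene = c("gA", "gB"), frequency = c(0.6, 0.6), exclusivity_group = "e")),
    "exceed 1")
})

test_that("planted effects shift the expected beta by delta_beta", {
  cgi <- config_probe_ids(small_cfg(), "CGI")
  cfg <- simulation_config(n_tumors = 400, n_normals = 10,
                           probes_per_subset = c(CGI = 60, SS = 40, open_sea = 40),
                           driver_genes = data.frame(gene = "gA", frequency = 0.5,
                                                     exclusivity_group = NA),
                           planted_effects = list(list(gene = "gA",
                                                       probes = cgi[1:30],
                                                       delta_beta = 0.3)),
                           seed = 9)
  sim <- generate_cohort(cfg)
  st <- sim$cohort$mutations$status["gA", ]
  tum <- tumor_samples(sim$cohort$beta)
  v <- sim$cohort$beta$values[cgi[1:30], tum]
  realized <- mean(rowMeans(v[, st[tum] == 1]) - rowMeans(v[, st[tum] == 0]))
  expect_lt(abs(realized - 0.3), 0.02)
  expect_equal(sim$truth$effect_map$gA, setNames(rep(0.3, 30), cgi[1:30]))
})

test_that("null cohorts carry no planted structure", {
  cfg <- small_cfg(seed = 10,
                   planted_effects = list(list(gene = "gene01",
                                               probes = "cgi_00001",
                                               delta_beta = 0.4)))
  sim <- generate_null_cohort(cfg)
  expect_length(sim$truth$effect_map, 0)
  expect_null(sim$truth$coupled_pairs)
  # mean |median beta difference| mutated vs non-mutated is ~0
  st <- sim$cohort$mutations$status
  tum <- tumor_samples(sim$cohort$beta)
  g <- rownames(st)[which(rowSums(st) >= 5)[1]]
  m <- st[g, tum] == 1
  v <- sim$cohort$beta$values[, tum]
  diffs <- matrixStats::rowMedians(v[, m]) - matrixStats::rowMedians(v[, !m])
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("zero-noise coupling gives exactly monotone expression", {
  cgi <- config_probe_ids(small_cfg(), "CGI")
  cfg <- small_cfg(seed = 12, expr_noise_sd = 0,
                   coupled_genes = data.frame(gene = "eg1", probe = cgi[1],
                                              sign = -1, slope = 3))
  sim <- generate_cohort(cfg)
  tum <- tumor_samples(sim$cohort$beta)
  rho <- spearman_correlation(sim$cohort$beta$values[cgi[1], tum],
                              sim$cohort$expression$values["eg1", tum])$rho
  expect_equal(rho, -1)
})

test_that("opposite planted effects separate subtypes in beta space", {
  cgi <- config_probe_ids(small_cfg(), "CGI")
  dg <- data.frame(gene = c("gA", "gB"), frequency = c(0.5, 0.5),
                   exclusivity_group = "e")
  cfg <- small_cfg(seed = 14, driver_genes = dg, planted_effects = list(
    list(gene = "gA", probes = cgi[1:20], delta_beta = 0.3),
    list(gene = "gB", probes = cgi[21:40], delta_beta = -0.3)))
  sim <- generate_cohort(cfg)
  tum <- tumor_samples(sim$cohort$beta)
  lab <- sim$truth$subtype_labels[tum]
  v <- sim$cohort$beta$values[cgi[1:40], tum]
  d <- as.matrix(dist(t(v)))
  same <- outer(lab, lab, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same], na.rm = TRUE), mean(d[same & !is.na(same)]))
})

test_that("cohorts round-trip through the on-disk TSV + truth JSON layout", {
  cgi <- config_probe_ids(small_cfg(), "CGI")
  cfg <- small_cfg(seed = 15,
                   planted_effects = list(list(gene = "gene01",
                                               probes = cgi[1:3],
                                               delta_beta = 0.2)),
                   coupled_genes = data.frame(gene = "eg1", probe = cgi[1],
                                              sign = 1, slope = 2))
  sim <- generate_cohort(cfg)
  d <- tempfile("cohort")
  write_cohort(sim, d)
  b <- load_beta_matrix(file.path(d, "beta.tsv"), file.path(d, "groups.tsv"))
  expect_equal(b$values, sim$cohort$beta$values)
  m <- load_mutations(file.path(d, "mutations.tsv"), "binary")
  expect_equal(m$status, sim$cohort$mutations$status)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(names(truth$effect_map), "gene01")
  expect_equal(unlist(truth$effect_map$gene01), setNames(rep(0.2, 3), cgi[1:3]))
})
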