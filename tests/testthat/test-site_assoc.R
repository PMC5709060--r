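planted_scan_fixture <- function(seed = 51, n_tumors = 100, freq = 0.3,
                                 delta = 0.3, n_planted = 50) {
  cfg <- simulation_config(seed = seed, n_tumors = n_tumors,
                           probes_per_subset = c(CGI = 400, SS = 300,
                                                 open_sea = 300))
  cgi <- config_probe_ids(cfg, "CGI")
  cfg <- simulation_config(seed = seed, n_tumors = n_tumors,
                           probes_per_subset = c(CGI = 400, SS = 300,
                                                 open_sea = 300),
                           driver_genes = data.frame(
                             gene = c("gHit", sprintf("g%02d", 1:5)),
                             frequency = c(freq, rep(0.2, 5)),
                             exclusivity_group = NA),
                           planted_effects = list(list(
                             gene = "gHit", probes = cgi[seq_len(n_planted)],
                             delta_beta = delta)))
  list(sim = generate_cohort(cfg), planted = cgi[seq_len(n_planted)])
}

test_that("the scan recovers planted gene-probe effects with high precision", {
  fx <- planted_scan_fixture()
  ch <- fx$sim$cohort
  tab <- associate_genes_with_probes(ch$beta, ch$mutations, ann = ch$annotation)
  hits <- tab$probe[tab$gene == "gHit"]
  expect_gte(sum(fx$planted %in% hits), 40)
  expect_gte(sum(tab$probe %in% fx$planted) / max(nrow(tab), 1), 0.9)
  expect_true(all(tab$direction[tab$gene == "gHit" &
                                  tab$probe %in% fx$planted] == 1))
  expect_true(all(tab$cpg_subset[tab$probe %in% fx$planted] == "CGI"))
  expect_equal(attr(tab, "n_tests"), 6 * 1000)
})

test_that("null cohorts yield (almost) no discoveries", {
  cfg <- simulation_config(seed = 52, n_tumors = 80,
                           probes_per_subset = c(CGI = 300, SS = 200,
                                                 open_sea = 200))
  sim <- generate_null_cohort(cfg)
  tab <- associate_genes_with_probes(sim$cohort$beta, sim$cohort$mutations)
  expect_lte(nrow(tab), 2)
})

test_that("ineligible genes never appear in the output", {
  fx <- planted_scan_fixture()
  ch <- fx$sim$cohort
  st <- ch$mutations$status
  st["g01", ] <- 0L
  st["g02", ] <- c(rep(1L, 3), rep(0L, ncol(st) - 3))
  tab <- associate_genes_with_probes(ch$beta, mutation_matrix(st),
                                     keep_all = TRUE)
  expect_false(any(c("g01", "g02") %in% tab$gene))
  expect_true("gHit" %in% tab$gene)
})

test_that("scan output is invariant to sample and probe order", {
  fx <- planted_scan_fixture(seed = 53, n_tumors = 40)
  ch <- fx$sim$cohort
  t1 <- associate_genes_with_probes(ch$beta, ch$mutations)
  set.seed(1)
  pperm <- sample(nrow(ch$beta$values)); sperm <- sample(ncol(ch$beta$values))
  beta2 <- beta_matrix(ch$beta$values[pperm, sperm],
                       ch$beta$sample_group[sperm])
  t2 <- associate_genes_with_probes(beta2, ch$mutations)
  key <- function(t) t[order(t$gene, t$probe), c("gene", "probe", "p", "q")]
  expect_equal(key(t2), key(t1), ignore_attr = TRUE)
})

test_that("complementing the mutation labels flips every direction", {
  fx <- planted_scan_fixture(seed = 54, n_tumors = 60)
  ch <- fx$sim$cohort
  t1 <- associate_genes_with_probes(ch$beta, ch$mutations, keep_all = TRUE)
  mut2 <- mutation_matrix(1L - ch$mutations$status)
  t2 <- associate_genes_with_probes(ch$beta, mut2, keep_all = TRUE)
  shared <- intersect(paste(t1$gene, t1$probe), paste(t2$gene, t2$probe))
  i1 <- match(shared, paste(t1$gene, t1$probe))
  i2 <- match(shared, paste(t2$gene, t2$probe))
  nz <- t1$direction[i1] != 0
  expect_equal(t2$direction[i2][nz], -t1$direction[i1][nz])
})

test_that("empirical FDR is deterministic in the seed and small for planted data", {
  fx <- planted_scan_fixture(seed = 55)
  ch <- fx$sim$cohort
  e1 <- estimate_empirical_fdr(ch$beta, ch$mutations, n_permutations = 5,
                               seed = 99)
  e2 <- estimate_empirical_fdr(ch$beta, ch$mutations, n_permutations = 5,
                               seed = 99)
  expect_identical(e1, e2)
  expect_lt(e1$empirical_fdr, 0.05)
  expect_gte(e1$n_observed, 40)
  expect_error(estimate_empirical_fdr(ch$beta, ch$mutations,
                                      n_permutations = 0), ">= 1")
})

test_that("dominance summaries match a hand tally and flag dominant genes", {
  tab <- data.frame(
    gene = c("gA", "gA", "gA", "gA", "gB", "gB"),
    probe = sprintf("p%d", 1:6),
    p = rep(1e-8, 6), q = rep(1e-6, 6),
    direction = c(1, 1, -1, 1, -1, -1),
    median_diff = c(0.3, 0.2, -0.1, 0.4, -0.2, -0.3),
    cpg_subset = c("CGI", "CGI", "SS", "open_sea", "CGI", "SS"),
    stringsAsFactors = FALSE)
  ab <- data.frame(probe_id = sprintf("p%d", 1:6),
                   call = c("hyper", "none", "hypo", "hyper", "hypo", "hypo"),
                   stringsAsFactors = FALSE)
  dom <- summarize_dominance(tab, ab)
  expect_equal(attr(dom, "n_total_probes"), 6)
  ga <- dom[dom$gene == "gA", ]
  expect_equal(ga$n_assoc, 4)
  expect_equal(ga$frac_of_total, 4 / 6)
  expect_equal(ga$pos_CGI, 2)
  expect_equal(ga$neg_SS, 1)
  expect_equal(ga$pos_open_sea, 1)
  expect_equal(ga$pos_hyper, 2)                  # p1 and p4
  expect_equal(ga$neg_hypo, 1)                   # p3
  expect_true(all(dom$dominant))                 # both genes exceed 10%
  single <- summarize_dominance(tab[tab$gene == "gA", ])
  expect_equal(single$frac_of_total, 1)
})

test_that("cross-cohort probe sharing equals the set-intersection oracle", {
  mk <- function(probes) data.frame(gene = "g", probe = probes,
                                    direction = -1, stringsAsFactors = FALSE)
  same <- sprintf("p%d", 1:5)
  res <- count_shared_probes(list(mk(same), mk(same), mk(same)), "g", -1)
  expect_equal(res, c(">=1" = 5L, ">=2" = 5L, ">=3" = 5L))
  res2 <- count_shared_probes(list(mk(c("a", "b")), mk(c("c", "d"))), "g", -1)
  expect_equal(res2[[">=2"]], 0L)
  set.seed(56)
  tables <- lapply(1:4, function(i) mk(sample(sprintf("p%d", 1:30), 12)))
  res3 <- count_shared_probes(tables, "g", -1)
  counts <- table(unlist(lapply(tables, `[[`, "probe")))
  for (k in 1:4)
    expect_equal(res3[[paste0(">=", k)]], sum(counts >= k))
  expect_length(count_shared_probes(tables, "absent", -1), 0)
})

test_that("single-gene re-correction never increases q and recovers a superset", {
  fx <- planted_scan_fixture(seed = 57)
  ch <- fx$sim$cohort
  joint <- associate_genes_with_probes(ch$beta, ch$mutations, keep_all = TRUE)
  solo <- reassociate_single_gene(ch$beta, ch$mutations, "gHit", keep_all = TRUE)
  jg <- joint[joint$gene == "gHit", ]
  m <- match(solo$probe, jg$probe)
  expect_true(all(solo$q <= jg$q[m] + 1e-12))
  joint_sig <- jg$probe[jg$q < 0.05]
  solo_sig <- solo$probe[solo$q < 0.05]
  expect_true(all(joint_sig %in% solo_sig))
  expect_error(reassociate_single_gene(ch$beta, ch$mutations, "nope"),
               "unknown gene")
  st <- ch$mutations$status; st["g01", ] <- 0L
  expect_error(reassociate_single_gene(ch$beta, mutation_matrix(st), "g01"),
               "not eligible")
})
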