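#!/usr/bin/env Rscript
# Build the cohorts every later stage analyzes: a "study" cohort with two
# mutually exclusive driver mutations planting opposite methylation shifts
# on disjoint CGI panels plus 20 methylation-coupled expression genes, and
# a matched null cohort with no planted structure. Written as TSVs under
# results/cohorts/ with the planted truth alongside.

suppressPackageStartupMessages(library(methdriver))

out_root <- "results/cohorts"
seed <- 20260923L

base <- simulation_config()
cgi <- config_probe_ids(base, "CGI")

coupled <- data.frame(gene = sprintf("cpl%02d", 1:20), probe = cgi[1:20],
                      sign = rep(c(-1, 1), 10), slope = 4)

study_cfg <- simulation_config(
  seed = seed, n_tumors = 210, n_normals = 30,
  driver_genes = data.frame(gene = c("drvA", "drvB", sprintf("g%02d", 1:6)),
                            frequency = c(0.45, 0.45, rep(0.10, 6)),
                            exclusivity_group = c("x", "x", rep(NA, 6))),
  planted_effects = list(
    list(gene = "drvA", probes = cgi[1:200], delta_beta = 0.3),
    list(gene = "drvB", probes = cgi[201:400], delta_beta = -0.3)),
  coupled_genes = coupled)

study <- generate_cohort(study_cfg)
write_cohort(study, file.path(out_root, "study"))

null_sim <- generate_null_cohort(simulation_config(seed = seed + 1L))
write_cohort(null_sim, file.path(out_root, "null"))

cat(sprintf("study cohort: %d probes x %d samples, %d driver genes, %d planted probes\n",
            nrow(study$cohort$beta$values), ncol(study$cohort$beta$values),
            nrow(study$cohort$mutations$status),
            length(unlist(lapply(study$truth$effect_map, names)))))
cat(sprintf("null cohort:  %d probes x %d samples, no planted effects\n",
            nrow(null_sim$cohort$beta$values),
            ncol(null_sim$cohort$beta$values)))
cat("written under", out_root, "\n")
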