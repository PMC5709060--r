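---
title: "Methods: linking driver mutations to DNA methylation in tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking driver mutations to DNA methylation in tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the data

Tumors accumulate both somatic driver mutations and genome-wide DNA
methylation changes, and in several cancers specific drivers co-occur with
methylation phenotypes (most prominently CpG-island methylator phenotypes,
CIMP). `methdriver` implements a cohort-level association analysis that asks,
for every driver gene and a 450K-style beta-value matrix, whether the
mutated tumors' methylation differs from the non-mutated tumors' — at three
resolutions (principal components of the methylome, genome-wide alteration
indices, and individual probes), followed by mutation-anchored subtyping and
an integration step that ties group-specific methylation changes to
group-specific expression changes.

The inputs are the field's standard matrices: beta values in [0,1] (probes
by samples, tumors plus adjacent normals), binary gene-level mutation status
(a gene counts as mutated in a sample if any somatic mutation was reported),
log2-scale RSEM expression, a probe annotation (chromosome, position, CpG
subset — island/shore-shelf/open-sea — and optional gene linkage), and GMT
gene sets. All analyses are per cohort.

# Statistical core

Every two-group comparison is a Wilcoxon rank-sum test. The scalar test
(`rank_sum_test`) uses the exact Wilcoxon tail when the pooled sample is
tie-free and no larger than 20, and otherwise the normal approximation with
midrank tie correction and continuity correction; the cutoff of 20 bounds
enumeration cost while covering the small-group regime (genes are only
tested with at least five mutated samples). The association scans run a
vectorized form of the same approximation (`rank_sum_scan`): ranks per
probe, rank sums for all genes at once by matrix multiplication, per-probe
tie correction. Agreement between the two routes, and against
`stats::wilcox.test` and full enumeration oracles, is asserted in the test
suite.

Direction is everywhere the sign of the median difference, mutated (or
tumor) group minus the reference, so "+" means higher methylation (or
expression, or index) with the mutation. Multiple testing uses
Benjamini–Hochberg q-values; the literature this analysis style comes from
cites a generic q-value method without a formula, and BH was chosen as the
deterministic, assumption-light variant (a Storey-type estimator can yield
q < p and cannot be reconstructed from printed counts alone). The BH family
is always stated explicitly per operation: all gene-by-PC tests jointly, all
gene-by-probe tests jointly (the single-gene re-correction restricts the
family to one gene's tests, which is the one analysis where family choice
materially changes counts), per direction for tumor-vs-normal calls, per
group for group-vs-normal calls, across links for methylation–expression
correlations, and across sets for enrichment.

# Probe filtering and aberrant-methylation calls

Standard 450K exclusions are applied before analysis: sex-chromosome,
cross-reactive, and SNP-adjacent probes (all injected as annotation flags,
since the published exclusion lists are external resources), plus probes
missing in at least 90% of samples — tumors and normals counted jointly,
the reading we adopted of "across all samples". When a probe matches
several reasons it is reported once under a fixed priority (sex >
cross-reactive > SNP > missingness) so reports are deterministic.

Hyper- and hypomethylated probes are called against matched normals with
two one-sided rank-sum tests, one per direction, BH-corrected within each
direction across all probes (the direction-wise family is our choice; the
source text specifies one test per direction but not the correction
family). A call additionally requires the median difference to have the
matching sign, which makes hyper and hypo mutually exclusive. Cohorts
without normal samples return an explicitly uncallable table rather than an
error, mirroring cohorts that lack adjacent-normal tissue.

# PCA and gene–PC association

PCA is fit on tumor samples only, centering probes without scaling (beta
values share a scale; scaling would up-weight near-constant probes).
Missing betas are mean-imputed per probe by default; an iterative EM-style
low-rank re-imputation (`impute = "em"`) is available and, at the planted
effect sizes used in testing, changes no association call. Five components
are the default, the conventional balance between captured variance and
test count. Because PC signs are arbitrary, each component is oriented so
its largest-magnitude loading is positive; association p-values are
invariant under sign flips and only the +/- extreme label changes.

The mitotic-index re-analysis computes a per-sample mean over a supplied
feature list (mean beta over a CpG list, or mean log2 expression over a
gene list — the 385-CpG and 9-gene lists of the epiTOC-style indices are
user inputs, not shipped), removes probes whose Pearson correlation with
the index has p < 0.05 across tumors, refits the PCA, and re-runs the
associations.

# HyperZ and HypoZ

The genome-wide indices summarize how broadly a tumor sample deviates from
the normal methylome. No formula is published for them in the text this
design follows, so we fixed a bounded, interpretable form: z-score each
probe against the normal-sample mean and SD (SD floored at 0.01 to avoid
division blow-ups on near-constant probes), and report per sample the
fraction of eligible probes beyond the cutoff — HyperZ over CGI probes
unmethylated in normals (normal mean < 0.3) with z > 2, HypoZ over open-sea
probes methylated in normals (normal mean > 0.7) with z < -2. Restricting
to eligible probes makes the indices measure aberrant change specifically;
all five constants are configuration. At least two normals are required;
otherwise the table is flagged not computable. An alternative aggregation
(summed or averaged z) is defensible and would change numeric values but
not the association logic.

# The gene-by-probe scan and empirical FDR

The core scan tests every eligible driver gene (at least five mutated and
one non-mutated tumor) against every probe and corrects over all pairs
jointly. Probes missing in more than half of either group are skipped for
that pair (a power floor; unspecified in the source design). The empirical
FDR check re-runs the full scan on permuted labels: by default each gene's
mutation labels are shuffled independently across tumors, preserving
per-gene counts while breaking gene–probe linkage; a joint mode permuting
whole sample columns (preserving co-mutation structure) is provided because
the published description does not disambiguate. Ten permutations are the
default — the scan is the costly unit, and the estimate
(mean null discoveries / observed discoveries, capped at 1) stabilizes
quickly at these test counts.

Dominance summaries count each gene's share of all probes associated with
any gene (a gene above 10% is flagged dominant); because a probe can
associate with several genes, the shares can sum above 1.

# Subtyping

Subtype discovery clusters tumors on the union of each dominant gene's top
k = 500 associated probes (smallest p, ties by larger absolute median
difference, then probe id). Distance and linkage are unstated in the
analyses this mirrors; Euclidean/Ward (`ward.D2`) is the default as the
stable, variance-minimizing choice for beta panels, with 1-Pearson/average
as an option. The cluster count defaults to 2 (subtypes in this style are
read off heatmaps, and no automatic selection is attempted). The variance
variant takes the top 1% most variable probes across tumors. Recovery
against planted labels is scored with the adjusted Rand index.

# Integration

The four-step procedure links methylation to expression within two
mutually exclusive mutation groups A and B: (1) probes map to genes as
promoter (within 1,500 bp of the strand-resolved TSS, inclusive) or body
(inside the span, outside the promoter window), and links are kept when
probe methylation and gene expression correlate across tumors (Spearman,
BH over links); (2) probes are called hyper/hypo per group against
normals, with an optional absolute-median-difference floor (0.1 beta in
the single-driver variant); (3) each candidate gene is tested for
expression change per group against normals (optionally also against
tumors outside the group, with a 0.5 log2 floor in the single-driver
variant); (4) a gene lands in `up_in_A_only` when it is up in A, not up in
B, and at least one significant link supports the change
direction-consistently — the probe's call in A combined with the link's
correlation sign implies the expression direction (hyper with negative rho
supports down, etc.), and the probe must be unchanged or opposite in B.
"No change" is operationalized as "not significant in that group", and
the B-side requirement accepts none-or-opposite, the permissive reading of
the source wording. A gene satisfying two categories at once (up in A and
down in B) is assigned the category with the larger absolute expression
difference, keeping categories mutually exclusive. Highly transcribed
genes are those with group median above 10 log2 RSEM and at least 1 log2
(one doubling) above normals. Enrichment is an upper-tail hypergeometric
test per gene set, with the universe taken as all genes carrying at least
one analyzed link (unstated in the source; this keeps draw and universe on
the same footing).

# The synthetic cohorts

The generator emulates exactly the structure the analysis assumes. Beta
values are logit-normal: per-probe baselines spread around CpG-subset
means (defaults CGI 0.15, shore/shelf 0.5, open sea 0.85 — the canonical
ordering), sample noise of 0.1 on the beta scale converted to a logit
sigma by the delta method. The logit-normal mean is matched numerically to
the target beta (a vectorized Newton solve), so a planted `delta_beta` is
the expected mutated-minus-unmutated difference in beta units — this
keeps recovery thresholds such as the 0.1 median-difference floor
interpretable. Mutations are Bernoulli at configured frequencies;
exclusivity groups draw at most one mutated gene per sample and reject
configurations whose frequencies sum above 1. Expression for coupled
genes is baseline + slope x sign x (probe beta - subset baseline) +
Gaussian noise, so a zero-noise coupling yields Spearman rho of exactly
+/-1. One master seed drives deterministic per-stage substreams.

Default cohort dimensions are 100 tumors, 30 normals, and 5,000 probes
(2,000 CGI / 1,500 SS / 1,500 open sea) with 20 driver genes at
frequencies 0.05–0.30 — the regime of a mid-sized TCGA cohort, scaled in
probe count so that a full scan runs in seconds; planted effect sizes of
|delta beta| = 0.3 and noise 0.1 are calibration choices, as real-data
effect distributions are only reported through thresholds. What the
generator does *not* emulate: probe-type chemistry, tumor purity mixture,
copy number, spatial correlation along the genome, and batch structure.
Passing recovery tests therefore shows the pipeline's statistics behave
correctly under its own model assumptions, not that real cohorts are this
clean.

# Numerical and degenerate-input policy

Fully tied features return p = 1 and direction 0 rather than NaN. Constant
vectors make correlations error (scalar) or skip the link (batch).
Zero-variance PCA input errors out instead of returning NaN scores. Ties in
probe selection break by probe id; clustering is deterministic for fixed
input. Missing values are first-class throughout: they are never silently
zero, indices and medians ignore them, and an index over zero eligible
probes is NA, not 0. Matrix writers emit doubles at 17 significant digits
so that write-then-load round trips are bit-identical.

# Known limitations

The scan's normal-approximation p-values cannot reach the extreme tails
that exact enumeration would assign for very small mutated groups, so at
genome-wide BH thresholds genes near the five-sample eligibility floor are
effectively unrecoverable — a conservative bias shared by the approximation
itself. HyperZ/HypoZ values are not numerically comparable to other
published index implementations (the aggregation is our choice). The
pipeline does not adjust for tumor purity or model combinatorial
multi-gene effects, and the probe-filtering step reproduces the exclusion
logic, not any published probe list.
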