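# Independent brute-force oracles, kept deliberately naive.

# Exact two-group rank-sum p by enumerating every assignment of the pooled
# midranks to group 1. Two-sided tail is P(|U - mu| >= |u_obs - mu|).
enum_rank_sum_p <- function(x, y, alternative = "two_sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  switch(alternative,
    greater = mean(u_all >= u_obs),
    less = mean(u_all <= u_obs),
    two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu)))
}

# BH step-up from the definition: q_(i) = min_{j>=i} p_(j) m / j, remapped.
bh_brute <- function(p) {
  o <- order(p)
  ps <- p[o]
  m <- length(p)
  qs <- vapply(seq_len(m), function(i) min(ps[i:m] * m / (i:m)), numeric(1))
  res <- numeric(m)
  res[o] <- pmin(qs, 1)
  res
}

# Hypergeometric upper tail by exhaustive enumeration of all draws.
enum_hypergeom_p <- function(hits, draw, set_size, universe) {
  members <- c(rep(TRUE, set_size), rep(FALSE, universe - set_size))
  sets <- utils::combn(universe, draw)
  mean(apply(sets, 2, function(ix) sum(members[ix]) >= hits))
}

# small planted two-block cohort used by several modules
make_two_block_cohort <- function(seed = 1, n_per_block = 50, n_probes = 100,
                                  lo = 0.2, hi = 0.8, noise = 0.05) {
  set.seed(seed)
  n <- 2 * n_per_block
  block <- rep(c(0, 1), each = n_per_block)
  pattern <- rep(c(0, 1), length.out = n_probes)
  mean_mat <- lo + (hi - lo) *
    outer(pattern, block, function(a, b) as.numeric(xor(a, b)))
  v <- mean_mat + matrix(rnorm(n_probes * n, 0, noise), n_probes, n)
  v <- pmin(pmax(v, 0), 1)
  rownames(v) <- sprintf("p%03d", seq_len(n_probes))
  colnames(v) <- sprintf("s%03d", seq_len(n))
  beta <- beta_matrix(v, setNames(rep("tumor", n), colnames(v)))
  list(beta = beta, block = setNames(block, colnames(v)))
}

# hand-built annotation fixture
make_annotation <- function(probe_id, cpg_subset = "CGI", chromosome = "chr1",
                            position = seq_along(probe_id) * 1000L,
                            linked_gene = "", link_region = "none", flags = "") {
  probe_annotation(data.frame(probe_id = probe_id, chromosome = chromosome,
                              position = position, cpg_subset = cpg_subset,
                              linked_gene = linked_gene,
                              link_region = link_region, flags = flags,
                              stringsAsFactors = FALSE))
}
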