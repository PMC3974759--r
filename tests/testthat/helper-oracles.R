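# Independent oracles and fixture builders used across the suite.

# textbook OLS via R's lm(): the reference implementation the engine must match
oracle_slope <- function(x, y) {
  co <- summary(stats::lm(y ~ x))$coefficients
  list(beta = co[2, 1], se = co[2, 2], t = co[2, 3], p = co[2, 4])
}

oracle_pearson <- function(x, y) {
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-300)

# A random single-concentration survivor-set instance in the shape
# assemble_triads() consumes, plus the universes needed for brute force.
make_step_instance <- function(seed, n_snps = 4, n_mirnas = 3, n_genes = 3) {
  withr::with_seed(seed, {
    snps <- sprintf("s%d", seq_len(n_snps))
    mirs <- sprintf("m%d", seq_len(n_mirnas))
    genes <- sprintf("g%d", seq_len(n_genes))
    rnd_p <- function(n) 10^stats::runif(n, -8, 0)
    s1_rec <- data.frame(gene_id = genes, p = rnd_p(n_genes))
    s2_rec <- data.frame(mirna_id = mirs, p = rnd_p(n_mirnas))
    s6_rec <- data.frame(snp_id = snps, p = rnd_p(n_snps))
    pg <- expand.grid(gene_id = genes, mirna_id = mirs,
                      stringsAsFactors = FALSE)
    pg$p <- rnd_p(nrow(pg)); pg$r <- -stats::runif(nrow(pg))
    pg$pass <- stats::runif(nrow(pg)) < 0.45
    p4 <- expand.grid(snp_id = snps, gene_id = genes,
                      stringsAsFactors = FALSE)
    p4$p <- rnd_p(nrow(p4)); p4$pass <- stats::runif(nrow(p4)) < 0.45
    p5 <- expand.grid(snp_id = snps, mirna_id = mirs,
                      stringsAsFactors = FALSE)
    p5$p <- rnd_p(nrow(p5)); p5$pass <- stats::runif(nrow(p5)) < 0.45
    st <- list(
      s1 = list(survivors = genes[stats::runif(n_genes) < 0.7],
                records = s1_rec),
      s2 = list(survivors = mirs[stats::runif(n_mirnas) < 0.7],
                records = s2_rec),
      s3 = list(pairs = pg),
      s4 = list(pairs = p4),
      s5 = list(pairs = p5),
      s6 = list(survivors = snps[stats::runif(n_snps) < 0.6],
                records = s6_rec)
    )
    list(steps = st, snps = snps, mirs = mirs, genes = genes)
  })
}

# exhaustive cross-product join: the brute-force triad oracle
oracle_triads <- function(inst) {
  st <- inst$steps
  grid <- expand.grid(snp_id = inst$snps, mirna_id = inst$mirs,
                      gene_id = inst$genes, stringsAsFactors = FALSE)
  keep <- logical(nrow(grid))
  pair_key <- function(df, a, b) paste(df[[a]], df[[b]])
  k3 <- pair_key(st$s3$pairs[st$s3$pairs$pass, ], "gene_id", "mirna_id")
  k4 <- pair_key(st$s4$pairs[st$s4$pairs$pass, ], "snp_id", "gene_id")
  k5 <- pair_key(st$s5$pairs[st$s5$pairs$pass, ], "snp_id", "mirna_id")
  for (i in seq_len(nrow(grid))) {
    g <- grid$gene_id[i]; m <- grid$mirna_id[i]; s <- grid$snp_id[i]
    keep[i] <- g %in% st$s1$survivors && m %in% st$s2$survivors &&
      paste(g, m) %in% k3 && paste(s, g) %in% k4 &&
      paste(s, m) %in% k5 && s %in% st$s6$survivors
  }
  out <- grid[keep, ]
  out[order(out$snp_id, out$mirna_id, out$gene_id), ]
}

triad_keys <- function(triads) {
  sort(paste(triads$snp_id, triads$mirna_id, triads$gene_id))
}

# small planted cohort used by several cascade tests
small_planted_cohort <- function(seed = 7, n_samples = 500) {
  generate_cohort(cohort_spec(
    n_samples = n_samples, n_snps = 120, n_genes = 120, n_mirnas = 40,
    n_planted_triads = 3, seed = seed
  ))
}
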