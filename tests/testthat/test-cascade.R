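# Cascade thresholds, gating, triad assembly, and recovery of planted
# structure under favourable conditions.

test_that("loose steps use strict inequality and strict steps non-strict", {
  cfg <- cascade_config()
  expect_true(passes_threshold(0.04, cfg, strict = FALSE))
  expect_false(passes_threshold(0.05, cfg, strict = FALSE))  # tie fails loose
  expect_false(passes_threshold(0.06, cfg, strict = FALSE))
  expect_true(passes_threshold(1e-4, cfg, strict = TRUE))    # tie passes strict
  expect_false(passes_threshold(2e-4, cfg, strict = TRUE))
  expect_error(cascade_config(alpha_loose = 0.05, alpha_strict = 0.1),
               "alpha_strict")
})

test_that("minimal toy survivor sets join into exactly the expected triads", {
  rec1 <- data.frame(gene_id = "g1", p = 0.01)
  rec2 <- data.frame(mirna_id = "m1", p = 0.02)
  rec6 <- data.frame(snp_id = "s1", p = 1e-5)
  base <- list(
    s1 = list(survivors = "g1", records = rec1),
    s2 = list(survivors = "m1", records = rec2),
    s3 = list(pairs = data.frame(gene_id = "g1", mirna_id = "m1",
                                 p = 1e-5, r = -0.6, pass = TRUE)),
    s4 = list(pairs = data.frame(snp_id = "s1", gene_id = "g1",
                                 p = 2e-5, pass = TRUE)),
    s5 = list(pairs = data.frame(snp_id = "s1", mirna_id = "m1",
                                 p = 0.01, pass = TRUE)),
    s6 = list(survivors = "s1", records = rec6)
  )
  tri <- assemble_triads(list("10" = base), cascade_config())
  expect_identical(nrow(tri), 1L)
  expect_identical(tri$snp_id, "s1")
  expect_equal(tri$p_s1, 0.01)
  expect_equal(tri$p_s6, 1e-5)
  expect_equal(tri$r_s3, -0.6)

  # the join requires all six memberships: drop the step-5 pair
  no5 <- base
  no5$s5$pairs$pass <- FALSE
  expect_identical(nrow(assemble_triads(list("10" = no5), cascade_config())),
                   0L)
})

test_that("triad assembly equals the exhaustive cross-product join", {
  for (seed in 1:12) {
    inst <- make_step_instance(seed)
    got <- assemble_triads(list("5" = inst$steps), cascade_config())
    want <- oracle_triads(inst)
    expect_identical(triad_keys(got), triad_keys(want))
  }
})

test_that("unique summary deduplicates triads across concentrations", {
  tri <- data.frame(
    snp_id = c("s1", "s1", "s1"), mirna_id = c("m1", "m1", "m2"),
    gene_id = c("g1", "g1", "g1"), concentration = c(5, 7, 5),
    p_s1 = 0.01, p_s2 = 0.01, p_s3 = 1e-5, p_s4 = 1e-5, p_s5 = 0.01,
    p_s6 = 1e-5, r_s3 = -0.5
  )
  u <- summarize_unique(tri)
  expect_identical(u$n_unique_triads, 2L)  # (s1,m1,g1) at 5 and 7 uM counted once
  expect_identical(u$n_snps, 1L)
  expect_identical(u$n_genes, 1L)
  expect_identical(u$n_mirnas, 2L)
  expect_identical(u$per_concentration$n_triads, c(2L, 1L))
})

test_that("an empty early step propagates to empty downstream output", {
  co <- generate_null_cohort(cohort_spec(
    n_samples = 40, n_snps = 30, n_genes = 30, n_mirnas = 10, seed = 3
  ))
  cfg <- cascade_config(alpha_loose = 1e-6, alpha_strict = 1e-7)
  res <- run_cascade(co$genotypes, co$gene_expr, co$mirna_expr,
                     co$phenotypes, cfg)
  for (cc in names(res$steps)) {
    expect_length(res$steps[[cc]]$s1$survivors, 0)
    expect_identical(nrow(res$steps[[cc]]$s4$pairs), 0L)
    expect_length(res$steps[[cc]]$s6$survivors, 0)
  }
  expect_identical(nrow(res$triads), 0L)
  expect_identical(res$unique_summary$n_unique_triads, 0L)
})

test_that("survivor sets are nested along the cascade", {
  co <- small_planted_cohort(seed = 5)
  res <- run_cascade(co$genotypes, co$gene_expr, co$mirna_expr,
                     co$phenotypes)
  for (cc in names(res$steps)) {
    st <- res$steps[[cc]]
    expect_true(all(st$s3$genes %in% st$s1$survivors))
    expect_true(all(st$s3$mirnas %in% st$s2$survivors))
    expect_true(all(st$s4$genes %in% st$s3$genes))
    expect_true(all(st$s5$snps %in% st$s4$snps))
    expect_true(all(st$s5$mirnas %in% st$s3$mirnas))
    expect_true(all(st$s6$survivors %in% st$s5$snps))
  }
})

test_that("a single planted triad is carried through all six steps", {
  co <- generate_cohort(cohort_spec(
    n_samples = 500, n_snps = 100, n_genes = 100, n_mirnas = 30,
    n_planted_triads = 1, seed = 19
  ))
  res <- run_cascade(co$genotypes, co$gene_expr, co$mirna_expr,
                     co$phenotypes)
  tr <- co$truth
  top <- res$steps[[length(res$steps)]]
  expect_true(tr$gene_id %in% top$s1$survivors)
  expect_true(tr$mirna_id %in% top$s2$survivors)
  p3 <- top$s3$pairs
  expect_true(any(p3$pass & p3$gene_id == tr$gene_id &
                    p3$mirna_id == tr$mirna_id))
  p4 <- top$s4$pairs
  expect_true(any(p4$pass & p4$snp_id == tr$snp_id &
                    p4$gene_id == tr$gene_id))
  expect_true(tr$snp_id %in% top$s6$survivors)
  hits <- res$triads[res$triads$concentration ==
                       max(res$config$concentrations), ]
  expect_true(paste(tr$snp_id, tr$mirna_id, tr$gene_id) %in%
                paste(hits$snp_id, hits$mirna_id, hits$gene_id))
  # every reported triad honours the threshold contract
  expect_true(all(res$triads$p_s1 < 0.05 & res$triads$p_s2 < 0.05 &
                    res$triads$p_s5 < 0.05))
  expect_true(all(res$triads$p_s3 <= 1e-4 & res$triads$p_s4 <= 1e-4 &
                    res$triads$p_s6 <= 1e-4))
  expect_true(all(res$triads$r_s3 < 0))
})

test_that("monomorphic SNPs are flagged degenerate and never pass step 4", {
  co <- small_planted_cohort(seed = 2, n_samples = 80)
  co$genotypes[, 5] <- 1L   # force a monomorphic dosage column
  s4 <- step4_snp_gene(colnames(co$gene_expr)[1:3], co$gene_expr,
                       co$genotypes, cascade_config())
  mono <- s4$pairs[s4$pairs$snp_id == colnames(co$genotypes)[5], ]
  expect_true(all(mono$flag == "degenerate"))
  expect_false(any(mono$pass))
})

test_that("a MAF floor removes rare SNPs from the scan", {
  co <- small_planted_cohort(seed = 4, n_samples = 100)
  co$genotypes[, 7] <- c(1L, rep(0L, 99))   # maf 0.005
  cfg <- cascade_config(maf_floor = 0.05)
  res <- run_cascade(co$genotypes, co$gene_expr, co$mirna_expr,
                     co$phenotypes, cfg)
  rare <- colnames(co$genotypes)[7]
  for (cc in names(res$steps)) {
    expect_false(rare %in% res$steps[[cc]]$s4$pairs$snp_id)
  }
})

test_that("sample roster mismatches raise an error listing the samples", {
  co <- small_planted_cohort(seed = 6, n_samples = 40)
  bad <- co$gene_expr
  rownames(bad)[1] <- "intruder"
  expect_error(
    run_cascade(co$genotypes, bad, co$mirna_expr, co$phenotypes),
    "intruder"
  )
})
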