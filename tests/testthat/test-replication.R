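# Cross-cohort replication, allele-frequency screening and the cell-panel
# drug-response evaluation.

two_shared_cohorts <- function(n_b = 500) {
  # same planted structure (same seed for layout is not guaranteed across
  # specs, so regenerate cohort B by re-planting with a different noise seed
  # but identical spec dimensions and effect sizes)
  spec_a <- cohort_spec(n_samples = 500, n_snps = 60, n_genes = 60,
                        n_mirnas = 20, n_planted_triads = 3, seed = 41)
  a <- generate_cohort(spec_a)
  spec_b <- spec_a
  spec_b$n_samples <- n_b
  spec_b$seed <- 42
  b <- generate_cohort(spec_b)
  list(a = a, b = b)
}

test_that("planted genes and miRNAs replicate across independent cohorts", {
  # cohorts share effect sizes but not planted identities, so candidates are
  # taken from cohort B's own truth: replication regresses them against B's
  # phenotypes, which is the operation under test
  co <- two_shared_cohorts()
  b <- co$b
  cands <- rbind(
    data.frame(entity_id = b$truth$gene_id, entity_type = "gene"),
    data.frame(entity_id = b$truth$mirna_id, entity_type = "miRNA")
  )
  rep <- replicate_entities(cands, b$phenotypes, b$gene_expr, b$mirna_expr)
  expect_true(all(rep$replicated))
  expect_true(all(rep$status == "replicated"))
  expect_true(all(rep$replication_p < 0.05))
})

test_that("candidates absent from the replication cohort get a missing flag", {
  co <- two_shared_cohorts(n_b = 60)
  b <- co$b
  cands <- data.frame(entity_id = c("gene_99999", b$truth$gene_id[1]),
                      entity_type = "gene")
  rep <- replicate_entities(cands, b$phenotypes, b$gene_expr, b$mirna_expr)
  expect_identical(rep$status[1], "missing")
  expect_false(rep$replicated[1])
})

test_that("self-replication holds: cohort-A step-1 survivors replicate on A", {
  co <- small_planted_cohort(seed = 13, n_samples = 120)
  cfg <- cascade_config()
  s1 <- step1_pheno_gene(co$phenotypes, co$gene_expr, cfg)
  surv <- unique(unlist(lapply(s1, `[[`, "survivors")))
  cands <- data.frame(entity_id = surv, entity_type = "gene")
  rep <- replicate_entities(cands, co$phenotypes, co$gene_expr,
                            co$mirna_expr, cfg)
  expect_true(all(rep$replicated))
})

test_that("negative-pair replication needs r < 0 at the strict threshold", {
  withr::with_seed(8, {
    n <- 60
    m <- rnorm(n)
    g_strong <- -0.8 * m + rnorm(n, sd = 0.6)   # strongly negative
    g_weak <- -0.32 * m + rnorm(n, sd = 1)      # negative but weak
    g_pos <- 0.9 * m + rnorm(n, sd = 0.3)       # positive
  })
  ge <- cbind(gA = g_strong, gB = g_weak, gC = g_pos)
  rownames(ge) <- sprintf("s%02d", 1:n)
  me <- cbind(m1 = m)
  rownames(me) <- rownames(ge)
  pairs <- data.frame(gene_id = c("gA", "gB", "gC"), mirna_id = "m1")
  rep <- replicate_negative_pairs(pairs, ge, me)
  expect_true(rep$replicated[1])
  o <- oracle_pearson(g_strong, m)
  expect_lt(rel_diff(rep$p[1], o$p), 1e-10)
  expect_lte(rep$p[1], 1e-4)
  # weak pair: right sign but p above 1e-4
  expect_gt(rep$p[2], 1e-4)
  expect_false(rep$replicated[2])
  expect_false(rep$replicated[3])   # wrong sign regardless of p
})

test_that("allele-frequency screen flags >0.30 differences and is symmetric", {
  mk <- function(freqs, n = 200, seed = 1) {
    withr::with_seed(seed, {
      G <- vapply(freqs, function(f) stats::rbinom(n, 2, f), numeric(n))
      dimnames(G) <- list(sprintf("s%03d", 1:n),
                          sprintf("rs%d", seq_along(freqs)))
      G
    })
  }
  ga <- mk(c(0.8, 0.5, 0.2), seed = 1)
  gb <- mk(c(0.4, 0.5, 0.25), seed = 2)
  scr <- allele_frequency_screen(ga, gb)
  expect_true(scr$flagged[1])     # ~0.40 apart
  expect_false(scr$flagged[2])    # identical frequencies
  expect_false(scr$flagged[3])
  rev <- allele_frequency_screen(gb, ga)
  expect_equal(rev$abs_diff, scr$abs_diff, tolerance = 1e-12)
  expect_identical(rev$flagged, scr$flagged)
})

test_that("swapped allele coding is auto-harmonised; ambiguous pairs excluded", {
  n <- 400
  withr::with_seed(3, {
    ga <- cbind(rs1 = stats::rbinom(n, 2, 0.8), rs2 = stats::rbinom(n, 2, 0.8))
    # cohort B measured the same populations but coded the other allele
    gb <- cbind(rs1 = 2L - stats::rbinom(n, 2, 0.8),
                rs2 = 2L - stats::rbinom(n, 2, 0.8))
  })
  rownames(ga) <- rownames(gb) <- sprintf("s%03d", 1:n)
  alleles_a <- data.frame(snp_id = c("rs1", "rs2"),
                          coded = c("G", "A"), other = c("A", "T"))
  alleles_b <- data.frame(snp_id = c("rs1", "rs2"),
                          coded = c("A", "T"), other = c("G", "A"))
  warns <- capture_warnings(
    scr <- allele_frequency_screen(ga, gb, alleles_a = alleles_a,
                                   alleles_b = alleles_b)
  )
  expect_match(warns, "opposite allele", all = FALSE)
  expect_match(warns, "strand-ambiguous", all = FALSE)
  # rs1: swap detected and harmonised -> frequencies agree, no flag
  expect_identical(scr$status[1], "swapped")
  expect_lt(scr$abs_diff[1], 0.1)
  expect_false(scr$flagged[1])
  # rs2 is A/T: strand-ambiguous mismatch must be excluded
  expect_identical(scr$status[2], "excluded")
  expect_false(scr$flagged[2])
})

test_that("GI50 evaluation correlates expression with -log10(GI50)", {
  withr::with_seed(14, {
    gi50 <- 10^runif(44, -8, -5)          # molar
    expr <- cbind(
      exact = -log10(gi50),
      assoc = -log10(gi50) + rnorm(44, sd = 0.4),
      noise = rnorm(44)
    )
  })
  rownames(expr) <- sprintf("line%02d", 1:44)
  names(gi50) <- rownames(expr)
  ev <- evaluate_vs_gi50(c("exact", "assoc", "noise", "absent"), expr, gi50)
  expect_equal(ev$r[1], 1)
  expect_true(ev$pass[1])
  o <- oracle_pearson(expr[, "assoc"], -log10(gi50))
  expect_lt(rel_diff(ev$p[2], o$p), 1e-10)
  expect_lt(rel_diff(ev$r[2], o$r), 1e-10)
  expect_identical(ev$status[4], "missing")
  expect_false(ev$pass[4])
})

test_that("GI50 pass rate on shuffled expression is near the nominal 0.05", {
  withr::with_seed(23, {
    gi50 <- 10^runif(44, -8, -5)
    expr <- matrix(rnorm(44 * 400), 44, 400,
                   dimnames = list(sprintf("line%02d", 1:44),
                                   sprintf("g%03d", 1:400)))
  })
  names(gi50) <- rownames(expr)
  ev <- evaluate_vs_gi50(colnames(expr), expr, gi50)
  band <- 2 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(ev$pass) - 0.05), band)
})
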