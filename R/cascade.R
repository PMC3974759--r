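# The six-step sequential association cascade and triad assembly.
#
# Per concentration, independently:
#   S1 gene ~ phenotype        (p < alpha_loose)
#   S2 miRNA ~ phenotype       (p < alpha_loose)
#   S3 gene ~ miRNA, r < 0     (p <= alpha_strict)
#   S4 gene ~ SNP (additive)   (p <= alpha_strict)
#   S5 miRNA ~ SNP (additive)  (p < alpha_loose)
#   S6 phenotype ~ SNP         (p <= alpha_strict)
# Final triads are (SNP, miRNA, gene) tuples passing all six memberships.
# Loose steps use a strict inequality (p < 0.05) and strict steps a
# non-strict one (p <= 1e-4), following the thresholds' typography;
# concentrations are processed fully independently and then unioned.

#' Cascade configuration
#'
#' @param alpha_loose Threshold for steps 1, 2 and 5 (entities pass when
#'   `p < alpha_loose`).
#' @param alpha_strict Threshold for steps 3, 4 and 6 (entities pass when
#'   `p <= alpha_strict`).
#' @param concentrations Ordered dose list the cascade iterates over.
#' @param maf_floor Optional minimum minor-allele frequency for SNPs entering
#'   genotype steps; `0` (default) applies no filter.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(alpha_loose = 0.05, alpha_strict = 1e-4,
                           concentrations = c(3, 5, 7, 10),
                           maf_floor = 0) {
  if (!(alpha_strict > 0 && alpha_strict <= alpha_loose &&
        alpha_loose < 1)) {
    stop("cascade_config requires 0 < alpha_strict <= alpha_loose < 1",
         call. = FALSE)
  }
  structure(
    list(alpha_loose = alpha_loose, alpha_strict = alpha_strict,
         concentrations = as.numeric(concentrations),
         maf_floor = maf_floor),
    class = "cascade_config"
  )
}

#' Threshold predicate of the cascade
#'
#' Loose steps (1, 2, 5) pass on `p < alpha_loose`; strict steps (3, 4, 6)
#' pass on `p <= alpha_strict`. Ties at exactly the threshold therefore fail
#' the loose test and pass the strict one.
#'
#' @param p P-value(s).
#' @param cfg A [cascade_config].
#' @param strict Use the strict threshold?
#' @return Logical vector.
#' @export
passes_threshold <- function(p, cfg, strict = FALSE) {
  if (strict) !is.na(p) & p <= cfg$alpha_strict
  else !is.na(p) & p < cfg$alpha_loose
}

usable <- function(records) records$flag %in% c("ok", "perfect_fit")

empty_pairs <- function(a, b) {
  out <- data.frame(x = character(0), y = character(0), n = integer(0),
                    beta = numeric(0), r = numeric(0), p = numeric(0),
                    flag = character(0), pass = logical(0),
                    stringsAsFactors = FALSE)
  names(out)[1:2] <- c(a, b)
  out
}

# single-concentration feature scan (steps 1, 2, 6 share this shape)
scan_features <- function(X, y, id_col, cfg, strict) {
  rec <- slope_scan(X, y)
  rec$pass <- usable(rec) & passes_threshold(rec$p, cfg, strict = strict)
  names(rec)[names(rec) == "x_id"] <- id_col
  list(survivors = rec[[id_col]][rec$pass], records = rec)
}

#' Step 1: phenotype ~ gene expression screen
#'
#' Regresses each concentration's log phenotype on every gene; genes with
#' `p < alpha_loose` survive.
#'
#' @param pheno A [phenotype_table].
#' @param genes Gene expression matrix (samples x genes), rownames matching
#'   the phenotype roster.
#' @param cfg A [cascade_config].
#' @return Named list (one element per concentration) of
#'   `list(survivors, records)`.
#' @export
step1_pheno_gene <- function(pheno, genes, cfg) {
  genes <- align_to_pheno(genes, pheno, "gene expression")
  out <- lapply(seq_along(pheno$concentrations), function(cc) {
    scan_features(genes, pheno$log_pheno[, cc], "gene_id", cfg,
                  strict = FALSE)
  })
  names(out) <- as.character(pheno$concentrations)
  out
}

#' Step 2: phenotype ~ miRNA expression screen
#'
#' @inheritParams step1_pheno_gene
#' @param mirnas miRNA expression matrix (samples x miRNAs).
#' @return Named per-concentration list of `list(survivors, records)`.
#' @export
step2_pheno_mirna <- function(pheno, mirnas, cfg) {
  mirnas <- align_to_pheno(mirnas, pheno, "miRNA expression")
  out <- lapply(seq_along(pheno$concentrations), function(cc) {
    scan_features(mirnas, pheno$log_pheno[, cc], "mirna_id", cfg,
                  strict = FALSE)
  })
  names(out) <- as.character(pheno$concentrations)
  out
}

#' Step 3: negatively correlated (gene, miRNA) pairs
#'
#' Tests every surviving gene against every surviving miRNA; a pair passes
#' when Pearson r < 0 and `p <= alpha_strict` (the repressive-regulation sign
#' gate). Genes/miRNAs appearing in at least one passing pair survive.
#'
#' @param genes_s1 Character vector of step-1 surviving gene ids (one
#'   concentration).
#' @param mirnas_s2 Step-2 surviving miRNA ids.
#' @param gene_expr,mirna_expr Expression matrices on a shared roster.
#' @param cfg A [cascade_config].
#' @return `list(pairs, genes, mirnas)`; `pairs` has columns
#'   `gene_id, mirna_id, n, beta, r, p, flag, pass`.
#' @export
step3_negative_pairs <- function(genes_s1, mirnas_s2, gene_expr, mirna_expr,
                                 cfg) {
  if (length(genes_s1) == 0 || length(mirnas_s2) == 0) {
    return(list(pairs = empty_pairs("gene_id", "mirna_id"),
                genes = character(0), mirnas = character(0)))
  }
  Xg <- gene_expr[, genes_s1, drop = FALSE]
  pairs <- do.call(rbind, lapply(mirnas_s2, function(m) {
    rec <- slope_scan(Xg, mirna_expr[, m])
    rec$pass <- usable(rec) & !is.na(rec$r) & rec$r < 0 &
      passes_threshold(rec$p, cfg, strict = TRUE)
    data.frame(gene_id = rec$x_id, mirna_id = m,
               rec[, c("n", "beta", "r", "p", "flag", "pass")],
               stringsAsFactors = FALSE)
  }))
  ok <- pairs[pairs$pass, , drop = FALSE]
  list(pairs = pairs,
       genes = sort(unique(ok$gene_id)),
       mirnas = sort(unique(ok$mirna_id)))
}

# shared SNP-vs-feature scan for steps 4 and 5
scan_snp_pairs <- function(features, expr, genotypes, snp_subset, feat_col,
                           cfg, strict) {
  if (length(features) == 0 || length(snp_subset) == 0) {
    return(empty_pairs("snp_id", feat_col))
  }
  Xs <- genotypes[, snp_subset, drop = FALSE]
  do.call(rbind, lapply(features, function(f) {
    rec <- slope_scan(Xs, expr[, f])
    rec$pass <- usable(rec) & passes_threshold(rec$p, cfg, strict = strict)
    out <- data.frame(snp_id = rec$x_id, feat = f,
                      rec[, c("n", "beta", "r", "p", "flag", "pass")],
                      stringsAsFactors = FALSE)
    names(out)[names(out) == "feat"] <- feat_col
    out
  }))
}

#' Step 4: eQTL scan of step-3 genes against all SNPs
#'
#' Additive-model regression of each surviving gene's expression on every SNP
#' dosage; pairs pass at `p <= alpha_strict`. Degenerate (monomorphic) SNPs
#' are flagged, never passed, and never abort the scan.
#'
#' @param genes_s3 Step-3 surviving gene ids (one concentration).
#' @param gene_expr Gene expression matrix.
#' @param genotypes Dosage matrix (samples x SNPs, entries 0/1/2/NA).
#' @param cfg A [cascade_config].
#' @param snp_subset Optional SNP ids to restrict the scan to (default: all).
#' @return `list(pairs, snps, genes)`.
#' @export
step4_snp_gene <- function(genes_s3, gene_expr, genotypes, cfg,
                           snp_subset = colnames(genotypes)) {
  pairs <- scan_snp_pairs(genes_s3, gene_expr, genotypes, snp_subset,
                          "gene_id", cfg, strict = TRUE)
  ok <- pairs[pairs$pass, , drop = FALSE]
  list(pairs = pairs,
       snps = sort(unique(ok$snp_id)),
       genes = sort(unique(ok$gene_id)))
}

#' Step 5: miR-QTL scan of step-3 miRNAs against step-4 SNPs
#'
#' @param snps_s4 Step-4 surviving SNP ids.
#' @param mirnas_s3 Step-3 surviving miRNA ids.
#' @param mirna_expr miRNA expression matrix.
#' @param genotypes Dosage matrix.
#' @param cfg A [cascade_config].
#' @return `list(pairs, snps, mirnas)`; pairs pass at the loose threshold
#'   (`p < alpha_loose`).
#' @export
step5_snp_mirna <- function(snps_s4, mirnas_s3, mirna_expr, genotypes, cfg) {
  pairs <- scan_snp_pairs(mirnas_s3, mirna_expr, genotypes, snps_s4,
                          "mirna_id", cfg, strict = FALSE)
  ok <- pairs[pairs$pass, , drop = FALSE]
  list(pairs = pairs,
       snps = sort(unique(ok$snp_id)),
       mirnas = sort(unique(ok$mirna_id)))
}

#' Step 6: genome-wide association of step-5 SNPs with the phenotype
#'
#' @param snps_s5 Step-5 surviving SNP ids.
#' @param genotypes Dosage matrix.
#' @param pheno A [phenotype_table].
#' @param concentration The dose being analysed.
#' @param cfg A [cascade_config].
#' @return `list(survivors, records)`; SNPs pass at `p <= alpha_strict`.
#' @export
step6_snp_pheno <- function(snps_s5, genotypes, pheno, concentration, cfg) {
  if (length(snps_s5) == 0) {
    rec <- slope_scan(matrix(numeric(0), nrow(genotypes), 0),
                      pheno$log_pheno[, as.character(concentration)])
    return(list(survivors = character(0),
                records = cbind(data.frame(snp_id = character(0)),
                                rec[, -1, drop = FALSE],
                                pass = logical(0))))
  }
  y <- pheno$log_pheno[, as.character(concentration)]
  scan_features(genotypes[, snps_s5, drop = FALSE], y, "snp_id", cfg,
                strict = TRUE)
}

#' Assemble (SNP, miRNA, gene) triads from the six step outputs
#'
#' A triad `(s, m, g)` at a concentration requires: `g` passed step 1, `m`
#' passed step 2, `(g, m)` passed step 3, `(s, g)` passed step 4, `(s, m)`
#' passed step 5 and `s` passed step 6. All six step p-values (and the
#' step-3 correlation) are attached.
#'
#' @param steps Named list (per concentration) of the step outputs, each a
#'   list with elements `s1 ... s6` as returned by the step functions.
#' @param cfg A [cascade_config].
#' @return Data.frame with one row per triad-concentration:
#'   `snp_id, mirna_id, gene_id, concentration, p_s1 ... p_s6, r_s3`.
#' @export
assemble_triads <- function(steps, cfg) {
  out <- lapply(names(steps), function(conc) {
    st <- steps[[conc]]
    p3 <- st$s3$pairs[st$s3$pairs$pass, c("gene_id", "mirna_id", "p", "r"),
                      drop = FALSE]
    p4 <- st$s4$pairs[st$s4$pairs$pass, c("snp_id", "gene_id", "p"),
                      drop = FALSE]
    p5 <- st$s5$pairs[st$s5$pairs$pass, c("snp_id", "mirna_id", "p"),
                      drop = FALSE]
    if (nrow(p3) == 0 || nrow(p4) == 0 || nrow(p5) == 0 ||
        length(st$s6$survivors) == 0) {
      return(NULL)
    }
    names(p3)[3:4] <- c("p_s3", "r_s3")
    names(p4)[3] <- "p_s4"
    names(p5)[3] <- "p_s5"
    tri <- merge(p3, p4, by = "gene_id")
    tri <- merge(tri, p5, by = c("snp_id", "mirna_id"))
    tri <- tri[tri$snp_id %in% st$s6$survivors &
                 tri$gene_id %in% st$s1$survivors &
                 tri$mirna_id %in% st$s2$survivors, , drop = FALSE]
    if (nrow(tri) == 0) return(NULL)
    lookup <- function(records, id_col, ids) {
      records$p[match(ids, records[[id_col]])]
    }
    tri$p_s1 <- lookup(st$s1$records, "gene_id", tri$gene_id)
    tri$p_s2 <- lookup(st$s2$records, "mirna_id", tri$mirna_id)
    tri$p_s6 <- lookup(st$s6$records, "snp_id", tri$snp_id)
    tri$concentration <- as.numeric(conc)
    tri[, c("snp_id", "mirna_id", "gene_id", "concentration",
            "p_s1", "p_s2", "p_s3", "p_s4", "p_s5", "p_s6", "r_s3")]
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(
      snp_id = character(0), mirna_id = character(0), gene_id = character(0),
      concentration = numeric(0), p_s1 = numeric(0), p_s2 = numeric(0),
      p_s3 = numeric(0), p_s4 = numeric(0), p_s5 = numeric(0),
      p_s6 = numeric(0), r_s3 = numeric(0), stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$concentration, out$snp_id, out$mirna_id, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deduplicated summary of triads across concentrations
#'
#' A triad found at several concentrations is one unique association.
#'
#' @param triads Triad data.frame from [assemble_triads].
#' @return List with `n_unique_triads`, `n_snps`, `n_genes`, `n_mirnas` and a
#'   `per_concentration` data.frame of per-dose counts.
#' @export
summarize_unique <- function(triads) {
  key <- paste(triads$snp_id, triads$mirna_id, triads$gene_id, sep = "\r")
  per_conc <- if (nrow(triads)) {
    do.call(rbind, lapply(split(triads, triads$concentration), function(d) {
      data.frame(concentration = d$concentration[1], n_triads = nrow(d),
                 n_snps = length(unique(d$snp_id)),
                 n_genes = length(unique(d$gene_id)),
                 n_mirnas = length(unique(d$mirna_id)))
    }))
  } else {
    data.frame(concentration = numeric(0), n_triads = integer(0),
               n_snps = integer(0), n_genes = integer(0),
               n_mirnas = integer(0))
  }
  rownames(per_conc) <- NULL
  list(
    n_unique_triads = length(unique(key)),
    n_snps = length(unique(triads$snp_id)),
    n_genes = length(unique(triads$gene_id)),
    n_mirnas = length(unique(triads$mirna_id)),
    per_concentration = per_conc
  )
}

align_to_pheno <- function(mat, pheno, what) {
  ids <- align_roster(pheno$samples, rownames(mat), what)
  mat[ids, , drop = FALSE]
}

#' Run the full six-step cascade
#'
#' Executes steps 1-6 independently for every concentration of the phenotype
#' table, assembles triads, and summarises unique associations across doses.
#' Sample rosters are aligned by identifier (never by position); a roster
#' mismatch raises an error listing the offending samples.
#'
#' @param genotypes Dosage matrix (samples x SNPs, 0/1/2/NA) with sample
#'   rownames.
#' @param gene_expr,mirna_expr Expression matrices with sample rownames.
#' @param pheno A [phenotype_table].
#' @param cfg A [cascade_config]; its `concentrations` must match the
#'   phenotype table's.
#' @return An object of class `cascade_result`: list with `steps` (per
#'   concentration step outputs), `triads`, `unique_summary` and `config`.
#' @export
run_cascade <- function(genotypes, gene_expr, mirna_expr, pheno,
                        cfg = cascade_config()) {
  stopifnot(inherits(pheno, "phenotype_table"))
  if (!isTRUE(all.equal(as.numeric(cfg$concentrations),
                        as.numeric(pheno$concentrations)))) {
    stop("cascade_config concentrations do not match the phenotype table",
         call. = FALSE)
  }
  genotypes <- align_to_pheno(genotypes, pheno, "genotypes")
  gene_expr <- align_to_pheno(gene_expr, pheno, "gene expression")
  mirna_expr <- align_to_pheno(mirna_expr, pheno, "miRNA expression")

  if (cfg$maf_floor > 0) {
    f <- allele_freq(genotypes)
    keep <- pmin(f, 1 - f) >= cfg$maf_floor
    genotypes <- genotypes[, keep, drop = FALSE]
  }

  s1_all <- step1_pheno_gene(pheno, gene_expr, cfg)
  s2_all <- step2_pheno_mirna(pheno, mirna_expr, cfg)

  steps <- lapply(as.character(pheno$concentrations), function(conc) {
    s1 <- s1_all[[conc]]
    s2 <- s2_all[[conc]]
    s3 <- step3_negative_pairs(s1$survivors, s2$survivors,
                               gene_expr, mirna_expr, cfg)
    s4 <- step4_snp_gene(s3$genes, gene_expr, genotypes, cfg)
    s5 <- step5_snp_mirna(s4$snps, s3$mirnas, mirna_expr, genotypes, cfg)
    s6 <- step6_snp_pheno(s5$snps, genotypes, pheno, conc, cfg)
    list(s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5, s6 = s6)
  })
  names(steps) <- as.character(pheno$concentrations)

  triads <- assemble_triads(steps, cfg)
  structure(
    list(steps = steps, triads = triads,
         unique_summary = summarize_unique(triads), config = cfg),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  u <- x$unique_summary
  cat(sprintf(
    paste0("cascade_result: %d triad-concentration hits; %d unique triads ",
           "(%d SNPs, %d genes, %d miRNAs) across %d doses\n"),
    nrow(x$triads), u$n_unique_triads, u$n_snps, u$n_genes, u$n_mirnas,
    length(x$steps)
  ))
  invisible(x)
}

#' Per-step survivor counts, one row per step entity, one column per dose
#'
#' Convenience summary mirroring how cascade results are usually tabulated.
#'
#' @param result A `cascade_result`.
#' @return Data.frame of survivor counts by step and concentration.
#' @export
cascade_step_counts <- function(result) {
  concs <- names(result$steps)
  rows <- list(
    c("step1_genes", vapply(concs, function(cc)
      length(result$steps[[cc]]$s1$survivors), numeric(1))),
    c("step2_mirnas", vapply(concs, function(cc)
      length(result$steps[[cc]]$s2$survivors), numeric(1))),
    c("step3_genes", vapply(concs, function(cc)
      length(result$steps[[cc]]$s3$genes), numeric(1))),
    c("step3_mirnas", vapply(concs, function(cc)
      length(result$steps[[cc]]$s3$mirnas), numeric(1))),
    c("step4_snps", vapply(concs, function(cc)
      length(result$steps[[cc]]$s4$snps), numeric(1))),
    c("step5_snps", vapply(concs, function(cc)
      length(result$steps[[cc]]$s5$snps), numeric(1))),
    c("step6_snps", vapply(concs, function(cc)
      length(result$steps[[cc]]$s6$survivors), numeric(1))),
    c("final_triads", vapply(concs, function(cc)
      sum(result$triads$concentration == as.numeric(cc)), numeric(1)))
  )
  out <- data.frame(step = vapply(rows, `[`, character(1), 1),
                    stringsAsFactors = FALSE)
  for (j in seq_along(concs)) {
    out[[paste0(concs[j], "uM")]] <-
      as.integer(vapply(rows, function(r) as.numeric(r[j + 1]), numeric(1)))
  }
  out
}
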