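# Cross-cohort triage of discovered markers: replication of entity-phenotype
# associations in a second cohort, strict replication of negative gene-miRNA
# pairs, allele-frequency-difference screening, and candidate evaluation
# against an independent drug-response panel.

#' Replicate gene/miRNA-phenotype associations in a second cohort
#'
#' Each candidate is regressed against every concentration phenotype of the
#' replication cohort; it replicates if any concentration gives
#' `p < alpha_loose` (the replicating concentration is recorded). Features
#' absent from the replication cohort are reported as missing, not fatal.
#'
#' @param candidates Data.frame with columns `entity_id`,
#'   `entity_type` (`"gene"` or `"miRNA"`), and optionally `discovery_p`.
#' @param pheno_b Replication-cohort [phenotype_table].
#' @param gene_expr_b,mirna_expr_b Replication-cohort expression matrices.
#' @param cfg A [cascade_config].
#' @return Data.frame: `entity_id, entity_type, discovery_p, replication_p,
#'   replication_concentration, replicated, status`.
#' @export
replicate_entities <- function(candidates, pheno_b, gene_expr_b,
                               mirna_expr_b, cfg = cascade_config()) {
  stopifnot(all(c("entity_id", "entity_type") %in% names(candidates)))
  gene_expr_b <- align_to_pheno(gene_expr_b, pheno_b, "gene expression (B)")
  mirna_expr_b <- align_to_pheno(mirna_expr_b, pheno_b, "miRNA expression (B)")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    id <- candidates$entity_id[i]
    type <- candidates$entity_type[i]
    mat <- if (type == "gene") gene_expr_b else mirna_expr_b
    disc <- if ("discovery_p" %in% names(candidates))
      candidates$discovery_p[i] else NA_real_
    if (!id %in% colnames(mat)) {
      return(data.frame(entity_id = id, entity_type = type,
                        discovery_p = disc, replication_p = NA_real_,
                        replication_concentration = NA_real_,
                        replicated = FALSE, status = "missing",
                        stringsAsFactors = FALSE))
    }
    recs <- do.call(rbind, lapply(seq_along(pheno_b$concentrations),
                                  function(cc) {
      fit_slope(mat[, id], pheno_b$log_pheno[, cc], x_id = id,
                y_id = as.character(pheno_b$concentrations[cc]))
    }))
    best <- which.min(recs$p)
    rep_ok <- any(passes_threshold(recs$p, cfg, strict = FALSE) &
                    usable(recs))
    data.frame(entity_id = id, entity_type = type, discovery_p = disc,
               replication_p = recs$p[best],
               replication_concentration =
                 pheno_b$concentrations[best],
               replicated = rep_ok,
               status = if (rep_ok) "replicated" else "NS",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replicate negative gene-miRNA correlations in a second cohort
#'
#' A pair replicates only with the discovery-stage contract intact: Pearson
#' r < 0 and `p <= alpha_strict` in the replication cohort.
#'
#' @param pairs Data.frame with columns `gene_id`, `mirna_id`.
#' @param gene_expr_b,mirna_expr_b Replication-cohort expression matrices on
#'   a shared roster.
#' @param cfg A [cascade_config].
#' @return Data.frame: `gene_id, mirna_id, n, r, p, replicated, status`.
#' @export
replicate_negative_pairs <- function(pairs, gene_expr_b, mirna_expr_b,
                                     cfg = cascade_config()) {
  stopifnot(all(c("gene_id", "mirna_id") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene_id[i]
    m <- pairs$mirna_id[i]
    if (!g %in% colnames(gene_expr_b) || !m %in% colnames(mirna_expr_b)) {
      return(data.frame(gene_id = g, mirna_id = m, n = NA_integer_,
                        r = NA_real_, p = NA_real_, replicated = FALSE,
                        status = "missing", stringsAsFactors = FALSE))
    }
    rec <- pearson_with_sign(gene_expr_b[, g], mirna_expr_b[, m],
                             required_sign = "negative",
                             alpha = cfg$alpha_strict, x_id = g, y_id = m)
    data.frame(gene_id = g, mirna_id = m, n = rec$n, r = rec$r, p = rec$p,
               replicated = rec$pass,
               status = if (rec$pass) "replicated" else "NS",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_strand_ambiguous <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "CG", "GC")
}

#' Allele-frequency-difference screen between two cohorts
#'
#' Compares the coded-allele frequency of each SNP between cohorts, flagging
#' SNPs whose absolute difference exceeds `threshold` (population-specific
#' marker candidates). When per-SNP allele labels are supplied, swapped
#' ref/alt coding in cohort B is detected (directly or through the strand
#' complement) and auto-harmonised with a warning; strand-ambiguous (A/T,
#' C/G) mismatches cannot be resolved and are excluded with a warning.
#'
#' @param genotypes_a,genotypes_b Dosage matrices for the two cohorts.
#' @param snp_list SNP ids to compare (default: those shared).
#' @param alleles_a,alleles_b Optional data.frames with columns
#'   `snp_id`, `coded`, `other` describing each cohort's allele coding.
#' @param threshold Flagging threshold on the absolute frequency difference
#'   (default 0.30).
#' @return Data.frame: `snp_id, freq_a, freq_b, abs_diff, flagged, status`
#'   with status in `ok`/`swapped`/`excluded`/`missing`.
#' @export
allele_frequency_screen <- function(genotypes_a, genotypes_b,
                                    snp_list = NULL,
                                    alleles_a = NULL, alleles_b = NULL,
                                    threshold = 0.30) {
  if (is.null(snp_list)) {
    snp_list <- intersect(colnames(genotypes_a), colnames(genotypes_b))
  }
  fa_all <- allele_freq(genotypes_a)
  fb_all <- allele_freq(genotypes_b)
  rows <- lapply(snp_list, function(s) {
    if (!s %in% colnames(genotypes_a) || !s %in% colnames(genotypes_b)) {
      return(data.frame(snp_id = s, freq_a = NA_real_, freq_b = NA_real_,
                        abs_diff = NA_real_, flagged = FALSE,
                        status = "missing", stringsAsFactors = FALSE))
    }
    fa <- unname(fa_all[s])
    fb <- unname(fb_all[s])
    status <- "ok"
    if (!is.null(alleles_a) && !is.null(alleles_b)) {
      aa <- alleles_a[alleles_a$snp_id == s, , drop = FALSE]
      ab <- alleles_b[alleles_b$snp_id == s, , drop = FALSE]
      if (nrow(aa) == 1 && nrow(ab) == 1) {
        same <- ab$coded == aa$coded && ab$other == aa$other
        comp_same <- ab$coded == COMPLEMENT[[aa$coded]] &&
          ab$other == COMPLEMENT[[aa$other]]
        swapped <- ab$coded == aa$other && ab$other == aa$coded
        comp_swapped <- ab$coded == COMPLEMENT[[aa$other]] &&
          ab$other == COMPLEMENT[[aa$coded]]
        ambiguous <- is_strand_ambiguous(aa$coded, aa$other)
        if (same) {
          status <- "ok"
        } else if (ambiguous) {
          warning(sprintf(
            "SNP %s: strand-ambiguous (%s/%s) allele mismatch; excluded",
            s, aa$coded, aa$other), call. = FALSE)
          return(data.frame(snp_id = s, freq_a = fa, freq_b = NA_real_,
                            abs_diff = NA_real_, flagged = FALSE,
                            status = "excluded", stringsAsFactors = FALSE))
        } else if (swapped || comp_swapped) {
          warning(sprintf(
            "SNP %s: cohort B coded on the opposite allele; harmonised", s),
            call. = FALSE)
          fb <- 1 - fb
          status <- "swapped"
        } else if (comp_same) {
          status <- "ok"
        } else {
          warning(sprintf("SNP %s: irreconcilable allele labels; excluded", s),
                  call. = FALSE)
          return(data.frame(snp_id = s, freq_a = fa, freq_b = NA_real_,
                            abs_diff = NA_real_, flagged = FALSE,
                            status = "excluded", stringsAsFactors = FALSE))
        }
      }
    }
    d <- abs(fa - fb)
    data.frame(snp_id = s, freq_a = fa, freq_b = fb, abs_diff = d,
               flagged = d > threshold, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate candidate gene expression with drug response in a cell panel
#'
#' Per candidate gene, Pearson correlation of panel expression with
#' `-log10(GI50)` (larger = more sensitive); the raw GI50 input is
#' transformed internally. Pass flag at `p < alpha`.
#'
#' @param candidate_genes Gene ids to evaluate.
#' @param panel_expression Expression matrix (cell lines x genes).
#' @param panel_gi50 Named numeric vector of raw GI50 values (molar), names
#'   matching `rownames(panel_expression)`.
#' @param alpha Pass threshold (default 0.05, strict inequality).
#' @return Data.frame: `gene_id, n, r, p, pass, status`.
#' @export
evaluate_vs_gi50 <- function(candidate_genes, panel_expression, panel_gi50,
                             alpha = 0.05) {
  roster <- align_roster(rownames(panel_expression), names(panel_gi50),
                         "GI50 panel")
  y <- -log10(panel_gi50[roster])
  rows <- lapply(candidate_genes, function(g) {
    if (!g %in% colnames(panel_expression)) {
      return(data.frame(gene_id = g, n = NA_integer_, r = NA_real_,
                        p = NA_real_, pass = FALSE, status = "missing",
                        stringsAsFactors = FALSE))
    }
    rec <- fit_slope(panel_expression[roster, g], y, x_id = g,
                     y_id = "-log10(GI50)")
    ok <- rec$flag %in% c("ok", "perfect_fit") & !is.na(rec$p) &
      rec$p < alpha
    data.frame(gene_id = g, n = rec$n, r = rec$r, p = rec$p, pass = ok,
               status = "tested", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
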