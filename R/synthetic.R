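# Synthetic multi-omic cohort generator with planted (SNP, miRNA, gene,
# phenotype) structure.
#
# Effect semantics: each planted effect is the MARGINAL pairwise slope of the
# corresponding cascade test in the generating population --
#   slope(miRNA ~ z)    = effect_qtl_mirna
#   slope(gene  ~ z)    = effect_qtl_gene
#   slope(gene  ~ miRNA)= effect_mirna_gene
#   slope(log-pheno ~ gene) = effect_gene_pheno * dose_scaling[c]
# where z is the standardised additive dosage. Internal path coefficients are
# calibrated accordingly (see the methods vignette): planting marginal slopes
# makes "planted effect" exactly the quantity each univariate step estimates,
# and avoids the cancellation between the direct SNP->gene path and the
# repressive SNP->miRNA->gene path that a naive structural parameterisation
# would induce.

#' Specification of a synthetic multi-omic cohort
#'
#' Defaults emulate the structure of the real study cohort at desk scale:
#' 58 samples, thousands of genes, ~201 expressed miRNAs, genome-wide
#' biallelic SNPs, and four dose phenotypes (3, 5, 7, 10 uM) whose
#' planted effect scale grows with concentration.
#'
#' @param n_samples,n_snps,n_genes,n_mirnas Cohort dimensions.
#' @param concentrations Dose values (uM).
#' @param n_planted_triads Number of planted (SNP, miRNA, gene) triads.
#' @param effect_qtl_gene Marginal standardised slope of SNP dosage on its
#'   planted gene's expression.
#' @param effect_qtl_mirna Marginal standardised slope of SNP dosage on its
#'   planted miRNA's expression.
#' @param effect_mirna_gene Marginal slope of gene expression on miRNA
#'   expression; must be negative (repressive regulation) to be discoverable
#'   by the cascade's sign gate.
#' @param effect_gene_pheno Marginal slope of log-viability on gene
#'   expression, before dose scaling.
#' @param dose_scaling Per-concentration multiplier on the phenotype effect;
#'   increases with dose by default, so inter-individual spread grows with
#'   concentration.
#' @param noise_sd Residual standard deviation of every generated equation.
#' @param maf_range Interval in (0, 0.5] for the uniform per-SNP minor allele
#'   frequency.
#' @param baseline_percent Per-concentration median percent viability of the
#'   noise-only phenotype (declines with dose).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 58, n_snps = 5000, n_genes = 2000,
                        n_mirnas = 201, concentrations = c(3, 5, 7, 10),
                        n_planted_triads = 5,
                        effect_qtl_gene = 0.8, effect_qtl_mirna = 0.8,
                        effect_mirna_gene = -0.8, effect_gene_pheno = 0.8,
                        dose_scaling = c(0.5, 0.75, 1, 1.25),
                        noise_sd = 1, maf_range = c(0.05, 0.5),
                        baseline_percent = c(88, 77, 66, 56),
                        seed = 1) {
  spec <- structure(
    list(
      n_samples = n_samples, n_snps = n_snps, n_genes = n_genes,
      n_mirnas = n_mirnas, concentrations = concentrations,
      n_planted_triads = n_planted_triads,
      effect_qtl_gene = effect_qtl_gene,
      effect_qtl_mirna = effect_qtl_mirna,
      effect_mirna_gene = effect_mirna_gene,
      effect_gene_pheno = effect_gene_pheno,
      dose_scaling = dose_scaling, noise_sd = noise_sd,
      maf_range = maf_range, baseline_percent = baseline_percent,
      seed = seed
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' @param spec A `cohort_spec`.
#' @return The spec, invisibly; otherwise a configuration error naming the
#'   violated invariant.
#' @export
validate_cohort_spec <- function(spec) {
  for (f in c("n_samples", "n_snps", "n_genes", "n_mirnas")) {
    assert_count(spec[[f]], f)
  }
  if (!is.numeric(spec$n_planted_triads) || spec$n_planted_triads < 0 ||
      spec$n_planted_triads != floor(spec$n_planted_triads)) {
    stop("invalid CohortSpec: 'n_planted_triads' must be a non-negative integer",
         call. = FALSE)
  }
  if (spec$n_planted_triads >
      min(spec$n_snps, spec$n_genes, spec$n_mirnas)) {
    stop("invalid CohortSpec: n_planted_triads exceeds min(n_snps, n_genes, n_mirnas)",
         call. = FALSE)
  }
  if (spec$n_planted_triads > 0 && !(spec$effect_mirna_gene < 0)) {
    stop("invalid CohortSpec: effect_mirna_gene must be negative (repressive regulation)",
         call. = FALSE)
  }
  if (length(spec$maf_range) != 2 || spec$maf_range[1] <= 0 ||
      spec$maf_range[2] > 0.5 || spec$maf_range[1] > spec$maf_range[2]) {
    stop("invalid CohortSpec: maf_range must lie within (0, 0.5]",
         call. = FALSE)
  }
  if (!(spec$noise_sd > 0)) {
    stop("invalid CohortSpec: noise_sd must be > 0", call. = FALSE)
  }
  if (length(spec$dose_scaling) != length(spec$concentrations)) {
    stop("invalid CohortSpec: dose_scaling must match concentrations in length",
         call. = FALSE)
  }
  if (length(spec$baseline_percent) != length(spec$concentrations) ||
      any(spec$baseline_percent <= 0)) {
    stop("invalid CohortSpec: baseline_percent must be positive, one per concentration",
         call. = FALSE)
  }
  if (!is.numeric(spec$seed) || length(spec$seed) != 1 || is.na(spec$seed)) {
    stop("invalid CohortSpec: seed must be a single integer", call. = FALSE)
  }
  invisible(spec)
}

#' Generate a synthetic cohort with planted triad structure
#'
#' Genotypes are drawn per SNP as `Binomial(2, f)` with `f` uniform in
#' `maf_range`; expression matrices are log-scale Gaussian noise except for
#' the planted columns; the log-viability phenotype is baseline plus the
#' planted gene contribution scaled per concentration, plus noise. Planted
#' SNPs are drawn among SNPs that are polymorphic in the realised sample, so
#' every planted effect is estimable.
#'
#' @param spec A `cohort_spec`.
#' @return An object of class `synthetic_cohort`: list with `genotypes`
#'   (samples x SNPs dosage matrix), `gene_expr`, `mirna_expr` (samples x
#'   features), `phenotypes` (a [phenotype_table]), `truth` (data.frame of
#'   planted `snp_id`, `mirna_id`, `gene_id`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_samples
    k <- spec$n_planted_triads
    s <- spec$noise_sd
    samples <- sprintf("samp_%04d", seq_len(n))
    snp_ids <- sprintf("snp_%05d", seq_len(spec$n_snps))
    gene_ids <- sprintf("gene_%05d", seq_len(spec$n_genes))
    mir_ids <- sprintf("mir_%04d", seq_len(spec$n_mirnas))

    maf <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
    G <- matrix(stats::rbinom(n * spec$n_snps, 2L,
                              rep(maf, each = n)),
                nrow = n, dimnames = list(samples, snp_ids))

    gene_expr <- matrix(stats::rnorm(n * spec$n_genes, 0, s),
                        nrow = n, dimnames = list(samples, gene_ids))
    mirna_expr <- matrix(stats::rnorm(n * spec$n_mirnas, 0, s),
                         nrow = n, dimnames = list(samples, mir_ids))

    n_conc <- length(spec$concentrations)
    log_pheno <- matrix(rep(log(spec$baseline_percent), each = n),
                        nrow = n) +
      matrix(stats::rnorm(n * n_conc, 0, s), nrow = n)
    dimnames(log_pheno) <- list(samples, as.character(spec$concentrations))

    truth <- data.frame(snp_id = character(0), mirna_id = character(0),
                        gene_id = character(0), stringsAsFactors = FALSE)
    if (k > 0) {
      poly <- which(apply(G, 2, function(g) length(unique(g)) > 1))
      if (length(poly) < k) {
        stop("too few polymorphic SNPs realised to plant the requested triads",
             call. = FALSE)
      }
      planted_snps <- sort(sample(poly, k))
      planted_genes <- sort(sample.int(spec$n_genes, k))
      planted_mirs <- sort(sample.int(spec$n_mirnas, k))

      e_qm <- spec$effect_qtl_mirna
      e_qg <- spec$effect_qtl_gene
      e_mg <- spec$effect_mirna_gene
      e_pg <- spec$effect_gene_pheno
      var_m <- e_qm^2 + s^2
      # path coefficient on the miRNA's non-genetic component, calibrated so
      # the marginal gene ~ miRNA slope equals e_mg despite the shared SNP
      b_m <- (e_mg * var_m - e_qm * e_qg) / s^2

      for (i in seq_len(k)) {
        si <- planted_snps[i]
        gi <- planted_genes[i]
        mi <- planted_mirs[i]
        f <- maf[si]
        z <- (G[, si] - 2 * f) / sqrt(2 * f * (1 - f))
        e_m <- mirna_expr[, mi]               # miRNA residual (pre-drawn noise)
        mirna_expr[, mi] <- e_qm * z + e_m
        gene_expr[, gi] <- e_qg * z + b_m * e_m + gene_expr[, gi]
        for (cc in seq_len(n_conc)) {
          log_pheno[, cc] <- log_pheno[, cc] +
            e_pg * spec$dose_scaling[cc] * gene_expr[, gi]
        }
      }
      truth <- data.frame(
        snp_id = snp_ids[planted_snps],
        mirna_id = mir_ids[planted_mirs],
        gene_id = gene_ids[planted_genes],
        stringsAsFactors = FALSE
      )
    }

    pheno <- phenotype_table(exp(log_pheno), spec$concentrations)
    structure(
      list(
        genotypes = G,
        gene_expr = gene_expr,
        mirna_expr = mirna_expr,
        phenotypes = pheno,
        truth = truth,
        spec = spec
      ),
      class = "synthetic_cohort"
    )
  })
}

#' Generate a pure-null cohort (identical marginals, zero planted effects)
#'
#' Used for type-I-error and false-discovery calibration of the cascade.
#'
#' @param spec A `cohort_spec`; its effect fields are ignored.
#' @return A `synthetic_cohort` with an empty truth table.
#' @export
generate_null_cohort <- function(spec) {
  validate_cohort_spec(spec)
  null_spec <- spec
  null_spec$n_planted_triads <- 0L
  null_spec$effect_qtl_gene <- 0
  null_spec$effect_qtl_mirna <- 0
  null_spec$effect_mirna_gene <- 0
  null_spec$effect_gene_pheno <- 0
  generate_cohort(null_spec)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    paste0("synthetic_cohort: %d samples; %d SNPs, %d genes, %d miRNAs; ",
           "%d planted triads; doses %s uM (seed %s)\n"),
    nrow(x$genotypes), ncol(x$genotypes), ncol(x$gene_expr),
    ncol(x$mirna_expr), nrow(x$truth),
    paste(x$spec$concentrations, collapse = "/"),
    format(x$spec$seed)
  ))
  invisible(x)
}
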