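# Tabular IO. TSV is the canonical dialect (sample rows, feature columns,
# header row, first column `sample_id`); lines starting with '#' carry
# provenance metadata and are skipped on read. Matrices are written with 17
# significant digits so that write -> read round-trips to full precision.
# Minimal GT-only VCF ingestion is provided for genotypes.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_matrix_tsv <- function(mat, path, meta = NULL, integer_cells = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  writeLines(paste(c("sample_id", colnames(mat)), collapse = "\t"), con)
  body <- if (integer_cells) {
    apply(mat, 2, function(col) ifelse(is.na(col), "NA", as.character(col)))
  } else {
    apply(mat, 2, fmt_num)
  }
  body <- matrix(body, nrow = nrow(mat))
  writeLines(paste(rownames(mat),
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

read_tsv_cells <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1) stop(sprintf("empty table: %s", path), call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  rows <- cells[-1]
  # strsplit drops a single trailing empty field; restore it
  body_lines <- lines[-1]
  short <- lengths(rows) == length(header) - 1L & endsWith(body_lines, "\t")
  rows[short] <- lapply(rows[short], function(r) c(r, ""))
  widths <- lengths(rows)
  if (length(rows) && any(widths != length(header))) {
    bad <- which(widths != length(header))[1]
    stop(sprintf("ragged row %d in %s (found %d cells, expected %d)",
                 bad, path, widths[bad], length(header)), call. = FALSE)
  }
  list(header = header, rows = rows)
}

check_unique <- function(ids, what, path) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate %s '%s' in %s", what, dup[1], path),
         call. = FALSE)
  }
}

#' Read a genotype dosage matrix from TSV
#'
#' Expects a header of SNP ids, a first column of sample ids, and cells in
#' `{0, 1, 2, NA}`. Comment lines (`#`) are skipped. Malformed cells and
#' duplicate sample/SNP ids raise parse errors with row/column coordinates.
#'
#' @param path Path to the TSV file.
#' @return Integer dosage matrix (samples x SNPs) with an `allele_freq`
#'   attribute of per-SNP coded-allele frequencies.
#' @export
read_genotype_table <- function(path) {
  tab <- read_tsv_cells(path)
  snp_ids <- tab$header[-1]
  check_unique(snp_ids, "SNP id", path)
  samples <- vapply(tab$rows, `[`, character(1), 1)
  check_unique(samples, "sample id", path)
  G <- matrix(NA_integer_, length(samples), length(snp_ids),
              dimnames = list(samples, snp_ids))
  for (i in seq_along(tab$rows)) {
    vals <- tab$rows[[i]][-1]
    bad <- !(vals %in% c("0", "1", "2", "NA", ""))
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf(
        "parse error in %s: invalid genotype cell '%s' at row %d, column %d (%s)",
        path, vals[j], i, j + 1L, snp_ids[j]), call. = FALSE)
    }
    vals[vals == ""] <- NA
    G[i, ] <- suppressWarnings(as.integer(vals))
  }
  attr(G, "allele_freq") <- allele_freq(G)
  G
}

#' Write a genotype dosage matrix as TSV
#'
#' @param G Dosage matrix (samples x SNPs).
#' @param path Output path.
#' @param meta Optional named list of provenance metadata written as `#`
#'   header lines.
#' @return The path, invisibly.
#' @export
write_genotype_table <- function(G, path, meta = NULL) {
  invisible(write_matrix_tsv(G, path, meta = meta, integer_cells = TRUE))
}

#' Read an expression matrix from TSV
#'
#' Numeric cells; blank cells become missing values. Non-numeric cells raise
#' a parse error with coordinates.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (samples x features).
#' @export
read_expression_table <- function(path) {
  tab <- read_tsv_cells(path)
  ids <- tab$header[-1]
  check_unique(ids, "feature id", path)
  samples <- vapply(tab$rows, `[`, character(1), 1)
  check_unique(samples, "sample id", path)
  M <- matrix(NA_real_, length(samples), length(ids),
              dimnames = list(samples, ids))
  for (i in seq_along(tab$rows)) {
    vals <- tab$rows[[i]][-1]
    vals[vals == ""] <- NA
    num <- suppressWarnings(as.numeric(vals))
    bad <- is.na(num) & !is.na(vals) & vals != "NA"
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf(
        "parse error in %s: non-numeric cell '%s' at row %d, column %d (%s)",
        path, vals[j], i, j + 1L, ids[j]), call. = FALSE)
    }
    M[i, ] <- num
  }
  M
}

#' Write an expression matrix as TSV (full precision)
#'
#' @inheritParams write_genotype_table
#' @param M Numeric matrix (samples x features).
#' @export
write_expression_table <- function(M, path, meta = NULL) {
  invisible(write_matrix_tsv(M, path, meta = meta))
}

#' Write a phenotype table as TSV
#'
#' Stores the percent-viable matrix at full precision, with the log base in
#' the metadata header; the log phenotype is recomputed on read, so the
#' round-trip is exact.
#'
#' @param pheno A [phenotype_table].
#' @param path Output path.
#' @param meta Optional extra metadata.
#' @export
write_phenotype_table <- function(pheno, path, meta = NULL) {
  stopifnot(inherits(pheno, "phenotype_table"))
  mat <- pheno$percent_viable
  colnames(mat) <- paste0("percent_", pheno$concentrations, "uM")
  meta <- c(list(
    concentrations = paste(pheno$concentrations, collapse = ","),
    log_base = sprintf("%.17g", pheno$log_base),
    units = "percent viable cells relative to control"
  ), meta)
  invisible(write_matrix_tsv(mat, path, meta = meta))
}

#' Read a phenotype table written by [write_phenotype_table]
#'
#' @param path Path to the TSV file.
#' @return A [phenotype_table].
#' @export
read_phenotype_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s:", key), meta_lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^# %s: ", key), "", hit[1])
  }
  concs <- as.numeric(strsplit(get_meta("concentrations") %||% "",
                               ",")[[1]])
  base <- as.numeric(get_meta("log_base") %||% sprintf("%.17g", exp(1)))
  M <- read_expression_table(path)
  if (length(concs) != ncol(M)) {
    stop(sprintf("phenotype file %s: concentration metadata does not match columns",
                 path), call. = FALSE)
  }
  colnames(M) <- as.character(concs)
  phenotype_table(M, concs, log_base = base)
}

#' Read genotypes from a minimal VCF (GT field only)
#'
#' Uses `vcfR` to parse the file and maps unphased or phased GT strings to
#' additive dosages (`0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./.` -> missing).
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Integer dosage matrix (samples x SNPs) with an `alleles`
#'   attribute data.frame (`snp_id`, `coded`, `other`); the coded allele is
#'   the VCF ALT allele.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  G <- apply(gt, 2, function(col) encode_additive(col))
  G <- matrix(as.integer(G), nrow = nrow(gt),
              dimnames = list(ids, colnames(gt)))
  G <- t(G)   # samples x SNPs
  attr(G, "alleles") <- data.frame(
    snp_id = ids,
    coded = vcfR::getALT(v),
    other = vcfR::getREF(v),
    stringsAsFactors = FALSE
  )
  attr(G, "allele_freq") <- allele_freq(G)
  G
}

#' Write genotypes as a minimal GT-only VCF
#'
#' @param G Dosage matrix (samples x SNPs).
#' @param path Output path.
#' @param alleles Optional data.frame (`snp_id`, `coded`, `other`); defaults
#'   to A (other/REF) and G (coded/ALT) placeholder alleles.
#' @export
write_genotype_vcf <- function(G, path, alleles = NULL) {
  snps <- colnames(G)
  if (is.null(alleles)) {
    alleles <- data.frame(snp_id = snps, coded = "G", other = "A",
                          stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  ), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_along(snps)) {
    al <- alleles[alleles$snp_id == snps[j], ]
    gt <- ifelse(is.na(G[, j]), "./.", gt_map[G[, j] + 1L])
    writeLines(paste(c("1", j, snps[j], al$other, al$coded, ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param meta Optional provenance metadata added to every file header.
#' @return Named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir, meta = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(list(seed = format(cohort$spec$seed)), meta)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    gene_expr = file.path(dir, "gene_expression.tsv"),
    mirna_expr = file.path(dir, "mirna_expression.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genotype_table(cohort$genotypes, paths["genotypes"], meta = meta)
  write_expression_table(cohort$gene_expr, paths["gene_expr"], meta = meta)
  write_expression_table(cohort$mirna_expr, paths["mirna_expr"], meta = meta)
  write_phenotype_table(cohort$phenotypes, paths["phenotypes"], meta = meta)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Write a triad table as TSV
#'
#' P-values are printed in scientific notation with 6 significant digits;
#' comparisons inside the package always use full-precision values.
#'
#' @param triads Triad data.frame from [assemble_triads].
#' @param path Output path.
#' @param meta Optional provenance metadata.
#' @export
write_triad_table <- function(triads, path, meta = NULL) {
  out <- triads
  for (col in grep("^(p_s[1-6]|r_s3)$", names(out), value = TRUE)) {
    out[[col]] <- sprintf("%.5e", triads[[col]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
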