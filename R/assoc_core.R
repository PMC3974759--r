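# Statistical engine used by every cascade step: univariate OLS slope test,
# Pearson correlation with optional sign constraint, additive genotype coding.
#
# The engine is implemented with the closed-form textbook formulas
# (beta = S_xy / S_xx, t = beta / se with n - 2 df) rather than per-pair
# lm() calls, because a genome-wide cascade performs 1e5-1e6 univariate fits.
# Agreement with lm()/cor.test() is asserted in the test suite.

# Flags attached to every association record:
#   "ok"            regular fit
#   "degenerate"    zero-variance predictor or response; p = 1, never passes
#   "perfect_fit"   zero residual variance; p is the smallest representable
#                   positive double
#   "insufficient"  fewer than 3 complete cases

#' Vectorised simple linear regression of one response on many predictors
#'
#' Fits `y ~ X[, j]` for every column of `X` using closed-form OLS with
#' listwise deletion of missing pairs, returning slope, standard error,
#' t statistic, two-sided p-value and Pearson correlation per column.
#'
#' Degenerate columns (zero predictor or response variance) yield a flagged
#' record with `beta = 0`, `p = 1` instead of an error, so genome-wide scans
#' never abort on monomorphic SNPs. Perfect fits (zero residual variance with
#' non-zero slope) report the smallest representable positive p with a
#' `"perfect_fit"` flag.
#'
#' @param X Numeric matrix (samples x predictors); `NA` allowed.
#' @param y Numeric response vector of length `nrow(X)`; `NA` allowed.
#' @param x_ids Predictor identifiers (default `colnames(X)`).
#' @return A data.frame with one row per column of `X`:
#'   `x_id, n, beta, se, t, p, r, flag`.
#' @export
slope_scan <- function(X, y, x_ids = colnames(X)) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  if (is.null(x_ids)) x_ids <- sprintf("x%d", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  y <- as.numeric(y)

  M <- (!is.na(X)) & !is.na(y)        # complete-case indicator, n x m
  Xz <- X
  Xz[!M] <- 0
  yz <- y
  yz[is.na(yz)] <- 0

  n <- colSums(M)
  Sx <- colSums(Xz)
  Sy <- colSums(M * yz)
  Sxx <- colSums(Xz * Xz)
  Syy <- colSums(M * yz * yz)
  Sxy <- colSums(Xz * yz)

  # centred sums of squares / cross-products
  sxx <- Sxx - Sx * Sx / pmax(n, 1)
  syy <- Syy - Sy * Sy / pmax(n, 1)
  sxy <- Sxy - Sx * Sy / pmax(n, 1)

  m <- ncol(X)
  beta <- se <- tt <- p <- r <- rep(NA_real_, m)
  flag <- rep("ok", m)

  insufficient <- n < 3
  # zero-variance detection is relative to the uncentred magnitude so that a
  # constant non-zero column is caught despite rounding in the centred sum
  degen_x <- !insufficient & !(sxx > 1e-12 * pmax(Sxx, .Machine$double.xmin))
  degen_y <- !insufficient & !degen_x &
    !(syy > 1e-12 * pmax(Syy, .Machine$double.xmin))

  flag[insufficient] <- "insufficient"
  flag[degen_x | degen_y] <- "degenerate"
  beta[degen_x | degen_y] <- 0
  p[degen_x | degen_y] <- 1
  tt[degen_x | degen_y] <- 0

  okc <- !insufficient & !degen_x & !degen_y
  if (any(okc)) {
    b <- sxy[okc] / sxx[okc]
    sse <- pmax(syy[okc] - b * sxy[okc], 0)
    perfect <- sse <= 1e-12 * syy[okc]
    df <- n[okc] - 2
    mse <- sse / df
    s <- sqrt(mse / sxx[okc])
    tv <- b / s
    pv <- 2 * stats::pt(-abs(tv), df)
    rv <- sxy[okc] / sqrt(sxx[okc] * syy[okc])
    if (any(perfect)) {
      s[perfect] <- 0
      tv[perfect] <- sign(b[perfect]) * Inf
      pv[perfect] <- .Machine$double.xmin
    }
    beta[okc] <- b
    se[okc] <- s
    tt[okc] <- tv
    p[okc] <- pv
    r[okc] <- rv
    fl <- flag[okc]
    fl[perfect] <- "perfect_fit"
    flag[okc] <- fl
  }

  data.frame(
    x_id = as.character(x_ids),
    n = as.integer(n),
    beta = beta, se = se, t = tt, p = p, r = r,
    flag = flag,
    stringsAsFactors = FALSE
  )
}

#' Univariate OLS slope test for a single predictor/response pair
#'
#' The workhorse association test of the cascade: ordinary least squares of
#' `y` on `x` with the two-sided t-test on the slope (`n - 2` df) and
#' listwise deletion of missing pairs.
#'
#' @param x Numeric predictor (e.g. expression values or additive genotype
#'   dosages 0/1/2).
#' @param y Numeric response.
#' @param x_id,y_id Identifiers recorded in the result.
#' @param step Provenance label (e.g. `"S1"`).
#' @return One-row data.frame (an association record):
#'   `x_id, y_id, step, n, beta, se, t, p, r, flag`.
#' @examples
#' fit_slope(c(0, 1, 2, 0, 1, 2), c(0.1, 1.9, 4.2, -0.2, 2.1, 3.9))
#' @export
fit_slope <- function(x, y, x_id = "x", y_id = "y", step = NA_character_) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    stop(sprintf(
      "insufficient data: only %d complete cases for (%s, %s); need >= 3",
      sum(ok), x_id, y_id
    ), call. = FALSE)
  }
  rec <- slope_scan(matrix(as.numeric(x), ncol = 1), as.numeric(y),
                    x_ids = x_id)
  data.frame(
    x_id = x_id, y_id = y_id, step = step,
    rec[, c("n", "beta", "se", "t", "p", "r", "flag")],
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation test with an optional sign constraint
#'
#' Computes Pearson's r and its two-sided p-value via the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` df. When
#' `required_sign = "negative"` (the miRNA-repression gate of the cascade's
#' step 3), the record is marked `pass` only if `r < 0` and `p <= alpha`.
#'
#' @param x,y Numeric vectors; missing pairs are dropped listwise.
#' @param required_sign `"any"` or `"negative"`.
#' @param alpha Significance threshold used for the `pass` flag.
#' @param x_id,y_id,step Provenance labels.
#' @return One-row data.frame:
#'   `x_id, y_id, step, n, r, t, p, pass, flag`.
#' @export
pearson_with_sign <- function(x, y, required_sign = c("any", "negative"),
                              alpha = 1e-4, x_id = "x", y_id = "y",
                              step = NA_character_) {
  required_sign <- match.arg(required_sign)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    stop(sprintf(
      "insufficient data: only %d complete cases for (%s, %s); need >= 3",
      sum(ok), x_id, y_id
    ), call. = FALSE)
  }
  rec <- slope_scan(matrix(as.numeric(x), ncol = 1), as.numeric(y),
                    x_ids = x_id)
  r <- rec$r
  p <- rec$p
  pass <- rec$flag %in% c("ok", "perfect_fit") &
    !is.na(p) & p <= alpha &
    (required_sign == "any" | (!is.na(r) & r < 0))
  data.frame(
    x_id = x_id, y_id = y_id, step = step,
    n = rec$n, r = r, t = rec$t, p = p,
    pass = pass, flag = rec$flag,
    stringsAsFactors = FALSE
  )
}

#' Additive genotype coding
#'
#' Codes genotype calls as the count (0/1/2) of the coded allele under an
#' additive genetic model. Accepts numeric dosages (validated and passed
#' through), VCF-style GT strings (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`,
#' phased variants with `|`), or two-letter allele-pair calls (`"AG"`)
#' given `ref` and `alt`; the coded allele is the alternate allele.
#'
#' @param calls Vector of genotype calls.
#' @param ref,alt Reference/alternate allele letters, required for allele-pair
#'   calls.
#' @return Integer vector of dosages with `NA` for missing calls; carries a
#'   logical attribute `monomorphic` (TRUE when the non-missing dosages have
#'   zero variance).
#' @examples
#' encode_additive(c("AA", "AG", "GG"), ref = "A", alt = "G")
#' encode_additive(c("0/0", "0/1", "1/1", "./."))
#' @export
encode_additive <- function(calls, ref = NULL, alt = NULL) {
  na_codes <- c("NA", "NN", "--", ".", "./.", ".|.", "")
  out <- rep(NA_integer_, length(calls))

  if (is.numeric(calls)) {
    bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
    if (any(bad)) {
      stop(sprintf("unrecognized genotype call '%s'",
                   format(calls[which(bad)[1]])), call. = FALSE)
    }
    out <- as.integer(calls)
  } else {
    calls <- as.character(calls)
    for (i in seq_along(calls)) {
      cl <- calls[i]
      if (is.na(cl) || cl %in% na_codes) next
      if (grepl("^[0-9.]([/|])[0-9.]$", cl)) {
        a <- substr(cl, 1, 1)
        b <- substr(cl, 3, 3)
        if (a == "." || b == ".") next
        if (!a %in% c("0", "1") || !b %in% c("0", "1")) {
          stop(sprintf("unrecognized genotype call '%s'", cl), call. = FALSE)
        }
        out[i] <- (a == "1") + (b == "1")
      } else if (cl %in% c("0", "1", "2")) {
        out[i] <- as.integer(cl)
      } else if (nchar(cl) == 2L && !is.null(ref) && !is.null(alt)) {
        alleles <- strsplit(cl, "")[[1]]
        if (!all(alleles %in% c(ref, alt))) {
          stop(sprintf("unrecognized genotype call '%s'", cl), call. = FALSE)
        }
        out[i] <- sum(alleles == alt)
      } else {
        stop(sprintf("unrecognized genotype call '%s'", cl), call. = FALSE)
      }
    }
  }
  v <- out[!is.na(out)]
  attr(out, "monomorphic") <- length(unique(v)) <= 1L
  out
}

#' Coded-allele frequencies of a genotype matrix
#'
#' @param G Dosage matrix (samples x SNPs) with entries in `{0, 1, 2, NA}`.
#' @return Named numeric vector: per SNP, sum of non-missing dosages divided
#'   by twice the non-missing count.
#' @export
allele_freq <- function(G) {
  G <- as.matrix(G)
  colSums(G, na.rm = TRUE) / (2 * colSums(!is.na(G)))
}

#' Permutation p-value for the slope t-test
#'
#' Empirical two-sided p-value of the observed slope t statistic under random
#' permutations of `y`; used as an independent Monte-Carlo check of the
#' analytic t-distribution p-value.
#'
#' @param x,y Numeric vectors without missing values.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with `p_perm` (with the +1 continuity correction),
#'   `p_analytic`, and `t_obs`.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000, seed = 1) {
  obs <- fit_slope(x, y)
  t_obs <- abs(obs$t)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(fit_slope(x, sample(y))$t) >= t_obs
    }, logical(1)))
  })
  list(
    p_perm = (exceed + 1) / (n_perm + 1),
    p_analytic = obs$p,
    t_obs = obs$t
  )
}
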