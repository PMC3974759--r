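# The regression/correlation engine against independent oracles and its
# documented edge-case contracts.

test_that("fit_slope matches the lm() oracle to near machine precision", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(10:120, 1)
      x <- rnorm(n)
      y <- runif(1, -1, 1) * x + rnorm(n, sd = runif(1, 0.2, 3))
      if (seed %% 5 == 0) {        # missing pairs exercise listwise deletion
        x[sample(n, 2)] <- NA
        y[sample(n, 2)] <- NA
      }
      f <- fit_slope(x, y)
      ok <- !is.na(x) & !is.na(y)
      o <- oracle_slope(x[ok], y[ok])
      expect_lt(rel_diff(f$beta, o$beta), 1e-10)
      expect_lt(rel_diff(f$se, o$se), 1e-10)
      expect_lt(rel_diff(f$t, o$t), 1e-10)
      expect_lt(rel_diff(f$p, o$p), 1e-10)
      expect_identical(f$n, as.integer(sum(ok)))
    })
  }
})

test_that("pearson_with_sign matches cor.test and enforces the sign gate", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      x <- rnorm(58)
      y <- -0.4 * x + rnorm(58)
      rec <- pearson_with_sign(x, y, "any")
      o <- oracle_pearson(x, y)
      expect_lt(rel_diff(rec$r, o$r), 1e-10)
      expect_lt(rel_diff(rec$p, o$p), 1e-10)
    })
  }
  x <- c(1, 2, 3, 4, 5)
  anti <- pearson_with_sign(x, -x, "negative", alpha = 0.5)
  expect_equal(anti$r, -1)
  expect_true(anti$pass)
  pro <- pearson_with_sign(x, x, "negative", alpha = 1)
  expect_equal(pro$r, 1)
  expect_false(pro$pass)   # positive correlation never passes the gate
})

test_that("slope t-test and correlation t-test give the same p-value", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x <- rnorm(40)
      y <- 0.3 * x + rnorm(40)
      expect_lt(rel_diff(fit_slope(x, y)$p,
                         pearson_with_sign(x, y, "any")$p), 1e-12)
    })
  }
})

test_that("p-values are invariant to affine rescaling of x and y", {
  withr::with_seed(3, {
    x <- rnorm(58)
    y <- 0.5 * x + rnorm(58)
  })
  p0 <- fit_slope(x, y)$p
  for (sc in list(c(2, -1, 0.1, 5), c(-3, 100, 7, -0.2))) {
    p1 <- fit_slope(sc[1] * x + sc[2], sc[3] * y + sc[4])$p
    expect_lt(rel_diff(p0, p1), 1e-10)
  }
})

test_that("degenerate and perfect-fit inputs follow the documented contract", {
  x <- c(0, 1, 2, 0, 1, 2)
  exact <- fit_slope(x, 2 * x)
  expect_equal(exact$beta, 2)
  expect_identical(exact$flag, "perfect_fit")
  expect_lte(exact$p, .Machine$double.xmin)

  flat_y <- fit_slope(x, rep(5, 6))
  expect_equal(flat_y$beta, 0)
  expect_identical(flat_y$flag, "degenerate")
  expect_equal(flat_y$p, 1)

  flat_x <- fit_slope(rep(1, 6), rnorm(6))
  expect_identical(flat_x$flag, "degenerate")
  expect_equal(flat_x$p, 1)

  expect_error(fit_slope(c(1, 2), c(1, 2)), "insufficient")
  expect_error(fit_slope(c(1, NA, 3, NA), c(1, 2, NA, 4)), "insufficient")
})

test_that("slope_scan agrees with per-column fit_slope including NA columns", {
  withr::with_seed(9, {
    X <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    X[sample(length(X), 30)] <- NA
    X[, 8] <- 1                       # constant column
    y <- rnorm(50)
  })
  sc <- slope_scan(X, y)
  for (j in 1:7) {
    f <- fit_slope(X[, j], y)
    expect_equal(sc$beta[j], f$beta)
    expect_equal(sc$p[j], f$p)
    expect_equal(sc$n[j], f$n)
  }
  expect_identical(sc$flag[8], "degenerate")
})

test_that("additive coding maps calls, GT strings and flags monomorphism", {
  expect_equal(as.integer(encode_additive(c("AA", "AG", "GG"),
                                          ref = "A", alt = "G")),
               c(0L, 1L, 2L))
  expect_equal(as.integer(encode_additive(c("GA"), ref = "A", alt = "G")), 1L)
  gt <- encode_additive(c("0/0", "0/1", "1/1", "./.", "0|1"))
  expect_equal(as.integer(gt), c(0L, 1L, 2L, NA, 1L))
  het <- encode_additive(c("0/1", "0/1", "0/1"))
  expect_true(attr(het, "monomorphic"))
  expect_false(attr(encode_additive(c(0, 1, 2)), "monomorphic"))
  expect_error(encode_additive(c("AA", "XX"), ref = "A", alt = "G"), "XX")
  expect_error(encode_additive(c(0, 3)), "3")
})

test_that("allele frequencies use non-missing calls only", {
  G <- cbind(a = c(0L, 1L, 2L, NA), b = c(2L, 2L, 2L, 2L))
  expect_equal(unname(allele_freq(G)), c(3 / 6, 1))
})

test_that("permutation null reproduces the analytic p-value", {
  withr::with_seed(21, {
    x <- rnorm(18)
    y <- 0.5 * x + rnorm(18)
  })
  pp <- permutation_pvalue(x, y, n_perm = 1000, seed = 5)
  mc_sd <- sqrt(pp$p_analytic * (1 - pp$p_analytic) / 1000)
  expect_lt(abs(pp$p_perm - pp$p_analytic), 3 * mc_sd + 2 / 1000)
})
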