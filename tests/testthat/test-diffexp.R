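test_that("bh_fdr matches the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_fdr(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))

  # exhaustive random checks at length <= 8, vs brute force and stats::p.adjust
  set.seed(77)
  for (len in 1:8) {
    for (rep in 1:20) {
      p <- round(runif(len), 3)
      q <- bh_fdr(p)
      expect_equal(q, brute_force_bh(p), tolerance = 1e-12)
      expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    }
  }

  # order invariance
  p <- runif(20)
  o <- sample(20)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
})

test_that("build_paired_differences forms tumor-minus-normal per subject", {
  v <- toy_matrix(0, 2, 6)
  colnames(v) <- c("S1_T", "S2_T", "S3_T", "S1_N", "S2_N", "S3_N")
  v["M1", ] <- c(2.0, 1.0, 3.0, 0.5, 1.0, 2.0)
  v["M2", ] <- c(1.0, NA, 2.0, 0.0, 1.0, NA)
  m <- abundance_matrix(v, "mad_normalized")
  pd <- build_paired_differences(m, paired_meta(3), covariates = character(0))
  expect_equal(unname(pd$d["M1", ]), c(1.5, 0.0, 1.0))
  # subject excluded where either tissue missing
  expect_equal(unname(is.na(pd$d["M2", ])), c(FALSE, TRUE, TRUE))
  expect_equal(sum(!is.na(pd$d["M2", ])), 1L)
})

test_that("paired-difference counts reflect joint observation", {
  set.seed(3)
  n <- 12L
  v <- toy_matrix(rnorm(2 * 2 * n), 2, 2 * n)
  colnames(v) <- c(paste0("S", 1:n, "_T"), paste0("S", 1:n, "_N"))
  v["M1", paste0("S", 1:3, "_T")] <- NA # 3 subjects lose the pair
  m <- abundance_matrix(v, "mad_normalized")
  pd <- build_paired_differences(m, paired_meta(n))
  expect_equal(sum(!is.na(pd$d["M1", ])), 9L)
})

test_that("fit_marker_model solves the OLS difference model", {
  f1 <- fit_marker_model(c(1, 1, 1, 1))
  expect_equal(f1$log2fc, 1)
  expect_equal(f1$s_sq, 0)
  expect_equal(f1$df, 3L)
  expect_equal(f1$v, 0.25)

  # hand-computed OLS: mean 1.0, residual SS = 0.08, df = 3
  f2 <- fit_marker_model(c(0.8, 1.2, 1.0, 1.0))
  expect_equal(f2$log2fc, 1.0)
  expect_equal(f2$s_sq, 0.08 / 3, tolerance = 1e-12)

  # constant covariate is collinear with the intercept -> dropped, fit proceeds
  cv <- matrix(0, 4, 1, dimnames = list(NULL, "age"))
  expect_warning(f3 <- fit_marker_model(c(0.8, 1.2, 1.0, 1.0), cv),
                 "collinear")
  expect_equal(f3$log2fc, 1.0)

  # with centered covariates the intercept variance is 1/n
  set.seed(2)
  cv2 <- matrix(scale(rnorm(10), scale = FALSE), ncol = 1,
                dimnames = list(NULL, "age"))
  f4 <- fit_marker_model(rnorm(10), cv2)
  expect_equal(f4$v, 0.1, tolerance = 1e-12)
  expect_equal(f4$df, 8L)
})

test_that("fit_moderation recovers prior parameters and handles degeneracy", {
  # all variances equal -> degenerate prior at that value
  fit0 <- fit_moderation(rep(0.5, 50), rep(4, 50))
  expect_identical(fit0$d0, Inf)
  expect_equal(fit0$s0_sq, 0.5)

  expect_error(fit_moderation(c(0.2, 0.3), c(4, 4)), "at least")

  # parameter recovery: s^2_i = sigma^2_i * chisq_d / d with
  # 1/sigma^2 ~ chisq_{d0} / (d0 s0^2); truth d0 = 5, s0^2 = 1, d = 4
  set.seed(123)
  n <- 2000L; d0 <- 5; s0_sq <- 1; d <- 4
  sigma_sq <- d0 * s0_sq / rchisq(n, df = d0)
  s_sq <- sigma_sq * rchisq(n, df = d) / d
  fit <- fit_moderation(s_sq, rep(d, n))
  expect_lt(abs(fit$d0 - d0) / d0, 0.30)
  expect_lt(abs(fit$s0_sq - s0_sq) / s0_sq, 0.10)
})

test_that("fit_moderation agrees with limma's F-dist fit", {
  skip_if_not_installed("limma")
  set.seed(45)
  n <- 500L
  sigma_sq <- 8 / rchisq(n, df = 8)
  s_sq <- sigma_sq * rchisq(n, df = 6) / 6
  fit <- fit_moderation(s_sq, rep(6, n))
  lf <- limma::fitFDist(s_sq, df1 = 6)
  expect_equal(fit$d0, lf$df2, tolerance = 0.05)
  expect_equal(fit$s0_sq, lf$scale, tolerance = 0.05)
})

test_that("moderated_t reduces to the classic t at d0 = 0 and obeys the blend", {
  # d0 = 0 limit: ordinary OLS t
  set.seed(31)
  for (rep in 1:5) {
    d <- rnorm(8, mean = 0.5)
    f <- fit_marker_model(d)
    mt <- moderated_t(f$log2fc, f$s_sq, f$df, list(d0 = 0, s0_sq = 1), f$v)
    oracle <- classic_t_oracle(d)
    expect_equal(mt$t_mod, oracle$t, tolerance = 1e-10)
    expect_equal(mt$pvalue, oracle$p, tolerance = 1e-10)
  }

  # zero effect -> t = 0, p = 1
  mt0 <- moderated_t(0, 0.3, 5, list(d0 = 4, s0_sq = 0.2), 0.1)
  expect_equal(mt0$t_mod, 0)
  expect_equal(mt0$pvalue, 1)

  # plug-in arithmetic: d0 = Inf prior equals s^2 -> t = fc / sqrt(s0^2 v)
  mt1 <- moderated_t(1.0, 0.02667, 3, list(d0 = Inf, s0_sq = 0.02667), 0.25)
  expect_equal(mt1$t_mod, 1 / sqrt(0.02667 / 4), tolerance = 1e-9)
  expect_equal(mt1$t_mod, 12.247, tolerance = 1e-3)
  expect_equal(mt1$pvalue, 2 * pnorm(-mt1$t_mod))
})

test_that("run_diffexp with d0 = 0 reproduces classic per-marker t-tests", {
  set.seed(19)
  n <- 15L
  v <- toy_matrix(rnorm(20 * 2 * n), 20, 2 * n)
  colnames(v) <- c(paste0("S", 1:n, "_T"), paste0("S", 1:n, "_N"))
  m <- abundance_matrix(v, "mad_normalized")
  dep <- run_diffexp(m, paired_meta(n), covariates = character(0),
                     min_pairs = 5L, d0_override = 0)
  for (i in 1:20) {
    d <- v[i, 1:n] - v[i, n + (1:n)]
    oracle <- classic_t_oracle(d)
    expect_equal(dep$log2fc[i], oracle$est, tolerance = 1e-10)
    expect_equal(dep$t_mod[i], oracle$t, tolerance = 1e-10)
    expect_equal(dep$pvalue[i], oracle$p, tolerance = 1e-10)
  }
})

test_that("run_diffexp log2fc is the mean paired difference without covariates", {
  set.seed(8)
  n <- 12L
  v <- toy_matrix(rnorm(10 * 2 * n), 10, 2 * n)
  colnames(v) <- c(paste0("S", 1:n, "_T"), paste0("S", 1:n, "_N"))
  m <- abundance_matrix(v, "mad_normalized")
  dep <- run_diffexp(m, paired_meta(n), covariates = character(0),
                     min_pairs = 5L)
  expect_equal(dep$log2fc,
               unname(rowMeans(v[, 1:n] - v[, n + (1:n)])), tolerance = 1e-12)
})

test_that("run_diffexp marks untestable markers and keeps them in the table", {
  set.seed(4)
  n <- 12L
  v <- toy_matrix(rnorm(12 * 2 * n), 12, 2 * n)
  colnames(v) <- c(paste0("S", 1:n, "_T"), paste0("S", 1:n, "_N"))
  v[1, 1:(n - 2)] <- NA # marker 1 has only 2 complete pairs
  m <- abundance_matrix(v, "mad_normalized")
  dep <- run_diffexp(m, paired_meta(n), covariates = character(0),
                     min_pairs = 10L)
  expect_equal(nrow(dep), 12L)
  expect_true(is.na(dep$pvalue[1]))
  expect_true(is.na(dep$fdr[1]))
  expect_false(dep$significant[1])
})

test_that("covariate adjustment removes a planted confounder from log2fc", {
  set.seed(21)
  n <- 40L
  age <- runif(n, 40, 75)
  # difference depends on age only; adjusted intercept at centered age is
  # the mean difference, and residual variance shrinks vs unadjusted
  d_true <- 0.05 * (age - mean(age))
  v <- toy_matrix(0, 12, 2 * n)
  colnames(v) <- c(paste0("S", 1:n, "_T"), paste0("S", 1:n, "_N"))
  for (i in 1:12) {
    nrm <- rnorm(n)
    v[i, n + (1:n)] <- nrm
    v[i, 1:n] <- nrm + d_true + rnorm(n, sd = 0.05)
  }
  m <- abundance_matrix(v, "mad_normalized")
  meta <- paired_meta(n, age = age)
  dep_adj <- run_diffexp(m, meta, covariates = "age", min_pairs = 10L)
  dep_raw <- run_diffexp(m, meta, covariates = character(0), min_pairs = 10L)
  expect_equal(dep_adj$log2fc, dep_raw$log2fc, tolerance = 1e-9)
  # age variance leaves the residual under adjustment
  mod <- attr(dep_adj, "moderation")
  expect_lt(mod$s0_sq, attr(dep_raw, "moderation")$s0_sq)
})
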