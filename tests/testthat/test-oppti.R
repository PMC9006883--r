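test_that("marker_standardize produces robust z-scores", {
  m <- toy_abmat(c(1, 2, 3), 1, 3, "mad_normalized")
  z <- marker_standardize(m)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1) / 1.4826, tolerance = 1e-9)
  expect_identical(z$scale_tag, "marker_zscore")

  # symmetric values -> symmetric z about 0
  ms <- toy_abmat(c(-2, -1, 0, 1, 2), 1, 5, "mad_normalized")
  zs <- marker_standardize(ms)$values[1, ]
  expect_equal(unname(zs), -unname(rev(zs)))

  # constant marker dropped with a warning
  v <- rbind(M1 = c(5, 5, 5, 5), M2 = c(1, 2, 3, 4))
  colnames(v) <- paste0("S", 1:4)
  expect_warning(zd <- marker_standardize(abundance_matrix(v, "mad_normalized")),
                 "zero-MAD")
  expect_identical(markers(zd), "M2")
  expect_identical(attr(zd, "dropped"), "M1")
})

test_that("build_neighbor_map ranks positive correlations, brute-force checked", {
  set.seed(61)
  n_s <- 20L
  v <- toy_matrix(rnorm(6 * n_s), 6, n_s)
  v["M2", ] <- v["M1", ] # exact duplicate
  z <- abundance_matrix(v, "marker_zscore")
  params <- oppti_params(k = 3L, min_overlap = 5L)
  nb <- build_neighbor_map(z, params)
  expect_identical(nb[["M1"]]$ids[1], "M2")
  expect_equal(nb[["M1"]]$weights[1],
               cor(v["M1", ], v["M2", ]) /
                 sum(sapply(nb[["M1"]]$ids, function(j) cor(v["M1", ], v[j, ]))))

  # oracle: every marker's neighbors are its top-k positively correlated
  # markers with weights proportional to correlation
  cc <- cor(t(v)); diag(cc) <- NA
  for (mk in names(nb)) {
    r <- cc[mk, ]
    pos <- r[!is.na(r) & r > 0]
    top <- sort(pos, decreasing = TRUE)[seq_len(min(3, length(pos)))]
    expect_identical(nb[[mk]]$ids, names(top))
    expect_equal(nb[[mk]]$weights, unname(top / sum(top)), tolerance = 1e-12)
    expect_equal(sum(nb[[mk]]$weights), 1, tolerance = 1e-9)
    expect_false(mk %in% nb[[mk]]$ids)
  }
})

test_that("build_neighbor_map clips k and excludes positive-free markers", {
  set.seed(30)
  base <- rnorm(12)
  v <- rbind(M1 = base + rnorm(12, sd = .2), M2 = base + rnorm(12, sd = .2),
             M3 = base + rnorm(12, sd = .2), M4 = -base + rnorm(12, sd = .05))
  colnames(v) <- paste0("S", 1:12)
  z <- abundance_matrix(v, "marker_zscore")
  nb <- build_neighbor_map(z, oppti_params(k = 10L, min_overlap = 4L))
  # k = 10 with few markers: clips to all positive-correlated others
  expect_lte(length(nb[["M1"]]$ids), 3L)
  expect_gte(length(nb[["M1"]]$ids), 2L)
  # M4 anticorrelates with everything -> excluded
  expect_true("M4" %in% attr(nb, "excluded"))
  one <- abundance_matrix(v[1, , drop = FALSE], "marker_zscore")
  expect_error(build_neighbor_map(one, oppti_params()), "at least 2 markers")
})

test_that("infer_background takes weight-renormalized neighbor means", {
  v <- rbind(M1 = c(1, -2, 0.5), M2 = c(1, -2, 0.5), M3 = c(2, 2, NA),
             M4 = c(-2, -2, NA))
  colnames(v) <- paste0("S", 1:3)
  z <- abundance_matrix(v, "marker_zscore")
  nb <- structure(list(
    M1 = list(ids = "M2", weights = 1),
    M2 = list(ids = c("M3", "M4"), weights = c(0.75, 0.25))),
    class = "NeighborMap", excluded = c("M3", "M4"))
  inf <- infer_background(z, nb)
  # single identical neighbor -> inferred = observed
  expect_equal(inf["M1", ], v["M2", ])
  # weighted mean 0.75*2 + 0.25*(-2) = 1
  expect_equal(unname(inf["M2", 1]), 1.0)
  # both neighbors missing in S3 -> missing
  expect_true(is.na(inf["M2", 3]))
  # excluded markers stay all-missing
  expect_true(all(is.na(inf["M3", ])))
})

test_that("dysregulation scores deviations and restandardizes robustly", {
  set.seed(55)
  v <- rbind(M1 = rnorm(30), M3 = rnorm(30))
  v <- rbind(v, M2 = v["M1", ]) # exact duplicate of M1
  colnames(v) <- paste0("S", 1:30)
  z <- abundance_matrix(v[c("M1", "M2", "M3"), ], "marker_zscore")
  nb <- structure(list(M1 = list(ids = "M2", weights = 1),
                       M3 = list(ids = "M1", weights = 1)),
                  class = "NeighborMap", excluded = "M2")
  inf <- infer_background(z, nb)
  raw <- dysregulation(z, inf, restandardize = FALSE)
  # marker equal to its neighbor -> all deviations zero
  expect_equal(unname(raw["M1", ]), rep(0, 30))

  # planted +5 spike is the marker's maximum restandardized score
  z2v <- z$values
  z2v["M3", 7] <- z2v["M3", 7] + 5
  z2 <- abundance_matrix(z2v, "marker_zscore")
  d2 <- dysregulation(z2, infer_background(z2, nb))
  expect_equal(which.max(d2["M3", ]), c(S7 = 7L))
  # median of a near-symmetric row is ~0 after restandardization
  expect_lt(abs(median(d2["M3", -7])), 0.5)
})

test_that("call_overexpression is strict and ignores missing scores", {
  d <- rbind(M1 = c(2, 2.1, NA, 1.9))
  colnames(d) <- paste0("S", 1:4)
  calls <- call_overexpression(d, 2)
  expect_identical(unname(calls[1, ]), c(FALSE, TRUE, FALSE, FALSE))
  expect_false(any(call_overexpression(matrix(1, 3, 3), 2)))
})

test_that("permutation null: no-op on column-constant scores, exact on small cases", {
  # all markers identical within each sample -> permutation changes nothing
  d <- matrix(rep(c(3, 0, 1), each = 4), 4, 3,
              dimnames = list(paste0("M", 1:4), paste0("S", 1:3)))
  pn <- permutation_null(d, 2, n_perm = 10L, seed = 42L)
  expect_true(all(pn$counts == rowSums(d > 2)[1]))

  # exhaustive: 2 markers x 3 samples, all 2^3 swaps
  set.seed(14)
  d2 <- matrix(rnorm(6, sd = 2), 2, 3,
               dimnames = list(c("A", "B"), paste0("S", 1:3)))
  pn2 <- permutation_null(d2, 1, exact = TRUE)
  expect_equal(pn2$n_perm, 8L)
  expect_equal(sort(pn2$counts), sort(brute_force_permutation_pool(d2, 1)))

  # determinism of the sampled null
  a <- permutation_null(d2, 1, n_perm = 25L, seed = 9L)
  b <- permutation_null(d2, 1, n_perm = 25L, seed = 9L)
  expect_identical(a$counts, b$counts)
  expect_error(permutation_null(d2, 1, n_perm = 0L), "n_perm")
})

test_that("enrichment_pvalues uses the add-one pooled estimator", {
  null <- structure(list(counts = c(0L, 1L, 2L, 3L, 0L), n_perm = 1L,
                         seed = 1L, exact = FALSE), class = "PermutationNull")
  # observed 0: every null count >= 0 -> p = 1
  expect_equal(enrichment_pvalues(0L, null), 1)
  # observed above the null maximum -> p = 1 / (1 + pool)
  expect_equal(enrichment_pvalues(10L, null), 1 / 6)
  # null counts >= 2 are {2, 3} -> p = (1 + 2) / 6
  expect_equal(enrichment_pvalues(2L, null), 0.5)
  expect_true(is.na(enrichment_pvalues(NA_integer_, null)))
})

test_that("planted enrichment among many nulls reaches small p", {
  # 200 null markers + 1 planted with 15% of samples at +4 robust-z
  set.seed(99)
  n_m <- 201L; n_s <- 100L
  d <- matrix(rnorm(n_m * n_s), n_m, n_s,
              dimnames = list(paste0("M", 1:n_m), paste0("S", 1:n_s)))
  hot <- sample(n_s, 15L)
  d[1, hot] <- d[1, hot] + 4
  pn <- permutation_null(d, 2, n_perm = 100L, seed = 3L)
  p <- enrichment_pvalues(rowSums(d > 2), pn)
  expect_lt(p[1], 0.01)
  expect_gt(mean(p[-1] > 0.05), 0.8)
})

test_that("run_oppti reports PRO as calls over quantified samples", {
  set.seed(6)
  # co-expressed block so the neighbor map exists
  base <- rnorm(40)
  v <- do.call(rbind, lapply(1:8, function(i) base + rnorm(40, sd = 0.3)))
  dimnames(v) <- list(paste0("M", 1:8), paste0("S", 1:40))
  v[1, 1:4] <- NA # marker 1 quantified in 36 samples
  res <- run_oppti(abundance_matrix(v, "mad_normalized"),
                   oppti_params(k = 3L, min_overlap = 10L, n_perm = 20L,
                                seed = 2L))
  tab <- res$table
  expect_equal(tab$n_quantified[1], 36L)
  expect_equal(tab$pro, tab$n_called / tab$n_quantified)
  expect_true(all(tab$pro >= 0 & tab$pro <= 1, na.rm = TRUE))
  # calls for a marker depend only on that marker's scores and T
  expect_identical(res$calls,
                   call_overexpression(res$dysregulation,
                                       res$params$threshold_T))
})

test_that("run_oppti is deterministic for a fixed seed and params", {
  set.seed(17)
  base <- rnorm(30)
  v <- do.call(rbind, lapply(1:10, function(i) base + rnorm(30, sd = 0.4)))
  dimnames(v) <- list(paste0("M", 1:10), paste0("S", 1:30))
  v[sample(300, 15)] <- NA
  m <- abundance_matrix(v, "mad_normalized")
  p <- oppti_params(k = 4L, min_overlap = 8L, n_perm = 30L, seed = 5L)
  r1 <- run_oppti(m, p)
  r2 <- run_oppti(m, p)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$calls, r2$calls)
})
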