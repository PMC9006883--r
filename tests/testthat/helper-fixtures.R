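# Shared fixture builders. Everything is generated in code; no binary data.

# small markers x samples matrix with dimnames
toy_matrix <- function(values, n_markers, n_samples,
                       marker_prefix = "M", sample_prefix = "S") {
  matrix(values, n_markers, n_samples,
         dimnames = list(paste0(marker_prefix, seq_len(n_markers)),
                         paste0(sample_prefix, seq_len(n_samples))))
}

toy_abmat <- function(values, n_markers, n_samples, scale_tag = "raw") {
  abundance_matrix(toy_matrix(values, n_markers, n_samples), scale_tag)
}

# paired meta for subjects S1..Sn with samples <subject>_T / <subject>_N
paired_meta <- function(n, age = NULL, gender = NULL) {
  sb <- paste0("S", seq_len(n))
  sample_meta(data.frame(
    sample_id = c(paste0(sb, "_T"), paste0(sb, "_N")),
    subject_id = c(sb, sb),
    tissue = rep(c("tumor", "normal"), each = n),
    age = if (is.null(age)) NA else rep(age, 2L),
    gender = if (is.null(gender)) NA else rep(gender, 2L),
    batch = NA, stringsAsFactors = FALSE))
}

# brute-force BH step-up: q_i = min_{j >= i} p_(j) * m / j, mapped back
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sort(p)[i:m] * m / (i:m)))
  }, numeric(1L))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# independent exhaustive oracle for the within-sample permutation null:
# enumerates every combination of per-column permutations of the observed
# entries and pools the per-marker exceedance counts
brute_force_permutation_pool <- function(d, threshold_T) {
  n_s <- ncol(d)
  perm_list <- lapply(seq_len(n_s), function(j) {
    ix <- which(!is.na(d[, j]))
    if (length(ix) <= 1L) return(list(ix))
    lapply(seq_len(nrow(perms_of(length(ix)))), function(r) {
      ix[perms_of(length(ix))[r, ]]
    })
  })
  combos <- expand.grid(lapply(perm_list, seq_along))
  pool <- integer(0)
  for (r in seq_len(nrow(combos))) {
    dp <- d
    for (j in seq_len(n_s)) {
      ix <- which(!is.na(d[, j]))
      if (length(ix) > 1L) dp[ix, j] <- d[perm_list[[j]][[combos[r, j]]], j]
    }
    pool <- c(pool, unname(rowSums(dp > threshold_T, na.rm = TRUE)))
  }
  pool
}

# all permutations of 1..n, rows (small n only)
perms_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# classic per-marker one-sample / OLS t-test oracle on differences
classic_t_oracle <- function(d_vec) {
  d_vec <- d_vec[!is.na(d_vec)]
  n <- length(d_vec)
  tt <- stats::t.test(d_vec)
  list(t = unname(tt$statistic), p = tt$p.value,
       est = unname(tt$estimate), df = n - 1L)
}
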