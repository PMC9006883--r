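#' Parameters for the outlier-overexpression detector
#'
#' @param k neighbor count for the co-expression background (default 10).
#' @param min_overlap minimum shared observed samples for a pairwise
#'   correlation; default `NULL` resolves at run time to
#'   `min(n_samples, max(30, ceiling(0.25 * n_samples)))`.
#' @param threshold_T robust-z cutoff for an overexpression call, strict
#'   `>` (default 2).
#' @param n_perm permutation iterations (default 100).
#' @param seed integer RNG seed for the permutation null (default 1).
#' @return list of class `OpptiParams`.
#' @export
oppti_params <- function(k = 10L, min_overlap = NULL, threshold_T = 2,
                         n_perm = 100L, seed = 1L) {
  stopifnot(k >= 1L, n_perm >= 1L, threshold_T > 0)
  structure(list(k = as.integer(k), min_overlap = min_overlap,
                 threshold_T = threshold_T, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "OpptiParams")
}

resolve_min_overlap <- function(min_overlap, n_samples) {
  if (!is.null(min_overlap)) return(as.integer(min_overlap))
  as.integer(min(n_samples, max(30L, ceiling(0.25 * n_samples))))
}

#' Robust per-marker standardization
#'
#' Transforms each marker to robust z-scores across samples,
#' `z = (x - median) / (1.4826 MAD)`, aligning marker scales so weighted
#' neighbor averages are meaningful. Markers with zero MAD are dropped with
#' a warning.
#'
#' @param m an `AbundanceMatrix` (normally `mad_normalized`).
#' @return An `AbundanceMatrix` with `scale_tag = "marker_zscore"`; dropped
#'   markers are recorded in `attr(, "dropped")`.
#' @export
marker_standardize <- function(m) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  v <- m$values
  z <- t(apply(v, 1L, robust_z))
  dimnames(z) <- dimnames(v)
  dropped <- rownames(z)[apply(z, 1L, function(r) all(is.na(r))) &
                           rowSums(!is.na(v)) > 0L]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " zero-MAD marker(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
    z <- z[!(rownames(z) %in% dropped), , drop = FALSE]
  }
  out <- abundance_matrix(z, "marker_zscore")
  attr(out, "dropped") <- dropped
  out
}

#' Build the weighted k-nearest-neighbor map
#'
#' For every marker, finds the `k` other markers with the highest positive
#' Pearson correlation (pairwise-complete, requiring at least `min_overlap`
#' shared observed samples) and assigns weights proportional to the
#' correlations, normalized to sum 1. Anticorrelated markers are never
#' neighbors; markers with no positive correlate are excluded from testing
#' and listed in `attr(, "excluded")`. When fewer than `k + 1` markers are
#' available, `k` is clipped to use all positive-correlated others.
#'
#' @param z a `marker_zscore` `AbundanceMatrix`.
#' @param params an `OpptiParams` object.
#' @return list of class `NeighborMap`: per retained marker a list with
#'   `ids` and `weights`.
#' @export
build_neighbor_map <- function(z, params = oppti_params()) {
  stopifnot(inherits(z, "AbundanceMatrix"))
  v <- z$values
  n_m <- nrow(v)
  if (n_m < 2L) stop("need at least 2 markers to build a neighbor map")
  k <- min(params$k, n_m - 1L) # clip when fewer markers than requested
  min_overlap <- resolve_min_overlap(params$min_overlap, ncol(v))
  cc <- suppressWarnings(stats::cor(t(v), use = "pairwise.complete.obs"))
  obs <- !is.na(v)
  overlap <- tcrossprod(obs * 1)
  cc[overlap < min_overlap] <- NA
  diag(cc) <- NA
  nb <- vector("list", n_m)
  names(nb) <- rownames(v)
  for (i in seq_len(n_m)) {
    r <- cc[i, ]
    pos <- which(!is.na(r) & r > 0)
    if (!length(pos)) next
    top <- pos[order(r[pos], decreasing = TRUE)][seq_len(min(k, length(pos)))]
    w <- r[top] / sum(r[top])
    nb[[i]] <- list(ids = rownames(v)[top], weights = unname(w))
  }
  excluded <- names(nb)[vapply(nb, is.null, logical(1L))]
  nb <- nb[!vapply(nb, is.null, logical(1L))]
  structure(nb, class = "NeighborMap", excluded = excluded)
}

#' Infer the co-expression background
#'
#' Predicts every (marker, sample) cell as the weighted mean of the
#' marker's neighbors' z-scores in that sample, renormalizing weights over
#' the neighbors actually observed there. A cell with no observed neighbor
#' is missing; excluded markers get all-missing rows.
#'
#' @param z a `marker_zscore` `AbundanceMatrix`.
#' @param nb a `NeighborMap` built on the same matrix.
#' @return numeric matrix aligned with `z$values`.
#' @export
infer_background <- function(z, nb) {
  v <- z$values
  out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (mk in names(nb)) {
    nz <- v[nb[[mk]]$ids, , drop = FALSE]
    w <- nb[[mk]]$weights
    wm <- matrix(w, nrow = length(w), ncol = ncol(v))
    wm[is.na(nz)] <- 0
    tot <- colSums(wm)
    pred <- colSums(wm * ifelse(is.na(nz), 0, nz)) / ifelse(tot > 0, tot, NA)
    out[mk, ] <- pred
  }
  out
}

#' Dysregulation scores
#'
#' Deviation of each observed value from its inferred background,
#' `d = z - inferred`, robustly restandardized per marker
#' (`(d - median) / (1.4826 MAD)`) so scores are comparable across markers.
#' Markers whose deviations have zero MAD are untestable and returned as
#' all-missing rows, listed in `attr(, "untestable")`.
#'
#' @param z a `marker_zscore` `AbundanceMatrix`.
#' @param inferred background matrix from [infer_background()].
#' @param restandardize logical; set `FALSE` to get raw deviations.
#' @return numeric score matrix aligned with `z$values`.
#' @export
dysregulation <- function(z, inferred, restandardize = TRUE) {
  d <- z$values - inferred
  if (!restandardize) return(d)
  out <- t(apply(d, 1L, robust_z))
  dimnames(out) <- dimnames(d)
  untestable <- rownames(d)[rowSums(!is.na(d)) > 0L &
                              apply(out, 1L, function(r) all(is.na(r)))]
  attr(out, "untestable") <- untestable
  out
}

#' Call overexpression events
#'
#' A cell is called overexpressed when its dysregulation score strictly
#' exceeds the cutoff `T`; missing scores are never called.
#'
#' @param d restandardized score matrix.
#' @param threshold_T cutoff in robust-z units (default 2).
#' @return logical matrix of calls.
#' @export
call_overexpression <- function(d, threshold_T = 2) {
  !is.na(d) & d > threshold_T
}

#' Within-sample permutation null for overexpression counts
#'
#' For each iteration, the observed dysregulation scores are independently
#' permuted within every sample across markers (missing entries stay in
#' place), and per-marker exceedance counts of `T` are recomputed. Counts
#' from all iterations are pooled into one empirical null. With
#' `exact = TRUE` the Cartesian product of all within-sample permutations
#' is enumerated instead (small matrices only).
#'
#' @param d restandardized score matrix.
#' @param threshold_T call cutoff.
#' @param n_perm number of iterations (ignored when `exact = TRUE`).
#' @param seed RNG seed.
#' @param exact enumerate all within-sample permutations exhaustively.
#' @param max_exact guard on the number of enumerated assignments.
#' @return list of class `PermutationNull`: `counts` (pooled integer
#'   vector of length iterations x markers), `n_perm`, `seed`, `exact`.
#' @export
permutation_null <- function(d, threshold_T = 2, n_perm = 100L, seed = 1L,
                             exact = FALSE, max_exact = 2e5) {
  if (nrow(d) < 2L) stop("permutation null needs at least 2 markers")
  if (!exact && n_perm < 1L) stop("n_perm must be >= 1")
  n_m <- nrow(d); n_s <- ncol(d)
  if (exact) {
    obs_idx <- lapply(seq_len(n_s), function(j) which(!is.na(d[, j])))
    perms <- lapply(obs_idx, function(ix) all_permutations(length(ix)))
    n_assign <- prod(vapply(perms, nrow, numeric(1L)))
    if (n_assign > max_exact) {
      stop("exact enumeration would need ", n_assign, " assignments (limit ",
           max_exact, ")")
    }
    counts <- integer(0)
    grid <- rep(1L, n_s)
    repeat {
      dp <- d
      for (j in seq_len(n_s)) {
        ix <- obs_idx[[j]]
        if (length(ix) > 1L) dp[ix, j] <- d[ix[perms[[j]][grid[j], ]], j]
      }
      counts <- c(counts, rowSums(dp > threshold_T, na.rm = TRUE))
      # odometer increment over the per-sample permutation indices
      j <- 1L
      while (j <= n_s) {
        grid[j] <- grid[j] + 1L
        if (grid[j] <= nrow(perms[[j]])) break
        grid[j] <- 1L; j <- j + 1L
      }
      if (j > n_s) break
    }
    return(structure(list(counts = as.integer(counts),
                          n_perm = as.integer(n_assign), seed = NA_integer_,
                          exact = TRUE),
                     class = "PermutationNull"))
  }
  counts <- with_seed(seed, {
    acc <- integer(0)
    for (it in seq_len(n_perm)) {
      dp <- d
      for (j in seq_len(n_s)) {
        ix <- which(!is.na(d[, j]))
        if (length(ix) > 1L) dp[ix, j] <- d[sample(ix), j]
      }
      acc <- c(acc, rowSums(dp > threshold_T, na.rm = TRUE))
    }
    acc
  })
  structure(list(counts = as.integer(counts), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), exact = FALSE),
            class = "PermutationNull")
}

# all permutations of 1..n as rows (n <= 7 kept small by the exact guard)
all_permutations <- function(n) {
  if (n <= 1L) return(matrix(1L, 1L, max(n, 1L)))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Permutation p-values for overexpression enrichment
#'
#' Add-one empirical p-value of each marker's observed call count against
#' the pooled permutation null:
#' `p = (1 + #\{null >= observed\}) / (1 + pool size)`.
#'
#' @param observed_counts integer vector of observed per-marker call counts.
#' @param null a `PermutationNull`.
#' @return numeric vector of p-values.
#' @export
enrichment_pvalues <- function(observed_counts, null) {
  stopifnot(inherits(null, "PermutationNull"), length(null$counts) > 0L)
  pool <- null$counts
  vapply(observed_counts, function(ct) {
    if (is.na(ct)) return(NA_real_)
    (1 + sum(pool >= ct)) / (1 + length(pool))
  }, numeric(1L))
}

#' Run the outlier-overexpression detector
#'
#' Full pipeline on a tumor-sample matrix (proteome or transcriptome):
#' robust marker standardization, weighted-KNN co-expression background,
#' dysregulation scoring, overexpression calls at the `T` cutoff, a
#' within-sample permutation null, add-one permutation p-values and BH FDR.
#' The overexpression rate `pro` is calls divided by quantified (non
#' missing) samples for the marker. Markers that are dropped (zero MAD),
#' have no positive co-expression neighbor, or have untestable
#' dysregulation are reported with missing statistics.
#'
#' @param m an `AbundanceMatrix` of tumor samples (typically
#'   `mad_normalized`; a `marker_zscore` matrix is used as-is).
#' @param params an `OpptiParams` object.
#' @return list of class `OpptiResult`: `table` (marker, pro, n_called,
#'   n_quantified, perm_p, fdr), `dysregulation` and `calls` matrices,
#'   `params`, `excluded`.
#' @export
run_oppti <- function(m, params = oppti_params()) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  z <- if (m$scale_tag == "marker_zscore") m else marker_standardize(m)
  nb <- build_neighbor_map(z, params)
  inferred <- infer_background(z, nb)
  d <- dysregulation(z, inferred)
  calls <- call_overexpression(d, params$threshold_T)
  testable <- rownames(d)[rowSums(!is.na(d)) > 0L]
  null <- permutation_null(d[testable, , drop = FALSE], params$threshold_T,
                           params$n_perm, params$seed)
  mk <- markers(m)
  n_quant <- rowSums(!is.na(m$values))[mk]
  n_called <- rep(NA_integer_, length(mk)); names(n_called) <- mk
  n_called[rownames(calls)] <- rowSums(calls)
  n_called[setdiff(mk, testable)] <- NA_integer_
  perm_p <- rep(NA_real_, length(mk)); names(perm_p) <- mk
  perm_p[testable] <- enrichment_pvalues(
    rowSums(calls[testable, , drop = FALSE]), null)
  fdr <- bh_fdr(perm_p)
  tab <- data.frame(marker = mk,
                    pro = ifelse(n_quant > 0, n_called / n_quant, NA_real_),
                    n_called = n_called, n_quantified = n_quant,
                    perm_p = perm_p, fdr = fdr, row.names = NULL)
  structure(list(table = tab, dysregulation = d, calls = calls,
                 params = params,
                 excluded = union(attr(z, "dropped") %||% character(0),
                                  attr(nb, "excluded"))),
            class = "OpptiResult")
}

#' @export
print.OpptiResult <- function(x, ...) {
  sig <- sum(x$table$fdr < 0.05, na.rm = TRUE)
  cat(sprintf(
    "OpptiResult: %d markers (%d untestable), %d enriched at FDR < 0.05 (T = %g, n_perm = %d)\n",
    nrow(x$table), sum(is.na(x$table$perm_p)), sig,
    x$params$threshold_T, x$params$n_perm))
  invisible(x)
}
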