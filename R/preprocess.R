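#' Per-sample MAD normalization
#'
#' Divides each sample's non-missing values by that sample's median absolute
#' deviation (median of absolute deviations from the sample median, no
#' Gaussian consistency constant), so every sample ends at unit MAD. Values
#' are log-ratio abundances and are assumed near-centered already; optional
#' median-centering is available but off by default.
#'
#' @param m an `AbundanceMatrix` with `scale_tag = "raw"`.
#' @param center logical; subtract the sample median before scaling.
#' @return An `AbundanceMatrix` with `scale_tag = "mad_normalized"`.
#' @export
mad_normalize <- function(m, center = FALSE) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (m$scale_tag != "raw") stop("mad_normalize expects a raw matrix")
  v <- m$values
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    if (sum(!is.na(x)) < 2L || length(unique(x[!is.na(x)])) < 2L) {
      stop("sample '", colnames(v)[j], "' has fewer than 2 distinct observed values")
    }
    s <- mad_raw(x)
    if (s == 0) stop("sample '", colnames(v)[j], "' has MAD = 0 (degenerate sample)")
    if (center) x <- x - stats::median(x, na.rm = TRUE)
    v[, j] <- x / s
  }
  abundance_matrix(v, "mad_normalized")
}

#' Drop markers with high missingness
#'
#' Removes markers whose missing fraction is at least `max_missing_frac`
#' (the boundary itself is removed); surviving markers keep their order and
#' values untouched.
#'
#' @param m an `AbundanceMatrix`.
#' @param max_missing_frac fraction in (0, 1]; default 0.20.
#' @param report logical; also return the per-marker filter report.
#' @return The filtered `AbundanceMatrix`, or if `report = TRUE` a list
#'   with elements `matrix` and `report` (marker, missing_frac, kept).
#' @export
filter_missing_markers <- function(m, max_missing_frac = 0.20, report = FALSE) {
  stopifnot(inherits(m, "AbundanceMatrix"),
            max_missing_frac > 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(m$values))
  keep <- frac < max_missing_frac
  if (!any(keep)) stop("all markers removed by the missingness filter (empty cohort)")
  out <- abundance_matrix(m$values[keep, , drop = FALSE], m$scale_tag)
  if (!report) return(out)
  list(matrix = out,
       report = data.frame(marker = rownames(m$values), missing_frac = frac,
                           kept = keep, row.names = NULL))
}

#' Normalize an FPKM transcriptome matrix
#'
#' Removes genes with zero expression in at least `rna_zero_frac` of the
#' samples, transforms survivors to `log2(FPKM + pseudocount)`, then
#' quantile-normalizes so all samples share the same sorted value vector
#' (reference = mean of order statistics; ties get the mean of their
#' reference quantiles). The log transform is applied before quantile
#' normalization; both orders are rank-equivalent within sample and the
#' log-first order keeps the reference distribution scale-stable.
#'
#' @param fpkm an `AbundanceMatrix` of nonnegative FPKM values.
#' @param rna_zero_frac zero-fraction filter threshold; default 0.20.
#' @param pseudocount added before log2; default 1.
#' @return An `AbundanceMatrix` (tag `mad_normalized` is not used here; the
#'   result carries tag `"raw"` and is ready for marker standardization).
#' @export
normalize_rna <- function(fpkm, rna_zero_frac = 0.20, pseudocount = 1) {
  stopifnot(inherits(fpkm, "AbundanceMatrix"))
  v <- fpkm$values
  if (any(v < 0, na.rm = TRUE)) stop("negative FPKM value encountered")
  zfrac <- rowMeans(v == 0, na.rm = TRUE)
  keep <- zfrac < rna_zero_frac
  if (!any(keep)) stop("all genes removed by the zero-expression filter")
  v <- log2(v[keep, , drop = FALSE] + pseudocount)
  abundance_matrix(quantile_normalize(v), "raw")
}

#' Quantile-normalize columns of a matrix
#'
#' Columns are forced onto a common reference distribution: the mean of the
#' per-column order statistics. Tied values within a column receive the
#' mean of the reference values their ranks span. Missing entries are
#' normalized per column using only the observed entries' ranks, mapped
#' into the reference quantile function by linear interpolation.
#'
#' @param v numeric matrix.
#' @return matrix of the same shape, quantile-normalized by column.
#' @export
quantile_normalize <- function(v) {
  n <- nrow(v)
  if (n == 0L || ncol(v) == 0L) return(v)
  # reference quantile function on probabilities (i - 0.5) / n_obs per column,
  # averaged across columns on a common length-n grid
  p_grid <- (seq_len(n) - 0.5) / n
  qmat <- vapply(seq_len(ncol(v)), function(j) {
    x <- sort(v[!is.na(v[, j]), j])
    if (length(x) == 0L) return(rep(NA_real_, n))
    if (length(x) == 1L) return(rep(x, n))
    p_obs <- (seq_along(x) - 0.5) / length(x)
    stats::approx(p_obs, x, xout = p_grid, rule = 2)$y
  }, numeric(n))
  ref <- rowMeans(qmat, na.rm = TRUE)
  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    if (!length(obs)) next
    x <- v[obs, j]
    m_j <- length(x)
    if (m_j == n) {
      # complete column: assign reference order statistics directly so that
      # sorted columns are exactly identical across complete samples
      r <- rank(x, ties.method = "min")
      rmax <- rank(x, ties.method = "max")
      sorted_ref <- if (m_j > 1L) {
        stats::approx(p_grid, ref, xout = (seq_len(m_j) - 0.5) / m_j, rule = 2)$y
      } else ref[1L]
      out[obs, j] <- vapply(seq_len(m_j),
                            function(i) mean(sorted_ref[r[i]:rmax[i]]), numeric(1L))
    } else {
      r <- rank(x, ties.method = "average")
      p <- (r - 0.5) / m_j
      out[obs, j] <- stats::approx(p_grid, ref, xout = p, rule = 2)$y
    }
  }
  out
}
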