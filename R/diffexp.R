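#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Classic step-up adjustment: for sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1. Missing p-values
#' propagate as missing and do not count toward `m`.
#'
#' @param pvalues numeric vector in \[0, 1\] (NA allowed).
#' @return vector of adjusted values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  m <- length(p)
  if (m == 0L) return(out)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / (m - seq_len(m) + 1L)))[ro]
  out[ok] <- q
  out
}

#' Build within-pair tumor-minus-normal differences
#'
#' For each subject with both a tumor and a normal sample, computes per
#' marker `d = tumor - normal` where both values are observed. Subject-level
#' covariates (age, numeric-coded gender, optionally batch) are carried
#' alongside and mean-centered, so the intercept of the difference model is
#' the covariate-adjusted log2 fold change.
#'
#' @param m an `AbundanceMatrix` (markers x samples).
#' @param meta a `SampleMeta` table covering the matrix samples.
#' @param covariates character vector among `c("age", "gender", "batch")`;
#'   covariates that are entirely missing are dropped silently.
#' @return list with `d` (markers x subjects difference matrix), `covars`
#'   (subjects x covariates numeric matrix, mean-centered, possibly zero
#'   columns), and `subjects`.
#' @export
build_paired_differences <- function(m, meta, covariates = c("age", "gender")) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  meta <- sample_meta(as.data.frame(meta))
  meta <- meta[meta$sample_id %in% samples(m), , drop = FALSE]
  tum <- meta[meta$tissue == "tumor", ]
  nor <- meta[meta$tissue == "normal", ]
  subjects <- intersect(tum$subject_id, nor$subject_id)
  if (!length(subjects)) stop("no subject has both a tumor and a normal sample")
  ts <- tum$sample_id[match(subjects, tum$subject_id)]
  ns <- nor$sample_id[match(subjects, nor$subject_id)]
  d <- m$values[, ts, drop = FALSE] - m$values[, ns, drop = FALSE]
  colnames(d) <- subjects

  cols <- list()
  sub_meta <- tum[match(subjects, tum$subject_id), ]
  for (cov in covariates) {
    x <- sub_meta[[cov]]
    if (is.null(x) || all(is.na(x))) next
    if (!is.numeric(x)) x <- as.numeric(factor(x))
    cols[[cov]] <- x
  }
  covars <- if (!length(cols)) {
    matrix(numeric(0), nrow = length(subjects), ncol = 0L,
           dimnames = list(subjects, NULL))
  } else {
    cm <- do.call(cbind, cols)
    rownames(cm) <- subjects
    sweep(cm, 2L, colMeans(cm, na.rm = TRUE))
  }
  list(d = d, covars = covars, subjects = subjects)
}

#' Per-marker least-squares fit of paired differences
#'
#' Fits `d ~ intercept + centered covariates` by OLS on the subjects where
#' the difference is observed. The intercept is the adjusted log2 fold
#' change. Collinear covariates (including constants) are dropped with a
#' warning. Subjects with a missing covariate value are excluded.
#'
#' @param d numeric difference vector (NA allowed).
#' @param covars numeric matrix of mean-centered covariates (may have zero
#'   columns), rows aligned with `d`.
#' @return list `log2fc`, `s_sq` (residual variance), `df` (residual
#'   degrees of freedom), `v` (unscaled variance of the intercept,
#'   `Var(log2fc) = s_sq * v`), `n_pairs`.
#' @export
fit_marker_model <- function(d, covars = NULL) {
  if (is.null(covars)) covars <- matrix(numeric(0), nrow = length(d), ncol = 0L)
  ok <- !is.na(d) & !apply(is.na(covars), 1L, any)
  y <- d[ok]
  X <- cbind(`(Intercept)` = 1, covars[ok, , drop = FALSE])
  n <- length(y)
  if (n < 1L) return(list(log2fc = NA_real_, s_sq = NA_real_, df = 0L,
                          v = NA_real_, n_pairs = 0L))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("dropping collinear covariate(s): ", paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- n - ncol(X)
  s_sq <- if (df > 0L) sum(res^2) / df else NA_real_
  xtx_inv <- chol2inv(qr.R(qrX))
  list(log2fc = unname(beta["(Intercept)"]), s_sq = s_sq, df = df,
       v = xtx_inv[1L, 1L], n_pairs = n)
}

#' Estimate the variance-moderation prior
#'
#' Empirical-Bayes prior for residual variances under the scaled
#' chi-square model `s^2 | sigma^2 ~ sigma^2 chi^2_df / df`,
#' `1/sigma^2 ~ chi^2_d0 / (d0 s0^2)`. The prior degrees of freedom `d0`
#' and prior variance `s0^2` are estimated by moment matching on
#' `log(s^2)` using digamma/trigamma identities; if the trigamma equation
#' has no positive solution the prior is degenerate (`d0 = Inf`) and
#' `s0^2` is the bias-corrected geometric mean.
#'
#' @param s_sq vector of residual variances (finite, positive).
#' @param df matching residual degrees of freedom (positive).
#' @param min_markers minimum markers required; default 10.
#' @return list of class `ModerationFit` with `d0` and `s0_sq`.
#' @export
fit_moderation <- function(s_sq, df, min_markers = 10L) {
  if (length(df) == 1L) df <- rep(df, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & is.finite(df) & df > 0
  s_sq <- s_sq[ok]; df <- df[ok]
  n <- length(s_sq)
  if (n < min_markers) stop("fit_moderation needs at least ", min_markers,
                            " markers with positive residual variance")
  if (diff(range(s_sq)) < 1e-12 * max(s_sq)) {
    # degenerate: no variance heterogeneity at all
    return(structure(list(d0 = Inf, s0_sq = s_sq[1L]), class = "ModerationFit"))
  }
  e <- log(s_sq) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1L)
  rhs <- evar - mean(trigamma(df / 2))
  if (is.finite(rhs) && rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ModerationFit")
}

# Newton solve of trigamma(y) = x for y > 0 (monotone decreasing)
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated t-statistic and two-sided p-value
#'
#' Shrinks each marker's residual variance toward the prior,
#' `s_tilde^2 = (d0 s0^2 + df s^2) / (d0 + df)`, and forms
#' `t = log2fc / sqrt(s_tilde^2 v)` referred to a t distribution on
#' `df + d0` degrees of freedom (standard normal when `d0 = Inf`). With
#' `d0 = 0` this is exactly the ordinary OLS t-test.
#'
#' @param log2fc effect estimate(s).
#' @param s_sq residual variance(s).
#' @param df residual degrees of freedom.
#' @param fit a `ModerationFit` (or list with `d0`, `s0_sq`).
#' @param v unscaled coefficient variance (e.g. `1/n` for a mean).
#' @return list with `t_mod`, `pvalue`, `s_tilde_sq`, `df_total`.
#' @export
moderated_t <- function(log2fc, s_sq, df, fit, v) {
  d0 <- fit$d0; s0_sq <- fit$s0_sq
  stopifnot(d0 >= 0, is.finite(s0_sq) || d0 == 0)
  s_tilde <- if (is.infinite(d0)) {
    rep(s0_sq, length(log2fc)) # the d0 -> Inf limit of the blend is the prior
  } else {
    (d0 * s0_sq + df * s_sq) / (d0 + df)
  }
  df_total <- df + d0
  t_mod <- log2fc / sqrt(s_tilde * v)
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t_mod)),
              2 * stats::pt(-abs(t_mod), df = df_total))
  list(t_mod = t_mod, pvalue = p, s_tilde_sq = s_tilde, df_total = df_total)
}

#' Paired moderated differential expression
#'
#' The tumor-vs-normal differential expression stage: within-pair
#' differences, per-marker covariate-adjusted OLS, empirical-Bayes variance
#' moderation across markers, moderated t-tests and BH FDR. Markers with
#' fewer than `min_pairs` complete pairs are reported with missing
#' statistics; markers with zero residual degrees of freedom are excluded
#' from prior estimation but still moderated.
#'
#' @param m an `AbundanceMatrix`.
#' @param meta a `SampleMeta` table.
#' @param covariates covariate names passed to [build_paired_differences()].
#' @param min_pairs minimum complete pairs for a marker to be tested
#'   (default 10).
#' @param fdr_max significance threshold on BH FDR (default 0.05).
#' @param fc_min up-regulation threshold on log2fc (default 1).
#' @param d0_override optional fixed prior df (e.g. 0 for unmoderated OLS).
#' @return data.frame (class `DepTable`): marker, log2fc, t_mod, pvalue,
#'   fdr, n_pairs, significant, up2fold.
#' @export
run_diffexp <- function(m, meta, covariates = c("age", "gender"),
                        min_pairs = 10L, fdr_max = 0.05, fc_min = 1,
                        d0_override = NULL) {
  pd <- build_paired_differences(m, meta, covariates)
  mk <- markers(m)
  fits <- lapply(seq_along(mk), function(i) {
    fit_marker_model(pd$d[i, ], pd$covars)
  })
  n_pairs <- vapply(fits, `[[`, integer(1L), "n_pairs")
  log2fc <- vapply(fits, `[[`, numeric(1L), "log2fc")
  s_sq <- vapply(fits, `[[`, numeric(1L), "s_sq")
  df <- vapply(fits, function(f) as.numeric(f$df), numeric(1L))
  v <- vapply(fits, `[[`, numeric(1L), "v")
  testable <- n_pairs >= min_pairs & is.finite(s_sq)

  fit <- if (!is.null(d0_override)) {
    list(d0 = d0_override,
         s0_sq = if (d0_override > 0) {
           fit_moderation(s_sq[testable], df[testable])$s0_sq
         } else 1)
  } else {
    fit_moderation(s_sq[testable], df[testable])
  }

  t_mod <- rep(NA_real_, length(mk)); pval <- rep(NA_real_, length(mk))
  if (any(testable)) {
    mt <- moderated_t(log2fc[testable], s_sq[testable], df[testable], fit,
                      v[testable])
    t_mod[testable] <- mt$t_mod
    pval[testable] <- mt$pvalue
  }
  fdr <- bh_fdr(pval)
  out <- data.frame(marker = mk, log2fc = ifelse(testable, log2fc, NA_real_),
                    t_mod = t_mod, pvalue = pval, fdr = fdr,
                    n_pairs = n_pairs,
                    significant = !is.na(fdr) & fdr < fdr_max,
                    up2fold = testable & !is.na(log2fc) & log2fc >= fc_min,
                    row.names = NULL)
  attr(out, "moderation") <- list(d0 = fit$d0, s0_sq = fit$s0_sq)
  class(out) <- c("DepTable", "data.frame")
  out
}
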