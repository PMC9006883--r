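#' Drug screen container
#'
#' Bundles a drugs-by-cell-lines percent-viability matrix, a
#' targets-by-cell-lines baseline expression matrix, and the drug-to-target
#' map connecting them.
#'
#' @param viability numeric matrix, drugs x cell lines.
#' @param expression numeric matrix, targets x cell lines.
#' @param drug_target_map data.frame with columns `drug`, `target`.
#' @return list of class `DrugScreen`.
#' @export
drug_screen <- function(viability, expression, drug_target_map) {
  stopifnot(is.matrix(viability), is.matrix(expression),
            !is.null(rownames(viability)), !is.null(colnames(viability)),
            !is.null(rownames(expression)), !is.null(colnames(expression)),
            all(c("drug", "target") %in% names(drug_target_map)))
  structure(list(viability = viability, expression = expression,
                 drug_target_map = drug_target_map[, c("drug", "target")]),
            class = "DrugScreen")
}

#' Align a drug screen on the shared cell lines
#'
#' Intersects the cell-line sets of the viability and expression matrices
#' and flags (drug, target) pairs that cannot be tested: target missing
#' from the expression rows, drug missing from the viability rows, or
#' fewer than `min_lines` complete (viability, expression) observations.
#'
#' @param screen a `DrugScreen`.
#' @param min_lines minimum complete observations per pair (default 3).
#' @return a `DrugScreen` restricted to shared lines, with
#'   `attr(, "skipped")` a data.frame (drug, target, reason).
#' @export
align_screen <- function(screen, min_lines = 3L) {
  stopifnot(inherits(screen, "DrugScreen"))
  lines <- intersect(colnames(screen$viability), colnames(screen$expression))
  if (!length(lines)) stop("no shared cell lines between viability and expression")
  vb <- screen$viability[, lines, drop = FALSE]
  ex <- screen$expression[, lines, drop = FALSE]
  map <- screen$drug_target_map
  reason <- rep(NA_character_, nrow(map))
  for (i in seq_len(nrow(map))) {
    if (!map$drug[i] %in% rownames(vb)) { reason[i] <- "drug_not_screened"; next }
    if (!map$target[i] %in% rownames(ex)) { reason[i] <- "target_not_measured"; next }
    n <- sum(!is.na(vb[map$drug[i], ]) & !is.na(ex[map$target[i], ]))
    if (n < min_lines) reason[i] <- "too_few_lines"
  }
  out <- drug_screen(vb, ex, map[is.na(reason), , drop = FALSE])
  attr(out, "skipped") <- data.frame(map[!is.na(reason), , drop = FALSE],
                                     reason = reason[!is.na(reason)],
                                     row.names = NULL)
  out
}

#' Regress cell viability on target expression
#'
#' Ordinary least-squares fit of viability on baseline expression across
#' the complete cell lines; the slope (viability units per expression
#' unit) is the reported dependency coefficient — negative means higher
#' expression predicts lower viability, i.e. an expression-driven
#' dependency. The p-value is the two-sided t-test for slope = 0.
#'
#' @param viability_row,expression_row numeric vectors over the same lines.
#' @return list: `slope`, `pvalue`, `n_lines` (NA statistics when the
#'   expression is constant or fewer than 3 complete pairs exist).
#' @export
fit_dependency <- function(viability_row, expression_row) {
  ok <- !is.na(viability_row) & !is.na(expression_row)
  n <- sum(ok)
  if (n < 3L) return(list(slope = NA_real_, pvalue = NA_real_, n_lines = n))
  x <- expression_row[ok]; y <- viability_row[ok]
  if (length(unique(x)) < 2L) {
    return(list(slope = NA_real_, pvalue = NA_real_, n_lines = n))
  }
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  res <- y - (mean(y) + slope * (x - mean(x)))
  s_sq <- sum(res^2) / (n - 2L)
  se <- sqrt(s_sq / sxx)
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), df = n - 2L)
  list(slope = slope, pvalue = p, n_lines = n)
}

#' Expression-driven dependency scan over a drug screen
#'
#' Runs [fit_dependency()] for every mapped (drug, target) pair of an
#' aligned screen, BH-adjusts the p-values jointly across all tested
#' pairs, and sorts by slope ascending so the strongest dependencies
#' (most negative slopes) come first.
#'
#' @param screen a `DrugScreen` (aligned with [align_screen()] if needed).
#' @param min_lines minimum complete observations per pair (default 3).
#' @return data.frame of class `DependencyTable`: drug, target, slope,
#'   pvalue, fdr, n_lines; `attr(, "skipped")` carries untestable pairs.
#' @export
run_dependency <- function(screen, min_lines = 3L) {
  aligned <- align_screen(screen, min_lines)
  map <- aligned$drug_target_map
  fits <- lapply(seq_len(nrow(map)), function(i) {
    fit_dependency(aligned$viability[map$drug[i], ],
                   aligned$expression[map$target[i], ])
  })
  out <- data.frame(
    drug = map$drug, target = map$target,
    slope = vapply(fits, `[[`, numeric(1L), "slope"),
    pvalue = vapply(fits, `[[`, numeric(1L), "pvalue"),
    n_lines = vapply(fits, function(f) as.integer(f$n_lines), integer(1L)),
    row.names = NULL)
  out$fdr <- bh_fdr(out$pvalue)
  out <- out[order(out$slope, out$drug, out$target), ,
             drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("drug", "target", "slope", "pvalue", "fdr", "n_lines")]
  attr(out, "skipped") <- attr(aligned, "skipped")
  class(out) <- c("DependencyTable", "data.frame")
  out
}

#' Pairwise Pearson correlation between two measurement rows
#'
#' Generic biomarker check (ligand vs receptor expression, ligand
#' expression vs drug response, ...): Pearson correlation over complete
#' pairs with the two-sided t-based p-value.
#'
#' @param x_row,y_row numeric vectors over the same samples/lines.
#' @return list: `r`, `pvalue`, `n` (`r` missing when an input is
#'   constant).
#' @export
biomarker_correlation <- function(x_row, y_row) {
  ok <- !is.na(x_row) & !is.na(y_row)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 complete pairs, have ", n)
  x <- x_row[ok]; y <- y_row[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(r = NA_real_, pvalue = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = n)
}
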