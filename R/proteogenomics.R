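#' Retain likely-functional somatic mutations
#'
#' Keeps every truncating mutation (frameshift/non-frameshift indel,
#' stop-gain, stop-loss) and every missense mutation whose
#' (gene, protein_change) occurs at least `min_recurrence` times in the
#' reference recurrence catalog; everything else is dropped. Idempotent.
#'
#' @param muts a `MutationTable`.
#' @param catalog a `RecurrenceCatalog` (gene, protein_change, count).
#' @param min_recurrence minimum catalog count for missense retention
#'   (default 3).
#' @return filtered `MutationTable`.
#' @export
filter_driver_mutations <- function(muts, catalog, min_recurrence = 3L) {
  stopifnot(inherits(muts, "MutationTable"))
  if (nrow(muts) == 0L) return(muts)
  trunc_keep <- muts$variant_class %in% TRUNCATING_CLASSES
  key <- paste(muts$gene, muts$protein_change, sep = "\r")
  cat_key <- paste(catalog$gene, catalog$protein_change, sep = "\r")
  counts <- catalog$count[match(key, cat_key)]
  mis_keep <- muts$variant_class == "missense" &
    !is.na(counts) & counts >= min_recurrence
  out <- muts[trunc_keep | mis_keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MutationTable", "data.frame")
  out
}

#' DNA alteration fraction of a gene
#'
#' Fraction of cohort samples carrying at least one retained mutation in
#' the gene; a sample with several retained mutations counts once. A gene
#' absent from the table has fraction 0.
#'
#' @param muts a filtered `MutationTable`.
#' @param gene gene symbol.
#' @param cohort_samples character vector of all cohort sample IDs.
#' @return fraction in \[0, 1\].
#' @export
dna_alteration_fraction <- function(muts, gene, cohort_samples) {
  stopifnot(length(cohort_samples) > 0L)
  carriers <- unique(muts$sample_id[muts$gene == gene])
  carriers <- intersect(carriers, cohort_samples)
  length(carriers) / length(cohort_samples)
}

#' Summarize DNA, RNA and protein alteration rates per gene
#'
#' Joins per-gene DNA mutation fractions, mRNA overexpression rates (the
#' detector run on the transcriptome with the same parameters) and protein
#' overexpression rates. Flags: `high_pro` when `PRO >= pro_min` (default
#' 0.10), `pro_over_rna_2x` when `PRO >= rna_fold * RNA` (default 2) and
#' RNA is available — a missing RNA layer never produces a fold-change
#' claim. `candidate` = both flags.
#'
#' @param dna_fracs named numeric vector of DNA fractions (may be NULL).
#' @param rna_pro named numeric vector (or `OpptiResult`) of mRNA
#'   overexpression rates.
#' @param pro named numeric vector (or `OpptiResult`) of protein
#'   overexpression rates.
#' @param pro_min high-overexpression threshold (default 0.10, `>=`).
#' @param rna_fold protein-vs-RNA fold threshold (default 2, `>=`).
#' @return data.frame of class `AlterationSummary`: gene, dna_frac,
#'   rna_over, pro, high_pro, pro_over_rna_2x, candidate.
#' @export
build_alteration_summary <- function(dna_fracs = NULL, rna_pro = NULL, pro,
                                     pro_min = 0.10, rna_fold = 2) {
  as_rate <- function(x) {
    if (inherits(x, "OpptiResult")) stats::setNames(x$table$pro, x$table$marker)
    else x
  }
  pro <- as_rate(pro); rna_pro <- as_rate(rna_pro)
  genes <- names(pro)
  stopifnot(!is.null(genes))
  dna <- if (is.null(dna_fracs)) rep(NA_real_, length(genes)) else
    unname(dna_fracs[genes])
  rna <- if (is.null(rna_pro)) rep(NA_real_, length(genes)) else
    unname(rna_pro[genes])
  stopifnot(all(pro >= 0 & pro <= 1, na.rm = TRUE),
            all(dna >= 0 & dna <= 1, na.rm = TRUE),
            all(rna >= 0 & rna <= 1, na.rm = TRUE))
  high_pro <- !is.na(pro) & pro >= pro_min
  pro2x <- !is.na(pro) & !is.na(rna) & pro >= rna_fold * rna
  out <- data.frame(gene = genes, dna_frac = dna, rna_over = rna,
                    pro = unname(pro), high_pro = high_pro,
                    pro_over_rna_2x = pro2x,
                    candidate = high_pro & pro2x, row.names = NULL)
  class(out) <- c("AlterationSummary", "data.frame")
  out
}

#' Select druggable candidate targets
#'
#' Strict tier: druggable markers with `log2fc >= fc_min`, differential
#' expression FDR `< fdr_max`, and overexpression FDR `< fdr_max` (the
#' printed operators: thresholds `>=`, FDRs strict `<`). The laxer
#' "both positive" tier additionally reports druggable markers with
#' `log2fc > 0` and `PRO > 0`.
#'
#' @param dep a `DepTable` from [run_diffexp()].
#' @param oppti an `OpptiResult` (or its `table`).
#' @param druggable character vector of druggable gene symbols.
#' @param fc_min log2 fold-change threshold (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return data.frame: marker, log2fc, dep_fdr, pro, oppti_fdr,
#'   both_positive, candidate; restricted to druggable markers present in
#'   both tables.
#' @export
select_candidates <- function(dep, oppti, druggable, fc_min = 1,
                              fdr_max = 0.05) {
  ot <- if (inherits(oppti, "OpptiResult")) oppti$table else oppti
  shared <- intersect(dep$marker, ot$marker)
  shared <- shared[shared %in% druggable]
  di <- match(shared, dep$marker); oi <- match(shared, ot$marker)
  log2fc <- dep$log2fc[di]; dfdr <- dep$fdr[di]
  pro <- ot$pro[oi]; ofdr <- ot$fdr[oi]
  both_pos <- !is.na(log2fc) & log2fc > 0 & !is.na(pro) & pro > 0
  cand <- !is.na(log2fc) & log2fc >= fc_min &
    !is.na(dfdr) & dfdr < fdr_max & !is.na(ofdr) & ofdr < fdr_max
  out <- data.frame(marker = shared, log2fc = log2fc, dep_fdr = dfdr,
                    pro = pro, oppti_fdr = ofdr, both_positive = both_pos,
                    candidate = cand, row.names = NULL)
  out <- out[order(out$marker), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-cohort concordance of overexpression rates
#'
#' Pearson correlation of per-marker overexpression rates over the shared
#' marker set of two cohorts, with the two-sided t-transformation p-value.
#'
#' @param pro_a,pro_b `OpptiResult` objects or named rate vectors.
#' @return list: `r`, `pvalue`, `n_shared`.
#' @export
cohort_concordance <- function(pro_a, pro_b) {
  as_rate <- function(x) {
    if (inherits(x, "OpptiResult")) stats::setNames(x$table$pro, x$table$marker)
    else x
  }
  a <- as_rate(pro_a); b <- as_rate(pro_b)
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(shared) < 3L) stop("need at least 3 shared markers, have ",
                                length(shared))
  ct <- stats::cor.test(a[shared], b[shared], method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value,
       n_shared = length(shared))
}
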