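#' Default pipeline configuration
#'
#' All analysis thresholds with their conventional defaults: missingness
#' filter 0.20, minimum pairs 10, FDR 0.05, log2 fold-change 1, high
#' overexpression rate 0.10, call cutoff T = 2, missense recurrence 3.
#'
#' @param seed global seed, expanded into per-stage child seeds.
#' @param ... overrides for any default entry.
#' @return named list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed),
              max_missing_frac = 0.20, rna_zero_frac = 0.20,
              min_pairs = 10L, fdr_max = 0.05, fc_min = 1,
              pro_min = 0.10, rna_fold = 2,
              k = 10L, threshold_T = 2, n_perm = 100L, min_overlap = NULL,
              min_recurrence = 3L, min_lines = 3L,
              covariates = c("age", "gender"))
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Run the full target-discovery pipeline on a simulated or supplied bundle
#'
#' Orchestrates preprocess -> paired differential expression -> outlier
#' overexpression (protein, and RNA when present) -> mutation filtering and
#' DNA/RNA/protein comparison -> druggable-candidate intersection ->
#' drug-screen dependency (when a screen is present). Every stage consumes
#' the previous stage's in-memory objects; per-stage TSVs and a manifest
#' are written when `out_dir` is given.
#'
#' @param inputs list with elements `tumor`, `normal` (`AbundanceMatrix`),
#'   `meta` (`SampleMeta`), and optionally `rna` (`AbundanceMatrix`, FPKM),
#'   `mutations` + `catalog`, `druggable` (character), `screen`
#'   (`DrugScreen`), `truth`. Use [simulate_bundle()] to build one.
#' @param config list from [default_config()].
#' @param out_dir optional output directory for stage TSVs and manifest.
#' @return list of class `PipelineBundle` with per-stage results.
#' @export
run_full_pipeline <- function(inputs, config = default_config(),
                              out_dir = NULL) {
  need <- c("tumor", "normal", "meta")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("pipeline inputs missing: ", paste(miss, collapse = ", "))

  # preprocess: missingness filter on the combined cohort, per-sample MAD
  combined <- bind_cohort(inputs$tumor, inputs$normal)
  filt <- filter_missing_markers(combined, config$max_missing_frac,
                                 report = TRUE)
  norm <- mad_normalize(filt$matrix)
  tumor_norm <- abundance_matrix(
    norm$values[, samples(inputs$tumor), drop = FALSE], "mad_normalized")

  dep <- run_diffexp(norm, inputs$meta, covariates = config$covariates,
                     min_pairs = config$min_pairs, fdr_max = config$fdr_max,
                     fc_min = config$fc_min)

  op <- oppti_params(k = config$k, min_overlap = config$min_overlap,
                     threshold_T = config$threshold_T,
                     n_perm = config$n_perm,
                     seed = child_seed(config$seed, "oppti_protein"))
  oppti_pro <- run_oppti(tumor_norm, op)

  oppti_rna <- NULL
  if (!is.null(inputs$rna)) {
    rna_norm <- normalize_rna(inputs$rna, config$rna_zero_frac)
    op_rna <- op
    op_rna$seed <- child_seed(config$seed, "oppti_rna")
    oppti_rna <- run_oppti(rna_norm, op_rna)
  }

  mut_filtered <- NULL; dna_fracs <- NULL
  if (!is.null(inputs$mutations)) {
    mut_filtered <- filter_driver_mutations(inputs$mutations, inputs$catalog,
                                            config$min_recurrence)
    cohort_samples <- samples(inputs$tumor)
    genes <- markers(filt$matrix)
    dna_fracs <- vapply(genes, function(g) {
      dna_alteration_fraction(mut_filtered, g, cohort_samples)
    }, numeric(1L))
  }

  summary_tab <- build_alteration_summary(
    dna_fracs = dna_fracs,
    rna_pro = if (!is.null(oppti_rna)) oppti_rna else NULL,
    pro = oppti_pro, pro_min = config$pro_min, rna_fold = config$rna_fold)

  candidates <- NULL
  if (!is.null(inputs$druggable)) {
    candidates <- select_candidates(dep, oppti_pro, inputs$druggable,
                                    fc_min = config$fc_min,
                                    fdr_max = config$fdr_max)
  }

  dependency <- NULL
  if (!is.null(inputs$screen)) {
    dependency <- run_dependency(inputs$screen, config$min_lines)
  }

  bundle <- structure(list(
    filter_report = filt$report, dep = dep, oppti_protein = oppti_pro,
    oppti_rna = oppti_rna, mutations_filtered = mut_filtered,
    alteration_summary = summary_tab, candidates = candidates,
    dependency = dependency, config = config,
    skipped_stages = c(if (is.null(inputs$rna)) "oppti_rna",
                       if (is.null(inputs$mutations)) "mutfilter",
                       if (is.null(inputs$druggable)) "candidates",
                       if (is.null(inputs$screen)) "dependency")),
    class = "PipelineBundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# serialize every stage table plus a deterministic manifest
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  tag <- sprintf("seed=%d T=%g k=%d n_perm=%d fdr_max=%g fc_min=%g",
                 cfg$seed, cfg$threshold_T, cfg$k, cfg$n_perm,
                 cfg$fdr_max, cfg$fc_min)
  wt <- function(df, name) {
    if (!is.null(df)) {
      write_result_table(as.data.frame(df), file.path(out_dir, name), tag)
    }
  }
  wt(bundle$filter_report, "filter_report.tsv")
  wt(bundle$dep, "diffexp.tsv")
  wt(bundle$oppti_protein$table, "oppti_protein.tsv")
  wt(if (!is.null(bundle$oppti_rna)) bundle$oppti_rna$table, "oppti_rna.tsv")
  wt(bundle$mutations_filtered, "mutations_filtered.tsv")
  wt(bundle$alteration_summary, "alteration_summary.tsv")
  wt(bundle$candidates, "candidates.tsv")
  wt(bundle$dependency, "dependency.tsv")
  tsvs <- sort(list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE))
  digests <- tools::md5sum(tsvs)
  names(digests) <- basename(tsvs)
  manifest <- list(config = cfg[order(names(cfg))],
                   skipped_stages = bundle$skipped_stages %||% character(0),
                   tables = as.list(digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' Build a full simulated input bundle
#'
#' Expands one seed into independent per-generator child seeds and emits
#' every input the pipeline consumes, including a druggable-gene list
#' drawn from the planted differentially expressed and outlier markers
#' (plus background genes) so candidate selection is exercised.
#'
#' @param p a `SimParams`.
#' @param seed global integer seed.
#' @return list matching the `inputs` contract of [run_full_pipeline()],
#'   plus `truth` entries.
#' @export
simulate_bundle <- function(p = sim_params(), seed = 1L) {
  cohort <- generate_cohort(p, child_seed(seed, "cohort"))
  rna <- generate_rna(cohort$truth, p, child_seed(seed, "rna"))
  muts <- generate_mutations(p, markers(cohort$tumor),
                             samples(cohort$tumor),
                             child_seed(seed, "mutations"))
  scr <- generate_screen(p, child_seed(seed, "screen"))
  druggable <- with_seed(child_seed(seed, "druggable"), {
    planted <- c(names(cohort$truth$de_markers),
                 cohort$truth$outlier_markers$marker)
    unique(c(planted, sample(markers(cohort$tumor),
                             min(100L, p$n_markers))))
  })
  list(tumor = cohort$tumor, normal = cohort$normal, meta = cohort$meta,
       rna = rna$fpkm, mutations = muts$mutations, catalog = muts$catalog,
       druggable = druggable, screen = scr$screen,
       truth = list(cohort = cohort$truth, rna_protein_only = rna$protein_only,
                    mutations = muts$truth, screen = scr$truth))
}

#' Summarize a pipeline bundle
#'
#' Per-stage counts in the reporting style of a results section: markers
#' tested, differentially expressed markers at the FDR threshold,
#' overexpression-enriched markers, candidates by tier, dependency hits.
#'
#' @param bundle a `PipelineBundle`.
#' @return character vector of summary lines (also printed).
#' @export
report_summary <- function(bundle) {
  cfg <- bundle$config
  lines <- c(
    sprintf("markers tested: %d", nrow(bundle$dep)),
    sprintf("DEPs at FDR < %g: %d", cfg$fdr_max,
            sum(bundle$dep$significant, na.rm = TRUE)),
    sprintf("DEPs with log2fc >= %g: %d", cfg$fc_min,
            sum(bundle$dep$up2fold, na.rm = TRUE)),
    sprintf("overexpression-enriched markers at FDR < %g: %d", cfg$fdr_max,
            sum(bundle$oppti_protein$table$fdr < cfg$fdr_max, na.rm = TRUE)))
  if (!is.null(bundle$oppti_rna)) {
    lines <- c(lines, sprintf(
      "mRNA overexpression-enriched genes at FDR < %g: %d", cfg$fdr_max,
      sum(bundle$oppti_rna$table$fdr < cfg$fdr_max, na.rm = TRUE)))
  }
  lines <- c(lines, sprintf(
    "genes with high PRO (>= %g) and PRO >= %gx RNA: %d",
    cfg$pro_min, cfg$rna_fold,
    sum(bundle$alteration_summary$candidate, na.rm = TRUE)))
  if (!is.null(bundle$candidates)) {
    lines <- c(lines,
               sprintf("druggable both-positive tier: %d",
                       sum(bundle$candidates$both_positive)),
               sprintf("druggable strict candidates: %d",
                       sum(bundle$candidates$candidate)))
  } else {
    lines <- c(lines, "druggable candidates: stage skipped (no gene list)")
  }
  if (!is.null(bundle$dependency)) {
    lines <- c(lines, sprintf(
      "dependency pairs tested: %d, at FDR < %g: %d",
      nrow(bundle$dependency), cfg$fdr_max,
      sum(bundle$dependency$fdr < cfg$fdr_max, na.rm = TRUE)))
  }
  if (length(bundle$skipped_stages)) {
    lines <- c(lines, paste("skipped stages:",
                            paste(bundle$skipped_stages, collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
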