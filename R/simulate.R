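#' Simulation parameters for synthetic cohorts
#'
#' Defaults describe a cohort of the scale the pipeline is designed for:
#' 500 markers over 150 paired subjects, co-expressed through 8 latent
#' modules, residual noise SD 0.5 on the log-ratio scale, 5% values missing
#' completely at random, 50 markers with a +1 log2 tumor shift, and 20
#' outlier markers overexpressed in 15% of tumors with amplitude 3
#' noise-SD units.
#'
#' @param n_markers number of protein markers.
#' @param n_subjects number of paired subjects (one tumor + one normal).
#' @param n_factors number of latent co-expression modules; each marker
#'   belongs to exactly one module with a positive loading, which is what
#'   makes weighted-KNN background inference possible.
#' @param noise_sd residual (marker-level) noise SD.
#' @param missing_rate MCAR missingness fraction.
#' @param n_de number of differentially expressed markers.
#' @param de_shift planted tumor-minus-normal log2 shift.
#' @param n_outlier_markers markers carrying outlier overexpression events.
#' @param outlier_rate per-tumor-sample event probability (pi).
#' @param outlier_amplitude event amplitude delta, in noise-SD units.
#' @param subject_sd SD of the shared per-subject offset.
#' @param rna_protein_corr gene-level RNA/protein latent correlation (rho).
#' @param rna_protein_only_frac fraction of outlier markers whose events
#'   are protein-only (absent from the RNA layer), so genes with
#'   PRO > RNA exist by construction.
#' @param rna_zero_gene_frac fraction of genes given structural zeros in
#'   over 20% of samples (removed by the RNA zero filter).
#' @param mut_truncating_rate,mut_recurrent_rate,mut_nonrecurrent_rate
#'   per-gene upper bounds for carrier rates of each mutation class;
#'   actual per-gene rates are drawn uniformly in \[0, bound\].
#' @param screen_n_lines,screen_n_drugs drug-screen panel dimensions.
#' @param screen_slopes planted negative slopes (viability units per
#'   expression unit) for the first dependent (drug, target) pairs; all
#'   other pairs have slope 0.
#' @param screen_noise_sd viability noise SD.
#' @return list of class `SimParams`.
#' @export
sim_params <- function(n_markers = 500L, n_subjects = 150L, n_factors = 8L,
                       noise_sd = 0.5, missing_rate = 0.05,
                       n_de = round(0.10 * n_markers), de_shift = 1,
                       n_outlier_markers = round(0.04 * n_markers),
                       outlier_rate = 0.15,
                       outlier_amplitude = 3, subject_sd = 0.3,
                       rna_protein_corr = 0.7, rna_protein_only_frac = 0.5,
                       rna_zero_gene_frac = 0.04,
                       mut_truncating_rate = 0.05, mut_recurrent_rate = 0.03,
                       mut_nonrecurrent_rate = 0.03,
                       screen_n_lines = 34L, screen_n_drugs = 31L,
                       screen_slopes = c(-10, -8, -6),
                       screen_noise_sd = 5) {
  p <- list(n_markers = as.integer(n_markers),
            n_subjects = as.integer(n_subjects),
            n_factors = as.integer(n_factors), noise_sd = noise_sd,
            missing_rate = missing_rate, n_de = as.integer(n_de),
            de_shift = de_shift,
            n_outlier_markers = as.integer(n_outlier_markers),
            outlier_rate = outlier_rate,
            outlier_amplitude = outlier_amplitude, subject_sd = subject_sd,
            rna_protein_corr = rna_protein_corr,
            rna_protein_only_frac = rna_protein_only_frac,
            rna_zero_gene_frac = rna_zero_gene_frac,
            mut_truncating_rate = mut_truncating_rate,
            mut_recurrent_rate = mut_recurrent_rate,
            mut_nonrecurrent_rate = mut_nonrecurrent_rate,
            screen_n_lines = as.integer(screen_n_lines),
            screen_n_drugs = as.integer(screen_n_drugs),
            screen_slopes = screen_slopes,
            screen_noise_sd = screen_noise_sd)
  stopifnot(p$n_factors >= 1L, p$missing_rate >= 0, p$missing_rate < 1,
            p$outlier_rate > 0, p$outlier_rate < 1,
            p$outlier_amplitude > 0,
            p$n_de + p$n_outlier_markers <= p$n_markers)
  class(p) <- "SimParams"
  p
}

#' Generate a paired tumor/normal proteomic cohort with planted truth
#'
#' Marker abundances follow a module-structured latent-factor model:
#' marker i in module f has baseline `lambda_i F_f(subject) + alpha(subject)
#' + noise`, with positive loadings `lambda_i ~ U(0.8, 1.2)` so markers of
#' a module are genuinely co-expressed (same-module correlation about 0.8
#' at the default noise). Tumor samples add the planted differential
#' shifts, and outlier events add `delta * noise_sd` to the recorded
#' (marker, tumor sample) cells. Missingness is MCAR. The returned truth
#' suffices to compute the expected value of every downstream headline
#' statistic without re-running the generator.
#'
#' @param p a `SimParams` object.
#' @param seed integer seed; the generator is a pure function of
#'   `(p, seed)`.
#' @return list: `tumor`, `normal` (`AbundanceMatrix`, `scale_tag = "raw"`),
#'   `meta` (`SampleMeta`), `truth` (class `CohortTruth`).
#' @export
generate_cohort <- function(p = sim_params(), seed = 1L) {
  stopifnot(inherits(p, "SimParams"))
  with_seed(seed, {
    m <- p$n_markers; n <- p$n_subjects
    mk <- sprintf("M%04d", seq_len(m))
    sb <- sprintf("S%03d", seq_len(n))
    module <- sample(rep_len(seq_len(p$n_factors), m))
    lambda <- stats::runif(m, 0.8, 1.2)
    FF <- matrix(stats::rnorm(p$n_factors * n), p$n_factors, n)
    alpha <- stats::rnorm(n, 0, p$subject_sd)
    latent <- lambda * FF[module, , drop = FALSE] # m x n, module signal
    base <- sweep(latent, 2L, alpha, `+`)

    de_idx <- seq_len(p$n_de)
    out_idx <- p$n_de + seq_len(p$n_outlier_markers)
    shift <- numeric(m); shift[de_idx] <- p$de_shift

    tumor <- base + shift +
      matrix(stats::rnorm(m * n, 0, p$noise_sd), m, n)
    normal <- base + matrix(stats::rnorm(m * n, 0, p$noise_sd), m, n)

    events <- matrix(FALSE, m, n)
    events[out_idx, ] <- matrix(stats::runif(length(out_idx) * n),
                                length(out_idx), n) < p$outlier_rate
    tumor <- tumor + events * (p$outlier_amplitude * p$noise_sd)

    miss_t <- matrix(stats::runif(m * n) < p$missing_rate, m, n)
    miss_n <- matrix(stats::runif(m * n) < p$missing_rate, m, n)
    tumor[miss_t] <- NA; normal[miss_n] <- NA
    ts <- paste0(sb, "_T"); ns <- paste0(sb, "_N")
    dimnames(tumor) <- list(mk, ts); dimnames(normal) <- list(mk, ns)

    meta <- sample_meta(data.frame(
      sample_id = c(ts, ns), subject_id = c(sb, sb),
      tissue = rep(c("tumor", "normal"), each = n),
      age = rep(round(stats::runif(n, 40, 75)), 2L),
      gender = rep(ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "F", "M"), 2L),
      batch = NA, stringsAsFactors = FALSE))

    ev <- which(events, arr.ind = TRUE)
    truth <- structure(list(
      de_markers = stats::setNames(rep(p$de_shift, p$n_de), mk[de_idx]),
      outlier_markers = data.frame(marker = mk[out_idx],
                                   rate = rep(p$outlier_rate,
                                              length(out_idx)),
                                   amplitude = rep(p$outlier_amplitude,
                                                   length(out_idx)),
                                   row.names = NULL),
      outlier_cells = data.frame(marker = mk[ev[, 1L]],
                                 sample = ts[ev[, 2L]], row.names = NULL),
      module = stats::setNames(module, mk),
      lambda = stats::setNames(lambda, mk),
      latent = `dimnames<-`(latent + shift, list(mk, ts)),
      noise_sd = p$noise_sd, seed = as.integer(seed)),
      class = "CohortTruth")

    list(tumor = abundance_matrix(tumor, "raw"),
         normal = abundance_matrix(normal, "raw"),
         meta = meta, truth = truth)
  })
}

#' Combine tumor and normal matrices into one cohort matrix
#' @param tumor,normal `AbundanceMatrix` objects with disjoint sample IDs
#'   and identical marker sets.
#' @return a single `AbundanceMatrix`.
#' @export
bind_cohort <- function(tumor, normal) {
  stopifnot(identical(markers(tumor), markers(normal)),
            identical(tumor$scale_tag, normal$scale_tag))
  abundance_matrix(cbind(tumor$values, normal$values), tumor$scale_tag)
}

#' Generate an FPKM-like transcriptome coupled to the protein cohort
#'
#' Per gene, the RNA latent signal is a `rho`-correlated transform of the
#' protein latent signal (same tumor samples), exponentiated to a
#' nonnegative FPKM scale. Protein outlier events propagate to the RNA of
#' the same cell except for a configurable protein-only subset of outlier
#' markers, so genes with protein overexpression exceeding their mRNA
#' overexpression exist by construction. A small set of genes receives
#' structural zeros in more than 20% of samples to exercise the RNA zero
#' filter.
#'
#' @param truth a `CohortTruth` from [generate_cohort()].
#' @param p the same `SimParams`.
#' @param seed integer seed (independent stream from the cohort's).
#' @return list: `fpkm` (`AbundanceMatrix`, nonnegative), `protein_only`
#'   (character vector of outlier markers absent from the RNA layer).
#' @export
generate_rna <- function(truth, p = sim_params(), seed = 2L) {
  stopifnot(inherits(truth, "CohortTruth"))
  with_seed(seed, {
    sig <- truth$latent
    m <- nrow(sig); n <- ncol(sig)
    rho <- p$rna_protein_corr
    lat <- rho * sig + sqrt(max(0, 1 - rho^2)) *
      matrix(stats::rnorm(m * n), m, n)

    out_mk <- truth$outlier_markers$marker
    n_po <- round(p$rna_protein_only_frac * length(out_mk))
    protein_only <- if (n_po > 0L) sample(out_mk, n_po) else character(0)
    shared <- truth$outlier_cells[!(truth$outlier_cells$marker %in% protein_only), ]
    if (nrow(shared)) {
      ij <- cbind(match(shared$marker, rownames(sig)),
                  match(shared$sample, colnames(sig)))
      lat[ij] <- lat[ij] + p$outlier_amplitude
    }

    fpkm <- 2^(lat + 3) # shift keeps typical FPKM around 8
    n_zero_genes <- round(p$rna_zero_gene_frac * m)
    if (n_zero_genes > 0L) {
      zg <- sample(seq_len(m), n_zero_genes)
      for (g in zg) {
        zs <- sample(seq_len(n), ceiling(0.3 * n))
        fpkm[g, zs] <- 0
      }
    }
    list(fpkm = abundance_matrix(fpkm, "raw"), protein_only = protein_only)
  })
}

#' Generate a somatic mutation table and a matching recurrence catalog
#'
#' Each gene draws carrier rates uniformly below the configured class
#' bounds for truncating, recurrent-missense, and non-recurrent-missense
#' mutations. Recurrent missense changes appear in the catalog with count
#' at least 3; non-recurrent ones with count at most 2, so the driver
#' filter retains exactly the truncating and recurrent-missense rows. The
#' truth records each gene's retained carrier fraction.
#'
#' @param p a `SimParams`.
#' @param genes character vector of gene symbols.
#' @param samples character vector of cohort sample IDs.
#' @param seed integer seed.
#' @return list: `mutations` (`MutationTable`), `catalog`
#'   (`RecurrenceCatalog`), `truth` (data.frame gene, retained_fraction).
#' @export
generate_mutations <- function(p, genes, samples, seed = 3L) {
  with_seed(seed, {
    rows <- list(); ridx <- 1L
    cat_rows <- list(); cidx <- 1L
    retained <- stats::setNames(numeric(length(genes)), genes)
    n <- length(samples)
    for (g in genes) {
      r_tr <- stats::runif(1L, 0, p$mut_truncating_rate)
      r_re <- stats::runif(1L, 0, p$mut_recurrent_rate)
      r_no <- stats::runif(1L, 0, p$mut_nonrecurrent_rate)
      tr <- samples[stats::runif(n) < r_tr]
      re <- samples[stats::runif(n) < r_re]
      no <- samples[stats::runif(n) < r_no]
      if (length(tr)) {
        rows[[ridx]] <- data.frame(
          gene = g, sample_id = tr,
          variant_class = sample(TRUNCATING_CLASSES, length(tr), replace = TRUE),
          protein_change = sprintf("p.%s%dfs", g, sample(900, length(tr))),
          stringsAsFactors = FALSE)
        ridx <- ridx + 1L
      }
      if (length(re)) {
        pc <- sprintf("p.R%dH", 100 + (cidx %% 700))
        rows[[ridx]] <- data.frame(gene = g, sample_id = re,
                                   variant_class = "missense",
                                   protein_change = pc,
                                   stringsAsFactors = FALSE)
        ridx <- ridx + 1L
        cat_rows[[cidx]] <- data.frame(gene = g, protein_change = pc,
                                       count = sample(3:12, 1L),
                                       stringsAsFactors = FALSE)
        cidx <- cidx + 1L
      }
      if (length(no)) {
        pc <- sprintf("p.A%dV", sample(200:899, length(no)))
        rows[[ridx]] <- data.frame(gene = g, sample_id = no,
                                   variant_class = "missense",
                                   protein_change = pc,
                                   stringsAsFactors = FALSE)
        ridx <- ridx + 1L
        cat_rows[[cidx]] <- data.frame(gene = g, protein_change = pc,
                                       count = sample(1:2, length(no),
                                                      replace = TRUE),
                                       stringsAsFactors = FALSE)
        cidx <- cidx + 1L
      }
      retained[g] <- length(unique(c(tr, re))) / n
    }
    muts <- if (length(rows)) mutation_table(do.call(rbind, rows)) else
      mutation_table(data.frame(gene = character(), sample_id = character(),
                                variant_class = character(),
                                protein_change = character()))
    catalog <- if (length(cat_rows)) do.call(rbind, cat_rows) else
      data.frame(gene = character(), protein_change = character(),
                 count = integer())
    class(catalog) <- c("RecurrenceCatalog", "data.frame")
    list(mutations = muts, catalog = catalog,
         truth = data.frame(gene = genes, retained_fraction = unname(retained),
                            row.names = NULL))
  })
}

#' Generate a drug-screen panel with planted dependencies
#'
#' Baseline target expressions are standard Gaussian per target; viability
#' is `100 + slope * expression + noise`. The first
#' `length(screen_slopes)` (drug, target) pairs carry the planted negative
#' slopes; all remaining pairs have slope 0.
#'
#' @param p a `SimParams`.
#' @param seed integer seed.
#' @return list: `screen` (`DrugScreen`), `truth` (data.frame drug,
#'   target, slope).
#' @export
generate_screen <- function(p = sim_params(), seed = 4L) {
  with_seed(seed, {
    nl <- p$screen_n_lines; nd <- p$screen_n_drugs
    lines <- sprintf("CL%02d", seq_len(nl))
    drugs <- sprintf("DRUG%02d", seq_len(nd))
    targets <- sprintf("TGT%02d", seq_len(nd))
    slopes <- rep(0, nd)
    k <- min(length(p$screen_slopes), nd)
    slopes[seq_len(k)] <- p$screen_slopes[seq_len(k)]
    expr <- matrix(stats::rnorm(nd * nl), nd, nl,
                   dimnames = list(targets, lines))
    noise <- matrix(stats::rnorm(nd * nl, 0, p$screen_noise_sd), nd, nl)
    viab <- 100 + slopes * expr + noise
    dimnames(viab) <- list(drugs, lines)
    list(screen = drug_screen(viab, expr,
                              data.frame(drug = drugs, target = targets,
                                         stringsAsFactors = FALSE)),
         truth = data.frame(drug = drugs, target = targets, slope = slopes,
                            row.names = NULL))
  })
}
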