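#' Abundance matrix container
#'
#' A markers-by-samples real-valued matrix of (log-ratio scale) abundances
#' with missing values allowed. The `scale_tag` records the normalization
#' state and is checked by downstream stages: `"raw"` on ingest,
#' `"mad_normalized"` after per-sample MAD scaling, `"marker_zscore"` after
#' per-marker robust standardization.
#'
#' @param values numeric matrix with unique rownames (marker IDs) and unique
#'   colnames (sample IDs).
#' @param scale_tag one of `"raw"`, `"mad_normalized"`, `"marker_zscore"`.
#' @return An object of class `AbundanceMatrix`.
#' @export
abundance_matrix <- function(values, scale_tag = c("raw", "mad_normalized", "marker_zscore")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry marker rownames and sample colnames")
  }
  dup_m <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_m)) {
    stop("duplicate marker IDs: ", paste(dup_m, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  }
  structure(list(values = values, scale_tag = scale_tag), class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d markers x %d samples [%s], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale_tag,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' Marker and sample identifiers of an AbundanceMatrix
#' @param m an `AbundanceMatrix`.
#' @return character vector of IDs.
#' @export
markers <- function(m) rownames(m$values)

#' @rdname markers
#' @export
samples <- function(m) colnames(m$values)

#' Read a tab-separated abundance matrix
#'
#' Expects a TSV with sample IDs in the first row and marker IDs in the
#' first column (`orientation = "markers_rows"`, the proteomics convention);
#' `"samples_rows"` accepts the transpose. Empty cells, `NA` and `NaN` are
#' read as missing. Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @param orientation `"markers_rows"` (default) or `"samples_rows"`.
#' @return An `AbundanceMatrix` with `scale_tag = "raw"`.
#' @export
read_abundance_matrix <- function(path, orientation = c("markers_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          na.strings = c("", "NA", "NaN"), check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an ID column plus at least one data column")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate IDs in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
                 vals[bad[1L, 1L], bad[1L, 2L]]))
  }
  if (orientation == "samples_rows") num <- t(num)
  abundance_matrix(num, "raw")
}

#' Write an AbundanceMatrix as TSV
#'
#' Markers as rows, samples as columns, `NA` for missing. An optional
#' leading `#` comment line records provenance (parameters, seed).
#'
#' @param m an `AbundanceMatrix`.
#' @param path output path.
#' @param comment optional character scalar written as a `#` header line.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(m, path, comment = NULL) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(marker = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample metadata table
#'
#' Validates per-sample metadata: each subject may contribute at most one
#' tumor and one normal sample, and sample IDs are unique.
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `tissue`
#'   (`"tumor"`/`"normal"`), and optionally `age`, `gender`, `batch`.
#' @return A validated data.frame of class `SampleMeta`.
#' @export
sample_meta <- function(df) {
  need <- c("sample_id", "subject_id", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (!all(df$tissue %in% c("tumor", "normal"))) {
    stop("tissue must be 'tumor' or 'normal'")
  }
  tab <- table(df$subject_id, df$tissue)
  if (any(tab > 1L)) {
    off <- rownames(tab)[apply(tab > 1L, 1L, any)]
    stop("subject(s) with more than one sample of the same tissue: ",
         paste(off, collapse = ", "))
  }
  for (col in c("age", "gender", "batch")) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[, c(need, "age", "gender", "batch")]
  class(df) <- c("SampleMeta", "data.frame")
  df
}

#' Read sample metadata from TSV
#' @param path TSV with a header matching [sample_meta()] columns.
#' @return A `SampleMeta` data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  sample_meta(df)
}

# closed vocabulary for somatic variant classes; truncating classes drive
# the driver-mutation filter
VARIANT_CLASSES <- c("missense", "frameshift_indel", "nonframeshift_indel",
                     "stopgain", "stoploss", "other")
TRUNCATING_CLASSES <- c("frameshift_indel", "nonframeshift_indel",
                        "stopgain", "stoploss")

#' Construct a somatic mutation table
#'
#' @param df data.frame with columns `gene`, `sample_id`, `variant_class`,
#'   `protein_change`. `variant_class` must come from the closed enum
#'   `missense`, `frameshift_indel`, `nonframeshift_indel`, `stopgain`,
#'   `stoploss`, `other`.
#' @return data.frame of class `MutationTable`.
#' @export
mutation_table <- function(df) {
  need <- c("gene", "sample_id", "variant_class", "protein_change")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$variant_class), VARIANT_CLASSES)
  if (length(bad)) {
    stop("unknown variant_class value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(VARIANT_CLASSES, collapse = ", "))
  }
  df <- df[, need]
  class(df) <- c("MutationTable", "data.frame")
  df
}

#' Read a MAF-like mutation table
#'
#' Tab-separated with required columns `gene`, `sample_id` (or `sample`),
#' `variant_class`, `protein_change`; extra columns are ignored.
#'
#' @param path TSV path.
#' @return A `MutationTable`.
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (is.null(df$sample_id) && !is.null(df$sample)) df$sample_id <- df$sample
  if (nrow(df) == 0L) {
    df <- data.frame(gene = character(), sample_id = character(),
                     variant_class = character(), protein_change = character(),
                     stringsAsFactors = FALSE)
  }
  mutation_table(df)
}

#' Read a recurrence catalog
#'
#' Reference counts of (gene, protein_change) occurrences in an external
#' mutation call set, used to keep recurrent missense mutations.
#'
#' @param path TSV with columns `gene`, `protein_change`, `count`.
#' @return data.frame of class `RecurrenceCatalog`.
#' @export
read_recurrence_catalog <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene", "protein_change", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog missing columns: ", paste(miss, collapse = ", "))
  if (any(df$count < 1L)) stop("catalog counts must be >= 1")
  df <- df[, need]
  class(df) <- c("RecurrenceCatalog", "data.frame")
  df
}

#' Read a gene list (one symbol per line)
#' @param path text file; blank lines and `#` comments skipped.
#' @return character vector of unique symbols, input order preserved.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Annotate markers against named gene lists
#'
#' Membership flags per marker for each supplied list (druggable genes,
#' kinases, oncogenic pathways, ...). Identity is the plain case-sensitive
#' symbol; non-members get `FALSE` everywhere.
#'
#' @param marker_ids character vector of marker symbols.
#' @param gene_lists named list of character vectors.
#' @return data.frame with `marker` plus one logical column per list.
#' @export
annotate_markers <- function(marker_ids, gene_lists) {
  stopifnot(is.list(gene_lists), !is.null(names(gene_lists)),
            all(nzchar(names(gene_lists))))
  out <- data.frame(marker = marker_ids, stringsAsFactors = FALSE)
  for (nm in names(gene_lists)) out[[nm]] <- marker_ids %in% gene_lists[[nm]]
  out
}

#' Write a result table as TSV with a provenance comment line
#' @param df data.frame to write.
#' @param path output path.
#' @param comment character scalar recorded as a `#` line (parameters, seed).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
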