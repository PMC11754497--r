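# Reading, writing and preprocessing of expression, phenotype, drug-response
# and gene-set tables. Expression matrices follow the GEO series-matrix
# convention: genes in rows, samples in columns, tab-delimited, header row of
# sample ids, first column of gene ids (first header cell ignored).

#' Read a gene-by-sample expression matrix
#'
#' Parses a delimited text file into a validated numeric matrix with gene ids
#' as row names and sample ids as column names. The file must have a header
#' row of sample identifiers (the first header cell is ignored) and a first
#' column of gene identifiers.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param sep Field separator; `"\t"` by default, use `","` for CSV.
#' @param collapse_map Optional probe-to-gene map (see [collapse_probes()]).
#'   When supplied, duplicate row ids are interpreted as probes and collapsed
#'   to one row per gene by largest interquartile range.
#' @param drop_na_genes If `TRUE`, rows containing missing values are dropped
#'   with a message; if `FALSE` (default) missing values are an error.
#' @param name Optional cohort label stored as the `"name"` attribute.
#'
#' @return A numeric matrix (genes x samples) with unique dimnames.
#' @seealso [write_expression()], [collapse_probes()]
#' @export
read_expression <- function(path, sep = "\t", collapse_map = NULL,
                            drop_na_genes = FALSE, name = NULL) {
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    abort(sprintf("'%s': expected a gene-id column plus at least one sample column", path))
  }
  gene_ids <- tab[[1]]
  sample_ids <- colnames(tab)[-1]
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    abort(sprintf("duplicate sample id(s) in header: %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- tab[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "" & toupper(col) != "NA")
    if (length(bad)) {
      abort(sprintf("non-numeric cell at row '%s', column '%s': \"%s\"",
                    gene_ids[bad[1]], sample_ids[j], col[bad[1]]))
    }
    vals[, j] <- num
  }
  rownames(vals) <- gene_ids

  if (anyNA(vals)) {
    if (drop_na_genes) {
      keep <- complete.cases(vals)
      inform(sprintf("dropping %d row(s) with missing values", sum(!keep)))
      vals <- vals[keep, , drop = FALSE]
    } else {
      bad <- rownames(vals)[!complete.cases(vals)]
      abort(sprintf("missing values in row(s): %s (use drop_na_genes = TRUE to drop them)",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }

  if (!is.null(collapse_map)) {
    vals <- collapse_probes(vals, collapse_map)
  } else if (anyDuplicated(rownames(vals))) {
    dup <- unique(rownames(vals)[duplicated(rownames(vals))])
    abort(sprintf("duplicate gene id(s): %s (supply collapse_map to collapse probes)",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(name)) attr(vals, "name") <- name
  vals
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: writes a genes x samples matrix as a
#' delimited text file with a `gene_id` first column. Values are written with
#' enough digits to round-trip exactly.
#'
#' @param x Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_expression <- function(x, path, sep = "\t") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  readr::write_delim(df, path, delim = sep)
  invisible(path)
}

#' Collapse probe rows to one row per gene by largest IQR
#'
#' Each gene is represented by the row of the probe with the largest
#' interquartile range across samples (type-7 quantiles); ties are broken by
#' the lexicographically smallest probe id, so the result is deterministic.
#' Probes without a mapping are dropped.
#'
#' @param probe_matrix Numeric matrix, probes x samples, probe ids as row names.
#' @param probe_to_gene_map Either a data frame with columns `probe_id` and
#'   `gene_id`, or a named character vector (names = probes, values = genes).
#'
#' @return Numeric matrix with one row per mapped gene; every row is an exact
#'   copy of some input probe row. Genes appear in order of their first mapped
#'   probe in the input.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene_map) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  map <- probe_to_gene_map
  if (is.data.frame(map)) {
    stopifnot(all(c("probe_id", "gene_id") %in% colnames(map)))
    map <- setNames(as.character(map$gene_id), as.character(map$probe_id))
  }
  if (length(map) == 0) abort("empty probe-to-gene map")
  if (anyDuplicated(names(map))) {
    abort("probe-to-gene map assigns some probe to more than one gene")
  }
  probes <- rownames(probe_matrix)
  mapped <- probes[probes %in% names(map)]
  if (length(mapped) == 0) abort("no probe in the matrix is covered by the map")
  genes_in_order <- unique(unname(map[mapped]))
  iqr <- apply(probe_matrix[mapped, , drop = FALSE], 1L, IQR, type = 7)
  pick <- vapply(genes_in_order, function(g) {
    cand <- mapped[map[mapped] == g]
    best <- cand[iqr[cand] == max(iqr[cand])]
    sort(best)[1]
  }, character(1))
  out <- probe_matrix[pick, , drop = FALSE]
  rownames(out) <- genes_in_order
  out
}

#' Log2-transform an expression matrix
#'
#' @param x Numeric matrix.
#' @param offset Pseudocount added before the log; default 1.
#' @return `log2(x + offset)`, same shape and dimnames.
#' @export
log2_transform <- function(x, offset = 1) {
  stopifnot(is.matrix(x) || is.numeric(x))
  bad <- which(x + offset <= 0, arr.ind = is.matrix(x))
  if (length(bad)) {
    if (is.matrix(x)) {
      lab <- apply(head(bad, 5), 1L, function(ij) {
        sprintf("[%s, %s]",
                rownames(x)[ij[1]] %||% ij[1], colnames(x)[ij[2]] %||% ij[2])
      })
    } else {
      lab <- head(bad, 5)
    }
    abort(sprintf("log2 undefined for %d cell(s) with value + offset <= 0: %s",
                  NROW(bad), paste(lab, collapse = ", ")))
  }
  log2(x + offset)
}

row_variances <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Common most-variable genes across several cohorts
#'
#' Ranks genes by variance within each dataset, keeps the top
#' `ceiling(top_fraction * G_d)` genes of each, and returns the intersection,
#' ordered as in the first dataset.
#'
#' @param datasets List of >= 2 expression matrices (genes x samples) sharing
#'   at least one gene id.
#' @param top_fraction Fraction of each dataset's genes to keep, in (0, 1].
#' @return Character vector of gene ids.
#' @export
variance_filter_common <- function(datasets, top_fraction = 0.5) {
  stopifnot(is.list(datasets), length(datasets) >= 2,
            top_fraction > 0, top_fraction <= 1)
  tops <- lapply(datasets, function(d) {
    stopifnot(is.matrix(d), !is.null(rownames(d)))
    v <- row_variances(d)
    k <- ceiling(top_fraction * nrow(d))
    rownames(d)[order(-v, rownames(d))][seq_len(k)]
  })
  common <- Reduce(intersect, tops)
  if (length(common) == 0) {
    abort("no gene survives the variance filter in every dataset; try a larger top_fraction")
  }
  first <- rownames(datasets[[1]])
  first[first %in% common]
}

#' Read a sample phenotype table
#'
#' Expects a delimited file with named columns `sample_id`, `os_time`,
#' `os_event` and optionally `rfs_time`, `rfs_event`, `age`, `sex`.
#'
#' @param path Path to a TSV file.
#' @param sep Field separator.
#' @return A tibble, validated (unique sample ids, positive times, 0/1 events).
#' @export
read_phenotype <- function(path, sep = "\t") {
  ph <- tibble::as_tibble(utils::read.table(path, sep = sep, header = TRUE,
                                            check.names = FALSE,
                                            stringsAsFactors = FALSE))
  validate_phenotype(ph)
}

validate_phenotype <- function(ph) {
  need <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(need, colnames(ph))
  if (length(missing_cols)) {
    abort(sprintf("phenotype table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(ph$sample_id)) abort("duplicate sample ids in phenotype table")
  for (tm in intersect(c("os_time", "rfs_time"), colnames(ph))) {
    if (any(ph[[tm]] <= 0, na.rm = TRUE)) abort(sprintf("%s must be positive", tm))
  }
  for (ev in intersect(c("os_event", "rfs_event", "sex"), colnames(ph))) {
    if (!all(ph[[ev]] %in% c(0, 1, NA))) abort(sprintf("%s must be 0/1", ev))
  }
  ph
}

#' Read a drug-response table
#'
#' @param path Path to a TSV with columns `sample_id` and `ic50`.
#' @param sep Field separator.
#' @return A tibble with unique sample ids and finite IC50 values.
#' @export
read_drug_response <- function(path, sep = "\t") {
  dr <- tibble::as_tibble(utils::read.table(path, sep = sep, header = TRUE,
                                            check.names = FALSE,
                                            stringsAsFactors = FALSE))
  if (!all(c("sample_id", "ic50") %in% colnames(dr))) {
    abort("drug-response table needs columns sample_id and ic50")
  }
  if (anyDuplicated(dr$sample_id)) abort("duplicate sample ids in drug-response table")
  if (!all(is.finite(dr$ic50))) abort("non-finite IC50 values")
  dr
}

#' Read gene sets from a GMT file
#'
#' Standard GMT format: one set per line, tab-separated fields
#' `name`, `description`, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors; descriptions kept as the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) abort(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}
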