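#' Expression tables
#'
#' An `expression_table` holds a trials-by-genes matrix of Z-scores together
#' with the drug identity of every trial (sample). It is the in-memory
#' carrier for Level-4-style L1000 perturbation data.
#'
#' @param values numeric matrix, samples (trials) in rows, landmark genes in
#'   columns; must carry row and column names.
#' @param drugs named character vector mapping every sample id to its drug id.
#' @return An object of class `"expression_table"`: a list with elements
#'   `values` (the matrix), `drugs` (sample -> drug map), `sample_ids`,
#'   `gene_ids`.
#' @export
expression_table <- function(values, drugs) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and gene column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids in `values`")
  }
  drugs <- drugs[rownames(values)]
  if (anyNA(names(drugs)) || anyNA(drugs)) {
    stop("`drugs` must cover every sample id")
  }
  structure(
    list(
      values = values,
      drugs = drugs,
      sample_ids = rownames(values),
      gene_ids = colnames(values)
    ),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(
    sprintf(
      "expression_table: %d trials x %d genes, %d drugs\n",
      nrow(x$values), ncol(x$values), length(unique(x$drugs))
    )
  )
  invisible(x)
}

#' @export
dim.expression_table <- function(x) dim(x$values)

#' Read a GCT 1.3 (or two-line-header TSV) expression file
#'
#' Parses the GCT 1.3 dialect used for L1000 data: a `#1.3` version line, a
#' dimension line `nrows ncols nrhd ncid`, genes in rows and samples in
#' columns, with one column-metadata row (`pert_iname`) carrying the drug
#' identity of each sample. A plain TSV with the same body but no version or
#' dimension lines is accepted as a fallback.
#'
#' @param path path to a `.gct` or `.tsv` file.
#' @return An [expression_table()] (samples x genes; the on-disk gene-major
#'   orientation is transposed on read).
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("malformed GCT: empty file")
  if (startsWith(lines[[1L]], "#1.3")) {
    if (length(lines) < 4L) stop("malformed GCT: truncated header")
    dims <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2])) {
      stop("malformed GCT: bad dimension line")
    }
    n_genes <- dims[[1L]]
    n_samples <- dims[[2L]]
    nrhd <- if (length(dims) >= 3L && !is.na(dims[[3L]])) dims[[3L]] else 0L
    ncid <- if (length(dims) >= 4L && !is.na(dims[[4L]])) dims[[4L]] else 1L
    body <- lines[-(1:2)]
  } else {
    n_genes <- NA_integer_
    n_samples <- NA_integer_
    nrhd <- 0L
    ncid <- 1L
    body <- lines
  }
  header <- strsplit(body[[1L]], "\t")[[1L]]
  sample_ids <- header[-seq_len(1L + nrhd)]
  if (length(body) < 1L + ncid + 1L) stop("malformed GCT: no data rows")
  meta <- lapply(body[1L + seq_len(ncid)], function(l) strsplit(l, "\t")[[1L]])
  names(meta) <- vapply(meta, `[[`, "", 1L)
  if (!"pert_iname" %in% names(meta)) {
    stop("malformed GCT: missing pert_iname metadata row")
  }
  drug_row <- meta[["pert_iname"]][-seq_len(1L + nrhd)]
  if (length(drug_row) != length(sample_ids)) {
    stop("malformed GCT: pert_iname row does not match sample count")
  }
  data_lines <- body[-seq_len(1L + ncid)]
  parts <- strsplit(data_lines, "\t")
  gene_ids <- vapply(parts, `[[`, "", 1L)
  vals <- lapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-seq_len(1L + nrhd)]))
    if (length(v) != length(sample_ids)) {
      stop("malformed GCT: data row width does not match sample count")
    }
    v
  })
  if (!is.na(n_genes) && length(gene_ids) != n_genes) {
    stop("malformed GCT: header declares ", n_genes, " genes, body has ",
         length(gene_ids))
  }
  if (!is.na(n_samples) && length(sample_ids) != n_samples) {
    stop("malformed GCT: header declares ", n_samples, " samples, body has ",
         length(sample_ids))
  }
  m <- do.call(rbind, vals)            # genes x samples
  rownames(m) <- gene_ids
  colnames(m) <- sample_ids
  drugs <- stats::setNames(drug_row, sample_ids)
  expression_table(t(m), drugs)
}

#' Write an expression table as GCT 1.3
#'
#' Inverse of [read_gct()]: genes in rows, samples in columns, one
#' `pert_iname` column-metadata row with the drug of each sample. Values are
#' printed with 17 significant digits so that a write/read cycle is
#' value-identical up to floating-point round-trip.
#'
#' @param x an [expression_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "expression_table"))
  m <- t(x$values)                     # genes x samples
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(paste(nrow(m), ncol(m), 0L, 1L, sep = "\t"), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(c("pert_iname", unname(x$drugs[colnames(m)])),
                   collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}
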