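#' Read a drug -> ATC label table
#'
#' Expects a two-column TSV (`drug_id`, labels), the second column holding
#' semicolon-separated first-level ATC letters. Multi-label drugs are kept
#' with all of their labels.
#'
#' @param path path to the TSV file. A header line `drug_id<TAB>atc` is
#'   accepted and skipped.
#' @return Named list mapping drug id to a character vector of ATC letters.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^drug_id\t", lines[[1L]])) {
    lines <- lines[-1L]
  }
  parts <- strsplit(lines, "\t")
  drugs <- vapply(parts, `[[`, "", 1L)
  labs <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[[2L]])) {
      stop("drug '", p[[1L]], "' has an empty label set")
    }
    strsplit(p[[2L]], ";", fixed = TRUE)[[1L]]
  })
  names(labs) <- drugs
  validate_labels(labs)
  labs
}

#' Write a drug -> ATC label table
#'
#' @param labels named list, drug id -> character vector of ATC letters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  lines <- c(
    "drug_id\tatc",
    vapply(names(labels), function(d) {
      paste0(d, "\t", paste(sort(labels[[d]]), collapse = ";"))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

validate_labels <- function(labels, alphabet = atc_letters()) {
  for (d in names(labels)) {
    l <- labels[[d]]
    if (length(l) == 0L) stop("drug '", d, "' has an empty label set")
    bad <- setdiff(l, alphabet)
    if (length(bad)) {
      stop("drug '", d, "' carries unknown ATC letter(s): ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(labels)
}

#' Binary label matrix from a label table
#'
#' Expands a drug (or sample) -> label-set map into the m x q binary
#' indicator matrix fed to the classifier; every row has at least one 1.
#'
#' @param labels named list, id -> character vector of class letters.
#' @param classes class alphabet fixing the column order; defaults to the 14
#'   first-level ATC letters.
#' @return Binary matrix with one row per entry of `labels` (in order) and
#'   one column per class.
#' @export
label_matrix <- function(labels, classes = atc_letters()) {
  validate_labels(labels, classes)
  lb <- matrix(0L, nrow = length(labels), ncol = length(classes),
               dimnames = list(names(labels), classes))
  for (i in seq_along(labels)) {
    lb[i, labels[[i]]] <- 1L
  }
  lb
}

#' Overlapping ATC communities of a drug cohort
#'
#' Inverts a label table into the per-class drug communities used for
#' node-to-community projection; drugs with multiple ATC codes belong to
#' multiple communities.
#'
#' @inheritParams label_matrix
#' @return Named list, class letter -> character vector of drug ids (possibly
#'   empty).
#' @export
community_partition <- function(labels, classes = atc_letters()) {
  validate_labels(labels, classes)
  stats::setNames(lapply(classes, function(cl) {
    names(labels)[vapply(labels, function(l) cl %in% l, NA)]
  }), classes)
}
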