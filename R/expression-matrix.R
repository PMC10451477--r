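#' Expression matrix container
#'
#' An `ExpressionMatrix` bundles a non-negative genes x subjects intensity
#' matrix with one binary class label per subject (levels `"Adeno"` and
#' `"Meso"`), gene and subject identifiers, and — for synthetic data — an
#' optional logical flag per gene marking the planted informative genes.
#'
#' @param values numeric matrix, genes in rows, subjects in columns; all
#'   entries must be finite and non-negative.
#' @param labels character or factor of length `ncol(values)` with values
#'   in `c("Adeno", "Meso")`.
#' @param gene_ids,subject_ids optional identifier vectors; defaults are
#'   `gene_1..gene_G` and `subj_1..subj_S`.
#' @param informative optional logical vector of length `nrow(values)`
#'   flagging ground-truth informative genes (synthetic data only).
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `labels`, `gene_ids`, `subject_ids`, `informative`.
#' @export
expression_matrix <- function(values, labels, gene_ids = NULL,
                              subject_ids = NULL, informative = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (any(values < 0)) stop("'values' must be non-negative")
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop(sprintf("number of labels (%d) must equal number of subjects (%d)",
                 length(labels), ncol(values)))
  }
  bad <- setdiff(unique(labels), c("Adeno", "Meso"))
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  labels <- factor(labels, levels = c("Adeno", "Meso"))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(subject_ids)) subject_ids <- paste0("subj_", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values)) stop("gene_ids length mismatch")
  if (length(subject_ids) != ncol(values)) stop("subject_ids length mismatch")
  if (!is.null(informative) && length(informative) != nrow(values)) {
    stop("informative flag length mismatch")
  }
  structure(list(values = values, labels = labels,
                 gene_ids = as.character(gene_ids),
                 subject_ids = as.character(subject_ids),
                 informative = informative),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d subjects (%d Adeno, %d Meso)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "Adeno"), sum(x$labels == "Meso")))
  if (!is.null(x$informative)) {
    cat(sprintf("  %d ground-truth informative genes flagged\n",
                sum(x$informative)))
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# numeric class codes used in the on-disk label row
.label_codes <- c(Adeno = 1, Meso = 2)

#' Write an expression matrix as delimited text with a trailing label row
#'
#' One row per gene; the final row carries the numeric class code of each
#' subject (Adeno = 1, Meso = 2). The format round-trips exactly with
#' [read_matrix()]: values are written at full precision (17 significant
#' digits) and the label row is integral.
#'
#' @param data an [expression_matrix()] object.
#' @param destination output file path.
#' @param delim field delimiter (default tab).
#' @return `destination`, invisibly.
#' @export
write_matrix <- function(data, destination, delim = "\t") {
  stopifnot(inherits(data, "ExpressionMatrix"))
  if (length(data$labels) != ncol(data$values)) {
    stop("subject count mismatch between values and labels; refusing to write")
  }
  lines <- apply(data$values, 1L, function(row) {
    paste(formatC(row, format = "g", digits = 17), collapse = delim)
  })
  label_line <- paste(.label_codes[as.character(data$labels)], collapse = delim)
  ok <- tryCatch({
    writeLines(c(lines, label_line), destination)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("failed to write matrix to '%s': %s",
                 destination, conditionMessage(ok)))
  }
  invisible(destination)
}

#' Read a delimited expression matrix whose final row holds class labels
#'
#' @param source input file path.
#' @param delim field delimiter (default tab).
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(source, delim = "\t") {
  if (!file.exists(source)) stop(sprintf("file '%s' does not exist", source))
  lines <- readLines(source)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop(sprintf("parse error in '%s': need at least one gene row plus a label row",
                 source))
  }
  fields <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("parse error in '%s': ragged row at line %d (%d fields, expected %d)",
                 source, bad, widths[bad], widths[1L]))
  }
  n <- length(lines)
  label_codes <- suppressWarnings(as.numeric(fields[[n]]))
  if (any(is.na(label_codes)) || !all(label_codes %in% .label_codes)) {
    offending <- setdiff(unique(fields[[n]]),
                         as.character(.label_codes))
    stop(sprintf("parse error in '%s': unknown class code(s) in label row (line %d): %s",
                 source, n, paste(offending, collapse = ", ")))
  }
  values <- matrix(NA_real_, nrow = n - 1L, ncol = widths[1L])
  for (i in seq_len(n - 1L)) {
    row <- suppressWarnings(as.numeric(fields[[i]]))
    if (any(is.na(row))) {
      stop(sprintf("parse error in '%s': non-numeric value at line %d", source, i))
    }
    if (any(row < 0)) {
      stop(sprintf("parse error in '%s': negative intensity at line %d", source, i))
    }
    values[i, ] <- row
  }
  labels <- names(.label_codes)[match(label_codes, .label_codes)]
  expression_matrix(values, labels)
}
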