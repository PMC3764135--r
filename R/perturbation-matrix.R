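#' Construct a perturbation matrix
#'
#' A perturbation matrix holds signed discrete differential-expression calls
#' for a panel of deletion-mutant strains: one row per gene, one column per
#' mutant, entries in \{-1, 0, +1\} meaning significant down-regulation, no
#' significant change, and significant up-regulation relative to wild type.
#' Mutant labels may name a single or a double deletion
#' (\code{"GENE1+GENE2"}) and may carry a dataset-of-origin tag
#' (\code{"GENE@dataset"}) so that a regulator profiled in two datasets keeps
#' two distinct columns.
#'
#' @param values integer matrix of calls in \{-1, 0, 1\}, genes x mutants.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param mutant_ids character vector of unique mutant labels (columns).
#' @return An integer matrix of class \code{"perturbation_matrix"} with
#'   \code{dimnames = list(gene_ids, mutant_ids)}.
#' @examples
#' m <- perturbation_matrix(matrix(c(1L, 0L, -1L, 0L, 1L, 0L), 3, 2),
#'                          c("g1", "g2", "g3"), c("mutA", "mutB"))
#' m["g1", "mutA"]
#' @export
perturbation_matrix <- function(values, gene_ids = rownames(values),
                                mutant_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(gene_ids) || is.null(mutant_ids))
    stop("gene_ids and mutant_ids are required")
  gene_ids <- as.character(gene_ids)
  mutant_ids <- as.character(mutant_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(mutant_ids))
    stop("dimensions of 'values' do not match the id vectors")
  dimnames(values) <- list(gene_ids, mutant_ids)
  class(values) <- c("perturbation_matrix", class(values))
  validate_perturbation_matrix(values)
}

#' Validate a perturbation matrix
#'
#' Checks the container invariants: every entry is exactly -1, 0 or +1, and
#' gene/mutant identifiers are unique. Called by all constructors and readers;
#' exported so externally assembled matrices can be checked too.
#'
#' @param m object to validate.
#' @return \code{m}, invisibly classed, if valid; otherwise an error naming
#'   the offending cell or identifier.
#' @export
validate_perturbation_matrix <- function(m) {
  if (!is.matrix(m)) stop("perturbation matrix must be a matrix")
  bad <- which(!(m %in% c(-1L, 0L, 1L)) | is.na(m))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("invalid call %s at gene '%s', mutant '%s': entries must be -1, 0 or 1",
                 deparse(m[bad[1L]]), rownames(m)[i[1L]], colnames(m)[i[2L]]))
  }
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicate gene id '%s'", rownames(m)[duplicated(rownames(m))][1L]))
  if (anyDuplicated(colnames(m)))
    stop(sprintf("duplicate mutant label '%s'", colnames(m)[duplicated(colnames(m))][1L]))
  m
}

#' Read a perturbation matrix from TSV
#'
#' The file layout is a header row of mutant labels, a leading column of gene
#' identifiers, and tab-separated integer cells in \{-1, 0, 1\}. Row and
#' column order are preserved.
#'
#' @param path path to a tab-separated file.
#' @return a \code{\link{perturbation_matrix}}.
#' @export
read_perturbation_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("matrix file needs a gene-id column and at least one mutant column")
  gene_ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.integer(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num) & !is.na(cells))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(cells))
    stop(sprintf("non-integer cell '%s' at gene '%s', mutant '%s'",
                 cells[bad[1L]], gene_ids[i[1L]], colnames(cells)[i[2L]]))
  }
  perturbation_matrix(num, gene_ids, colnames(cells))
}

#' Write a perturbation matrix to TSV
#'
#' Inverse of \code{\link{read_perturbation_matrix}}: header row of mutant
#' labels, leading \code{gene} column, tab-separated calls.
#'
#' @param m a \code{\link{perturbation_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_perturbation_matrix <- function(m, path) {
  validate_perturbation_matrix(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Threshold continuous log-ratios into discrete calls
#'
#' A convenience discretizer for continuous genes x mutants log-ratio tables:
#' entries at or above \code{up} become +1, entries at or below \code{down}
#' become -1, everything else (including missing values) becomes 0. It stands
#' in for a full differential-expression calling pipeline when only a
#' continuous matrix is at hand; matrices produced by proper per-dataset
#' statistics should be read directly with
#' \code{\link{read_perturbation_matrix}}.
#'
#' @param log_ratios numeric matrix (genes x mutants), e.g. log2 ratios
#'   mutant/WT, with dimnames.
#' @param up up-regulation threshold, > 0 (default 1 on the log2 scale).
#' @param down down-regulation threshold, < 0 (default -1).
#' @return a \code{\link{perturbation_matrix}} of the same shape.
#' @export
discretize_expression <- function(log_ratios, up = 1, down = -1) {
  if (!is.numeric(up) || !is.numeric(down) || !(down < 0) || !(up > 0))
    stop("thresholds must satisfy down < 0 < up")
  x <- as.matrix(log_ratios)
  if (!is.numeric(x)) stop("log-ratio matrix must be numeric")
  calls <- matrix(0L, nrow(x), ncol(x))
  calls[which(x >= up)] <- 1L
  calls[which(x <= down)] <- -1L  # which() drops NAs -> NA stays 0
  perturbation_matrix(calls, rownames(x), colnames(x))
}

#' Per-mutant signed target-gene lists
#'
#' The target list of a deletion mutant is the set of genes whose mRNA level
#' is significantly up- or down-regulated in that mutant versus wild type,
#' i.e. exactly the nonzero entries of its column.
#'
#' @param m a \code{\link{perturbation_matrix}}.
#' @return a named list (one element per mutant, in column order) of named
#'   integer vectors: names are gene ids, values the signs (+1 or -1). A
#'   mutant with no differentially expressed gene gets a zero-length vector.
#' @examples
#' m <- perturbation_matrix(matrix(c(1L, 0L, -1L), 3, 1),
#'                          c("g1", "g2", "g3"), "mutA")
#' extract_target_lists(m)$mutA
#' @export
extract_target_lists <- function(m) {
  validate_perturbation_matrix(m)
  genes <- rownames(m)
  out <- lapply(seq_len(ncol(m)), function(j) {
    nz <- which(m[, j] != 0L)
    stats::setNames(as.integer(m[nz, j]), genes[nz])
  })
  names(out) <- colnames(m)
  out
}

#' Export target lists as GMT lines
#'
#' One line per mutant: label, description, then member genes, tab-separated
#' (signs are dropped; GMT is an unsigned set format).
#'
#' @param targets result of \code{\link{extract_target_lists}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_target_gmt <- function(targets, path) {
  lines <- vapply(names(targets), function(id) {
    paste(c(id, sprintf("targets of %s", id), names(targets[[id]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# --- mutant label grammar -----------------------------------------------

#' Strip the dataset tag from mutant labels
#'
#' @param labels character vector of mutant labels, possibly of the form
#'   \code{"GENE@dataset"} or \code{"GENE1+GENE2@dataset"}.
#' @return labels with any \code{"@..."} suffix removed.
#' @export
strip_dataset_tag <- function(labels) sub("@.*$", "", labels)

#' Constituent gene names of mutant labels
#'
#' Splits double-deletion labels (\code{"GENE1+GENE2"}) after stripping any
#' dataset tag.
#'
#' @param labels character vector of mutant labels.
#' @return a list of character vectors, one per label.
#' @export
mutant_genes <- function(labels) strsplit(strip_dataset_tag(labels), "+", fixed = TRUE)
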