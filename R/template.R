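#' Build the regulator-regulator template matrix
#'
#' The template is an R x R binary matrix over mutant labels constraining
#' which directed edges the structure search may use: \code{allow[a, b] = 1}
#' licenses the edge a -> b. For each unordered pair \{A, B\} the rules are,
#' in order of precedence:
#' \enumerate{
#'   \item mutual membership -- B is a target of A's deletion and A a target
#'     of B's: both directions allowed (the dominant direction is unknown);
#'   \item one-way membership -- B is a target of A only: A -> B allowed,
#'     the reverse forbidden (and vice versa);
#'   \item target overlap -- neither is a target of the other but their
#'     target lists share at least one gene (sign-insensitive): both
#'     directions allowed (they may co-regulate common targets);
#'   \item otherwise the pair is forbidden.
#' }
#' Membership tests match the regulator's constituent gene name(s), with any
#' dataset tag stripped; a double-deletion mutant matches if either
#' constituent gene appears in the partner's target list.
#'
#' @param targets named list of signed target vectors, as returned by
#'   \code{\link{extract_target_lists}}.
#' @param node_ids mutant labels to include, in order (default: all of
#'   \code{targets}).
#' @return an integer 0/1 matrix of class \code{"template_matrix"} with zero
#'   diagonal and \code{dimnames = list(node_ids, node_ids)}.
#' @export
build_template <- function(targets, node_ids = names(targets)) {
  node_ids <- as.character(node_ids)
  missing <- setdiff(node_ids, names(targets))
  if (length(missing))
    stop(sprintf("no target list for node '%s'", missing[1L]))
  R <- length(node_ids)
  genes <- lapply(targets[node_ids], names)
  constituents <- mutant_genes(node_ids)
  allow <- matrix(0L, R, R, dimnames = list(node_ids, node_ids))
  if (R >= 2L) {
    for (i in seq_len(R - 1L)) {
      for (j in (i + 1L):R) {
        b_in_a <- any(constituents[[j]] %in% genes[[i]])
        a_in_b <- any(constituents[[i]] %in% genes[[j]])
        if (b_in_a && a_in_b) {
          allow[i, j] <- allow[j, i] <- 1L
        } else if (b_in_a) {
          allow[i, j] <- 1L
        } else if (a_in_b) {
          allow[j, i] <- 1L
        } else if (any(genes[[i]] %in% genes[[j]])) {
          allow[i, j] <- allow[j, i] <- 1L
        }
      }
    }
  }
  class(allow) <- c("template_matrix", class(allow))
  allow
}

#' Fully permissive template
#'
#' Every off-diagonal entry allowed; the template-free mode used to test
#' whether orientation accuracy depends on prior knowledge.
#'
#' @param node_ids mutant labels.
#' @return a \code{"template_matrix"} of ones off the diagonal.
#' @export
permissive_template <- function(node_ids) {
  R <- length(node_ids)
  allow <- matrix(1L, R, R, dimnames = list(node_ids, node_ids))
  diag(allow) <- 0L
  class(allow) <- c("template_matrix", class(allow))
  allow
}

validate_template <- function(t) {
  if (!is.matrix(t) || nrow(t) != ncol(t))
    stop("template must be a square matrix")
  if (!all(t %in% c(0L, 1L))) stop("template entries must be 0 or 1")
  if (any(diag(t) != 0L)) stop("template diagonal must be 0")
  if (is.null(rownames(t)) || !identical(rownames(t), colnames(t)))
    stop("template must carry identical row and column node labels")
  invisible(t)
}

#' Asymmetric (one-way) template constraints
#'
#' The ordered pairs a -> b with \code{allow[a, b] = 1} and
#' \code{allow[b, a] = 0}. These encode prior causal knowledge from the
#' deletion experiments (the partner gene responded to the deletion, not
#' vice versa) and are handed to \code{\link{to_pdag}} as background
#' orientations. Mutually allowed pairs are symmetric and contribute
#' nothing.
#'
#' @param t a \code{"template_matrix"}.
#' @return a two-column character matrix (\code{from}, \code{to}); zero rows
#'   when the template is fully symmetric.
#' @export
asymmetric_constraints <- function(t) {
  validate_template(t)
  one_way <- which(t == 1L & t(t) == 0L, arr.ind = TRUE)
  out <- cbind(from = rownames(t)[one_way[, 1L]],
               to = colnames(t)[one_way[, 2L]])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' Read / write a template matrix as TSV adjacency
#'
#' Same dialect as the perturbation matrix: header row and leading label
#' column, 0/1 cells.
#'
#' @param path file path.
#' @return \code{read_template}: a \code{"template_matrix"};
#'   \code{write_template}: \code{path}, invisibly.
#' @export
read_template <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  class(m) <- c("template_matrix", class(m))
  validate_template(m)
  m
}

#' @rdname read_template
#' @param t a \code{"template_matrix"}.
#' @export
write_template <- function(t, path) {
  validate_template(t)
  df <- data.frame(node = rownames(t), unclass(t), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
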