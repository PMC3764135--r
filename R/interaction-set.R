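#' Construct a reference interaction set
#'
#' Reference interactions between regulator genes, used for precision/recall
#' evaluation. Each record is a pair of gene names with a direction flag:
#' undirected (\code{"--"}) or directed from the first to the second gene
#' (\code{"->"}). Undirected records are stored with the lexicographically
#' smaller gene first, so (A,B,--) and (B,A,--) collapse to one record;
#' exact duplicates are dropped.
#'
#' @param node_a,node_b character vectors of gene names (dataset tags are
#'   stripped).
#' @param direction character vector, each \code{"--"} or \code{"->"}.
#' @return a \code{data.frame} of class \code{"interaction_set"} with columns
#'   \code{node_a}, \code{node_b}, \code{direction}.
#' @export
interaction_set <- function(node_a = character(), node_b = character(),
                            direction = rep("--", length(node_a))) {
  node_a <- strip_dataset_tag(as.character(node_a))
  node_b <- strip_dataset_tag(as.character(node_b))
  direction <- as.character(direction)
  if (length(node_a) != length(node_b) || length(node_a) != length(direction))
    stop("node_a, node_b and direction must have equal length")
  bad <- which(!direction %in% c("--", "->"))
  if (length(bad))
    stop(sprintf("unknown direction flag '%s' (expected '--' or '->')",
                 direction[bad[1L]]))
  undir <- direction == "--"
  swap <- undir & node_a > node_b
  tmp <- node_a[swap]; node_a[swap] <- node_b[swap]; node_b[swap] <- tmp
  df <- unique(data.frame(node_a = node_a, node_b = node_b,
                          direction = direction, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("interaction_set", "data.frame")
  df
}

#' Read a reference interaction set from TSV
#'
#' Three tab-separated columns per row: node_a, node_b, direction flag
#' (\code{"--"} undirected, \code{"->"} directed a to b). No header.
#'
#' @param path path to the file.
#' @return an \code{\link{interaction_set}}.
#' @export
read_interaction_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) != 3L)
    stop("interaction file must have exactly 3 tab-separated columns")
  interaction_set(df[[1L]], df[[2L]], df[[3L]])
}

#' Write a reference interaction set to TSV
#'
#' @param x an \code{\link{interaction_set}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_interaction_set <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Unordered pair keys used throughout evaluation.
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
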