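#' Directed network over regulators
#'
#' A light container for the acyclic directed graph returned by structure
#' search: node labels plus a two-column (from, to) edge matrix.
#'
#' @param nodes character vector of node labels.
#' @param edges two-column character matrix (or data.frame) of directed
#'   edges; zero rows for the empty graph.
#' @param check verify acyclicity and node membership (default TRUE).
#' @return an object of class \code{"dm_network"}.
#' @export
dm_network <- function(nodes, edges = NULL, check = TRUE) {
  nodes <- as.character(nodes)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), 0L, 2L)
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("from", "to")
  net <- structure(list(nodes = nodes, edges = edges), class = "dm_network")
  if (check) {
    if (!all(edges %in% nodes)) stop("edge endpoints must be network nodes")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
      stop("duplicate edges are not allowed")
    if (is.null(topological_order(net)))
      stop("edge set contains a directed cycle")
  }
  net
}

#' @export
print.dm_network <- function(x, ...) {
  cat(sprintf("Directed network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    shown <- utils::head(seq_len(nrow(x$edges)), 20L)
    cat(paste0("  ", x$edges[shown, 1L], " -> ", x$edges[shown, 2L],
               collapse = "\n"), "\n")
    if (nrow(x$edges) > 20L) cat(sprintf("  ... and %d more\n", nrow(x$edges) - 20L))
  }
  invisible(x)
}

# Kahn's algorithm; NULL if cyclic.
topological_order <- function(net) {
  nodes <- net$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(net$edges)) {
    tab <- table(net$edges[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- names(indeg)[indeg == 0L]
  edges <- net$edges
  while (length(avail)) {
    n <- avail[1L]; avail <- avail[-1L]
    out <- c(out, n)
    kids <- edges[edges[, 1L] == n, 2L]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

parent_sets <- function(net) {
  ps <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (n in net$nodes) ps[[n]] <- character(0)
  if (nrow(net$edges))
    for (k in seq_len(nrow(net$edges)))
      ps[[net$edges[k, 2L]]] <- c(ps[[net$edges[k, 2L]]], net$edges[k, 1L])
  ps
}

#' Read / write a directed edge list as TSV
#'
#' Two tab-separated columns (from, to), no header.
#'
#' @param path file path.
#' @param nodes node labels (superset of endpoints); defaults to the
#'   endpoints present in the file.
#' @return \code{read_network}: a \code{"dm_network"};
#'   \code{write_network}: \code{path}, invisibly.
#' @export
read_network <- function(path, nodes = NULL) {
  df <- tryCatch(utils::read.table(path, header = FALSE, sep = "\t",
                                   colClasses = "character", quote = "",
                                   comment.char = ""),
                 error = function(e) NULL)
  edges <- if (is.null(df)) matrix(character(), 0, 2) else as.matrix(df[, 1:2])
  if (is.null(nodes)) nodes <- unique(as.character(edges))
  dm_network(nodes, edges)
}

#' @rdname read_network
#' @param net a \code{"dm_network"}.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
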