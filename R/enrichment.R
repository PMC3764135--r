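#' Gene-set collection for enrichment testing
#'
#' A named list of gene sets together with the universe they are drawn
#' from. For deletion-mutant analyses the natural universe is every gene
#' with a significant expression change in any mutant
#' (\code{\link{expression_universe}}).
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe character vector of all eligible gene ids.
#' @return a list of class \code{"gene_set_collection"}.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(sets) || is.null(names(sets)))
    stop("sets must be a non-empty named list")
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  outside <- vapply(sets, function(s) any(!s %in% universe), logical(1))
  if (any(outside))
    stop(sprintf("gene set '%s' contains genes outside the universe",
                 names(sets)[outside][1L]))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Universe of differentially expressed genes
#'
#' All genes with a nonzero call in at least one mutant column: the default
#' universe G of the hypergeometric enrichment test.
#'
#' @param m a \code{\link{perturbation_matrix}}.
#' @return a character vector of gene ids.
#' @export
expression_universe <- function(m) {
  validate_perturbation_matrix(m)
  rownames(m)[rowSums(m != 0L) > 0L]
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors (descriptions are dropped).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1L]))
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' P(X >= m) where X counts category genes in a size-n draw without
#' replacement from a universe of G genes of which S belong to the
#' category:
#' \deqn{p = \sum_{k=m}^{\min(S,n)} \binom{S}{k}\binom{G-S}{n-k} \big/ \binom{G}{n}.}
#'
#' @param G universe size (genes with significant change in any mutant).
#' @param S category size.
#' @param n query size (genes with significant change in the current
#'   mutant).
#' @param m overlap between query and category.
#' @return the upper-tail p-value in (0, 1].
#' @examples
#' hypergeom_tail(10, 5, 4, 4)  # 5/210
#' @export
hypergeom_tail <- function(G, S, n, m) {
  if (any(c(G, S, n, m) < 0) || m > min(S, n) || S > G || n > G)
    stop("need 0 <= m <= min(S, n) and S, n <= G")
  if (m == 0) return(1)
  stats::phyper(m - 1, S, G - S, n, lower.tail = FALSE)
}

#' Enrichment of a query gene list against a collection
#'
#' One hypergeometric test per gene set; results are sorted by ascending
#' p-value with Benjamini-Hochberg adjusted p-values appended. Query genes
#' outside the universe are dropped with a warning.
#'
#' @param query character vector of gene ids (e.g. one mutant's target
#'   list).
#' @param collection a \code{\link{gene_set_collection}}.
#' @return a data.frame with columns \code{set}, \code{S}, \code{n},
#'   \code{m}, \code{p_value}, \code{p_adjust}.
#' @export
enrich_targets <- function(query, collection) {
  if (!inherits(collection, "gene_set_collection"))
    stop("collection must be a gene_set_collection")
  query <- unique(if (is.null(names(query))) as.character(query)
                  else names(query))
  drop <- !query %in% collection$universe
  if (any(drop)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", sum(drop)))
    query <- query[!drop]
  }
  G <- length(collection$universe)
  n <- length(query)
  res <- data.frame(
    set = names(collection$sets),
    S = vapply(collection$sets, length, integer(1)),
    n = n,
    m = vapply(collection$sets,
               function(s) length(intersect(query, s)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  res$p_value <- mapply(function(S, m) hypergeom_tail(G, S, n, m),
                        res$S, res$m)
  res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set), , drop = FALSE]
}
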