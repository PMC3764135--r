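#' Partially directed network
#'
#' Compelled (directed) plus non-compelled (undirected) edges over a node
#' set; the causal summary of a learned DAG's Markov-equivalence class under
#' optional background orientations.
#'
#' @param nodes character vector of node labels.
#' @param directed two-column (from, to) matrix of compelled edges.
#' @param undirected two-column matrix of non-compelled edges (stored with
#'   the lexicographically smaller node first).
#' @return an object of class \code{"dm_pdag"}.
#' @export
dm_pdag <- function(nodes, directed = NULL, undirected = NULL) {
  fix <- function(e) {
    if (is.null(e) || NROW(e) == 0L) return(matrix(character(), 0L, 2L))
    e <- as.matrix(e)[, 1:2, drop = FALSE]
    storage.mode(e) <- "character"
    e
  }
  directed <- fix(directed)
  undirected <- fix(undirected)
  if (nrow(undirected)) {
    swap <- undirected[, 1L] > undirected[, 2L]
    undirected[swap, ] <- undirected[swap, c(2L, 1L)]
    undirected <- unique(undirected)
  }
  colnames(directed) <- colnames(undirected) <- c("from", "to")
  if (length(intersect(pair_key(directed[, 1L], directed[, 2L]),
                       pair_key(undirected[, 1L], undirected[, 2L]))))
    stop("an edge cannot be both directed and undirected")
  structure(list(nodes = as.character(nodes), directed = directed,
                 undirected = undirected), class = "dm_pdag")
}

#' @export
print.dm_pdag <- function(x, ...) {
  cat(sprintf("Partially directed network: %d nodes, %d compelled, %d non-compelled\n",
              length(x$nodes), nrow(x$directed), nrow(x$undirected)))
  invisible(x)
}

#' Convert a learned DAG into a PDAG with Meek's rules
#'
#' Identifies which edge orientations of the learned network are compelled
#' -- identical in every Markov-equivalent DAG consistent with the supplied
#' background orientations -- and which are reversible. The procedure: start
#' from the undirected skeleton; orient every v-structure a -> c <- b (a, b
#' non-adjacent) as in the input DAG; orient every background pair present
#' in the graph; then close under Meek's rules R1-R4:
#' \itemize{
#'   \item R1: c -> a, a - b, c and b non-adjacent: orient a -> b (else a
#'     new v-structure at a).
#'   \item R2: a -> c -> b, a - b: orient a -> b (else a cycle).
#'   \item R3: a - b, a - c, a - d, c -> b, d -> b, c and d non-adjacent:
#'     orient a -> b.
#'   \item R4: a - b, a - c, c -> d, d -> b, c and b non-adjacent: orient
#'     a -> b.
#' }
#' Background orientations here are the one-way pairs of the template
#' (\code{\link{asymmetric_constraints}}): prior causal knowledge from the
#' deletion experiments that disambiguates directions Meek's rules alone
#' could not. Background pairs whose edge is absent from the graph are
#' ignored with a warning (the template licenses edges, it does not mandate
#' them); a background pair opposing a v-structure orientation is an error.
#'
#' @param net an acyclic \code{"dm_network"}.
#' @param background optional two-column (from, to) matrix of prior
#'   orientations.
#' @return a \code{"dm_pdag"} with the same skeleton as \code{net}; every
#'   compelled edge keeps its orientation in \code{net}.
#' @export
to_pdag <- function(net, background = NULL) {
  if (is.null(topological_order(net))) stop("input network must be acyclic")
  nodes <- net$nodes
  R <- length(nodes)
  idx <- stats::setNames(seq_len(R), nodes)
  dag <- matrix(FALSE, R, R)
  if (nrow(net$edges))
    dag[cbind(idx[net$edges[, 1L]], idx[net$edges[, 2L]])] <- TRUE
  skel <- dag | t(dag)

  und <- skel            # currently undirected adjacencies (symmetric)
  dir <- matrix(FALSE, R, R)  # compelled orientations

  orient <- function(i, j) {
    und[i, j] <<- und[j, i] <<- FALSE
    dir[i, j] <<- TRUE
  }

  # v-structures of the DAG
  for (c_ in seq_len(R)) {
    ps <- which(dag[, c_])
    if (length(ps) >= 2L) {
      for (a in ps) for (b in ps) {
        if (a < b && !skel[a, b]) { orient(a, c_); orient(b, c_) }
      }
    }
  }

  # background orientations
  if (!is.null(background) && NROW(background)) {
    background <- as.matrix(background)[, 1:2, drop = FALSE]
    for (k in seq_len(nrow(background))) {
      a <- idx[[background[k, 1L]]]; b <- idx[[background[k, 2L]]]
      if (is.null(a) || is.null(b) || !skel[a, b]) {
        warning(sprintf("background pair %s -> %s has no edge in the graph; ignored",
                        background[k, 1L], background[k, 2L]))
        next
      }
      if (dir[b, a])
        stop(sprintf("background pair %s -> %s conflicts with a v-structure orientation",
                     background[k, 1L], background[k, 2L]))
      if (und[a, b]) orient(a, b)
    }
  }

  # Meek closure
  repeat {
    changed <- FALSE
    e <- which(und, arr.ind = TRUE)     # both (a,b) and (b,a) listed
    for (k in seq_len(nrow(e))) {
      a <- e[k, 1L]; b <- e[k, 2L]
      if (!und[a, b]) next              # oriented earlier this sweep
      fire <-
        any(dir[, a] & !skel[, b] & seq_len(R) != b) ||             # R1
        any(dir[a, ] & dir[, b] & seq_len(R) != a & seq_len(R) != b) # R2
      if (!fire) {                                                   # R3
        cs <- which(und[a, ] & dir[, b])
        if (length(cs) >= 2L)
          for (c1 in cs) {
            if (any(!skel[c1, cs] & cs != c1)) { fire <- TRUE; break }
          }
      }
      if (!fire) {                                                   # R4
        cs <- which(und[a, ] & !skel[, b] & seq_len(R) != b)
        for (c1 in cs) {
          if (any(dir[c1, ] & dir[, b])) { fire <- TRUE; break }
        }
      }
      if (fire) { orient(a, b); changed <- TRUE }
    }
    if (!changed) break
  }

  de <- which(dir, arr.ind = TRUE)
  ue <- which(und & upper.tri(und), arr.ind = TRUE)
  out <- dm_pdag(nodes,
                 directed = cbind(nodes[de[, 1L]], nodes[de[, 2L]]),
                 undirected = cbind(nodes[ue[, 1L]], nodes[ue[, 2L]]))
  # soundness: every compelled edge must carry the DAG's own orientation
  if (nrow(out$directed)) {
    ok <- dag[cbind(idx[out$directed[, 1L]], idx[out$directed[, 2L]])]
    stopifnot(all(ok))
  }
  out
}

#' Read / write a PDAG edge list as TSV
#'
#' Three tab-separated columns: source, target, type (\code{directed} or
#' \code{undirected}); undirected rows are written once with the
#' lexicographically smaller node first. No header.
#'
#' @param path file path.
#' @param nodes node labels; defaults to the endpoints present.
#' @return \code{read_pdag}: a \code{"dm_pdag"}; \code{write_pdag}:
#'   \code{path}, invisibly.
#' @export
read_pdag <- function(path, nodes = NULL) {
  df <- tryCatch(utils::read.table(path, header = FALSE, sep = "\t",
                                   colClasses = "character", quote = "",
                                   comment.char = ""),
                 error = function(e) NULL)
  if (is.null(df)) return(dm_pdag(if (is.null(nodes)) character() else nodes))
  if (ncol(df) != 3L) stop("PDAG file must have 3 tab-separated columns")
  bad <- setdiff(unique(df[[3L]]), c("directed", "undirected"))
  if (length(bad)) stop(sprintf("unknown edge type '%s'", bad[1L]))
  d <- df[[3L]] == "directed"
  if (is.null(nodes)) nodes <- unique(c(df[[1L]], df[[2L]]))
  dm_pdag(nodes, directed = as.matrix(df[d, 1:2]),
          undirected = as.matrix(df[!d, 1:2]))
}

#' @rdname read_pdag
#' @param pdag a \code{"dm_pdag"}.
#' @export
write_pdag <- function(pdag, path) {
  rows <- rbind(
    if (nrow(pdag$directed))
      cbind(pdag$directed, type = "directed"),
    if (nrow(pdag$undirected))
      cbind(pdag$undirected, type = "undirected"))
  if (is.null(rows)) rows <- matrix(character(), 0L, 3L)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
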