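#' Incremental acyclicity checker for structure search
#'
#' Maintains the ancestor (reachability) relation of a DAG under edge
#' additions, deletions and reversals, so the search can ask "would this
#' move create a directed cycle?" without a fresh graph traversal per
#' candidate move. Adding a -> b creates a cycle iff b already reaches a;
#' reversing a -> b creates one iff some other directed path a ~> b exists.
#' Additions update the closure incrementally (ancestors of a gain all
#' descendants of b); deletions and reversals recompute the closure, which
#' is the rarer move in greedy ascent.
#'
#' @param nodes character vector of node labels.
#' @param edges optional two-column (from, to) matrix of initial edges; must
#'   form a DAG.
#' @return an environment ("guard") with functions:
#'   \code{would_create_cycle(type, from, to)} for \code{type} in
#'   \code{"add"}, \code{"delete"}, \code{"reverse"};
#'   \code{apply_move(type, from, to)}; \code{has_edge(from, to)};
#'   \code{edges()} returning the current edge matrix; and
#'   \code{reaches(from, to)} exposing the closure.
#' @export
acyclicity_guard <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  R <- length(nodes)
  idx <- stats::setNames(seq_len(R), nodes)
  adj <- matrix(FALSE, R, R, dimnames = list(nodes, nodes))
  reach <- adj

  closure <- function(a) {
    r <- a
    repeat {
      nxt <- r | ((r %*% r) > 0)
      if (identical(nxt, r)) return(r)
      r <- nxt
    }
  }

  resolve <- function(u) {
    i <- idx[[u]]
    if (is.null(i)) stop(sprintf("unknown node '%s'", u))
    i
  }

  would_create_cycle <- function(type, from, to) {
    i <- resolve(from); j <- resolve(to)
    switch(type,
      add = {
        if (i == j) return(TRUE)
        reach[j, i]
      },
      delete = {
        if (!adj[i, j]) stop(sprintf("no edge %s -> %s to delete", from, to))
        FALSE
      },
      reverse = {
        if (!adj[i, j]) stop(sprintf("no edge %s -> %s to reverse", from, to))
        a2 <- adj; a2[i, j] <- FALSE
        # does i still reach j without the direct edge?
        frontier <- which(a2[i, ])
        seen <- rep(FALSE, R)
        while (length(frontier)) {
          if (any(frontier == j)) return(TRUE)
          seen[frontier] <- TRUE
          frontier <- which(colSums(a2[frontier, , drop = FALSE]) > 0 & !seen)
        }
        FALSE
      },
      stop(sprintf("unknown move type '%s'", type)))
  }

  apply_move <- function(type, from, to) {
    i <- resolve(from); j <- resolve(to)
    if (would_create_cycle(type, from, to))
      stop(sprintf("move %s %s -> %s would create a cycle", type, from, to))
    if (type == "add") {
      if (adj[i, j]) stop(sprintf("edge %s -> %s already present", from, to))
      adj[i, j] <<- TRUE
      anc <- reach[, i] | seq_len(R) == i
      desc <- reach[j, ] | seq_len(R) == j
      reach[anc, desc] <<- TRUE
    } else if (type == "delete") {
      adj[i, j] <<- FALSE
      reach <<- closure(adj)
    } else {
      adj[i, j] <<- FALSE
      adj[j, i] <<- TRUE
      reach <<- closure(adj)
    }
    invisible(NULL)
  }

  if (!is.null(edges) && nrow(edges)) {
    for (k in seq_len(nrow(edges))) apply_move("add", edges[k, 1L], edges[k, 2L])
  }

  env <- new.env(parent = emptyenv())
  env$would_create_cycle <- would_create_cycle
  env$apply_move <- apply_move
  env$has_edge <- function(from, to) adj[resolve(from), resolve(to)]
  env$reaches <- function(from, to) reach[resolve(from), resolve(to)]
  env$edges <- function() {
    e <- which(adj, arr.ind = TRUE)
    cbind(from = nodes[e[, 1L]], to = nodes[e[, 2L]])
  }
  env$adjacency <- function() adj
  class(env) <- "acyclicity_guard"
  env
}
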