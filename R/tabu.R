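#' Template-constrained greedy TABU structure search
#'
#' Learns the best-scoring DAG over the mutant columns by greedy ascent from
#' the empty graph. Each iteration enumerates every legal single-edge move --
#' adding an edge the template allows, deleting a current edge, or reversing
#' an edge whose opposite direction the template allows -- discards moves
#' that would create a directed cycle (checked incrementally by
#' \code{\link{acyclicity_guard}}), and applies the move with the largest
#' score gain. An applied move and its inverse are both tabu for
#' \code{tabu_tenure} iterations unless the move would beat the best score
#' seen (aspiration); accepting the best move even when it worsens the
#' score lets the search climb out of shallow local optima. After the first
#' phase converges, \code{restarts} rounds of iterated local search perturb
#' the incumbent with a few random legal moves and re-climb, which undoes
#' early orientation mistakes that pure greedy ascent locks in. The
#' best-scoring graph visited anywhere is returned.
#'
#' Zero-variance columns (mutants with no differentially expressed gene)
#' carry no information under the DM kernel; they stay in the node set but
#' are excluded from move generation, with a warning.
#'
#' Ties between equal-gain moves break lexicographically (add < delete <
#' reverse, then parent label, then child label); all randomness is driven
#' by \code{config$seed}, so a run is fully reproducible.
#'
#' @param data a \code{\link{perturbation_matrix}}.
#' @param template a \code{"template_matrix"} over exactly the mutant set of
#'   \code{data}, or NULL for the fully permissive template.
#' @param config a \code{\link{search_config}}.
#' @param verbose emit one message per applied move (iteration, move, score
#'   delta).
#' @return the best \code{"dm_network"} found, with attributes
#'   \code{score}, \code{iterations} and \code{config}.
#' @export
tabu_search <- function(data, template = NULL, config = search_config(),
                        verbose = FALSE) {
  validate_perturbation_matrix(data)
  nodes <- colnames(data)
  R <- length(nodes)
  if (is.null(template)) template <- permissive_template(nodes)
  validate_template(template)
  if (!setequal(rownames(template), nodes))
    stop("template node set must equal the mutant set of the data")
  allow <- unclass(template)[nodes, nodes]

  scorer <- as_scorer(data, config)
  active <- !scorer$zero_variance[nodes]
  if (any(!active))
    warning(sprintf("%d zero-variance mutant(s) excluded from move generation: %s",
                    sum(!active), paste(nodes[!active], collapse = ", ")))

  max_iter <- config$max_iterations
  if (is.null(max_iter)) max_iter <- 10L * R * R
  eps <- 1e-9
  type_rank <- c(add = 1L, delete = 2L, reverse = 3L)
  move_key <- function(type, u, v) paste(type, u, v, sep = "\r")
  inverse_key <- function(type, u, v) switch(type,
    add = move_key("delete", u, v),
    delete = move_key("add", u, v),
    reverse = move_key("reverse", v, u))

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  # mutable search state
  guard <- acyclicity_guard(nodes)
  pa <- stats::setNames(replicate(R, character(0), simplify = FALSE), nodes)
  ls_cur <- stats::setNames(numeric(R), nodes)
  cur_score <- 0
  best_score <- 0
  best_edges <- matrix(character(), 0L, 2L)
  tabu <- new.env(parent = emptyenv())
  iter <- 0L

  reset_to <- function(edges) {
    guard <<- acyclicity_guard(nodes, edges)
    pa <<- stats::setNames(replicate(R, character(0), simplify = FALSE), nodes)
    if (nrow(edges))
      for (k in seq_len(nrow(edges)))
        pa[[edges[k, 2L]]] <<- c(pa[[edges[k, 2L]]], edges[k, 1L])
    for (n in nodes)
      ls_cur[[n]] <<- local_score(n, pa[[n]], scorer, config)
    cur_score <<- sum(ls_cur)
    tabu <<- new.env(parent = emptyenv())
  }

  # legal moves in the current state, as a list of (type, u, v)
  legal_moves <- function() {
    adj <- guard$adjacency()
    out <- list()
    for (ui in seq_len(R)) {
      u <- nodes[ui]
      if (!active[ui]) next
      for (vi in seq_len(R)) {
        v <- nodes[vi]
        if (ui == vi || !active[vi]) next
        if (adj[ui, vi]) {
          out[[length(out) + 1L]] <- list(type = "delete", u = u, v = v)
          if (allow[vi, ui] == 1L &&
              length(pa[[u]]) < config$max_parents &&
              !guard$would_create_cycle("reverse", u, v))
            out[[length(out) + 1L]] <- list(type = "reverse", u = u, v = v)
        } else if (allow[ui, vi] == 1L && !adj[vi, ui] &&
                   length(pa[[v]]) < config$max_parents &&
                   !guard$would_create_cycle("add", u, v)) {
          out[[length(out) + 1L]] <- list(type = "add", u = u, v = v)
        }
      }
    }
    out
  }

  move_gain <- function(m) {
    if (m$type == "add") {
      local_score(m$v, c(pa[[m$v]], m$u), scorer, config) - ls_cur[[m$v]]
    } else if (m$type == "delete") {
      local_score(m$v, setdiff(pa[[m$v]], m$u), scorer, config) - ls_cur[[m$v]]
    } else {
      (local_score(m$v, setdiff(pa[[m$v]], m$u), scorer, config) - ls_cur[[m$v]]) +
        (local_score(m$u, c(pa[[m$u]], m$v), scorer, config) - ls_cur[[m$u]])
    }
  }

  apply_state_move <- function(m, gain) {
    force(gain)   # must be evaluated against the pre-move state
    stopifnot(m$type != "add" || allow[m$u, m$v] == 1L)   # template invariant
    guard$apply_move(m$type, m$u, m$v)
    if (m$type == "add") {
      pa[[m$v]] <<- c(pa[[m$v]], m$u)
    } else if (m$type == "delete") {
      pa[[m$v]] <<- setdiff(pa[[m$v]], m$u)
    } else {
      pa[[m$v]] <<- setdiff(pa[[m$v]], m$u)
      pa[[m$u]] <<- c(pa[[m$u]], m$v)
      ls_cur[[m$u]] <<- local_score(m$u, pa[[m$u]], scorer, config)
    }
    ls_cur[[m$v]] <<- local_score(m$v, pa[[m$v]], scorer, config)
    cur_score <<- cur_score + gain
    if (isTRUE(getOption("dmbn.debug")) && abs(cur_score - sum(ls_cur)) > 1e-6)
      stop(sprintf("desync after %s %s->%s: cur %.4f, true %.4f",
                   m$type, m$u, m$v, cur_score, sum(ls_cur)))
  }

  climb <- function() {
    non_improving <- 0L
    while (iter < max_iter && non_improving < config$patience) {
      iter <<- iter + 1L
      best_move <- NULL
      best_gain <- -Inf
      for (m in legal_moves()) {
        gain <- move_gain(m)
        expiry <- tabu[[move_key(m$type, m$u, m$v)]]
        is_tabu <- !is.null(expiry) && expiry >= iter
        if (is_tabu && !(cur_score + gain > best_score + eps)) next
        better <- gain > best_gain + eps
        tie <- !better && gain > best_gain - eps && !is.null(best_move) &&
          (type_rank[[m$type]] < type_rank[[best_move$type]] ||
             (type_rank[[m$type]] == type_rank[[best_move$type]] &&
                (m$u < best_move$u ||
                   (m$u == best_move$u && m$v < best_move$v))))
        if (better || tie) {
          best_move <- m
          best_move$gain <- gain
          best_gain <- max(best_gain, gain)
        }
      }
      if (is.null(best_move)) break
      m <- best_move
      if (isTRUE(getOption("dmbn.debug"))) {
        g2 <- move_gain(m)
        if (abs(g2 - m$gain) > 1e-6)
          stop(sprintf("stale gain for %s %s->%s: selected %.4f, fresh %.4f",
                       m$type, m$u, m$v, m$gain, g2))
      }
      apply_state_move(m, m$gain)
      tabu[[inverse_key(m$type, m$u, m$v)]] <- iter + config$tabu_tenure
      tabu[[move_key(m$type, m$u, m$v)]] <- iter + config$tabu_tenure
      if (verbose)
        message(sprintf("iter %d: %s %s -> %s (gain %+.4f, score %.4f)",
                        iter, m$type, m$u, m$v, m$gain, cur_score))
      if (isTRUE(getOption("dmbn.debug"))) {
        adj <- guard$adjacency()
        stopifnot(!any(adj & t(adj)))
        stopifnot(!any(vapply(pa, anyDuplicated, integer(1)) > 0))
        for (n in nodes) {
          stopifnot(setequal(pa[[n]], nodes[adj[, n]]))
          stopifnot(abs(ls_cur[[n]] - local_score(n, pa[[n]], scorer, config)) < 1e-6)
        }
        stopifnot(abs(cur_score - sum(ls_cur)) < 1e-6)
      }
      if (cur_score > best_score + eps) {
        best_score <<- cur_score
        best_edges <<- guard$edges()
        non_improving <- 0L
      } else {
        non_improving <- non_improving + 1L
      }
    }
  }

  climb()

  # Systematic deepening. A greedy phase can lock in a wrongly oriented
  # edge whose cost only materializes through the extra edges it later
  # attracts; single moves cannot escape, because each extra edge still
  # carries real marginal dependence. Two macro-neighbourhoods repair
  # this: (a) force-reversing one incumbent edge, and (b) "lifting" one
  # node -- deleting all its incident edges at once -- then re-climbing;
  # any strict improvement is kept and the sweeps repeat until clean.
  deepen <- function(moves_for) {
    repeat {
      improved <- FALSE
      snapshot <- best_edges
      for (forced in moves_for(snapshot)) {
        if (iter >= max_iter) break
        reset_to(snapshot)
        legal <- TRUE
        for (m in forced) {
          if (m$type == "reverse" && guard$would_create_cycle("reverse", m$u, m$v)) {
            legal <- FALSE
            break
          }
          apply_state_move(m, move_gain(m))
        }
        if (!legal) next
        before <- best_score
        climb()
        if (best_score > before + eps) {
          improved <- TRUE
          break
        }
      }
      if (!improved || iter >= max_iter) break
    }
  }

  deepen(function(snapshot) {      # single-edge reversals
    out <- list()
    for (k in seq_len(nrow(snapshot))) {
      u <- snapshot[k, 1L]; v <- snapshot[k, 2L]
      if (allow[v, u] == 1L)
        out[[length(out) + 1L]] <- list(list(type = "reverse", u = u, v = v))
    }
    out
  })
  deepen(function(snapshot) {      # node lifts
    lapply(nodes[active], function(n) {
      inc <- snapshot[snapshot[, 1L] == n | snapshot[, 2L] == n, ,
                      drop = FALSE]
      lapply(seq_len(nrow(inc)), function(k)
        list(type = "delete", u = inc[k, 1L], v = inc[k, 2L]))
    })
  })

  if (config$restarts > 0L) {
    for (r in seq_len(config$restarts)) {
      if (iter >= max_iter) break
      reset_to(best_edges)
      for (p in seq_len(config$perturb_moves)) {
        mv <- legal_moves()
        if (!length(mv)) break
        m <- mv[[sample.int(length(mv), 1L)]]
        apply_state_move(m, move_gain(m))
      }
      if (verbose)
        message(sprintf("restart %d: perturbed to score %.4f", r, cur_score))
      climb()
    }
  }

  net <- dm_network(nodes, best_edges)
  attr(net, "score") <- best_score
  attr(net, "iterations") <- iter
  attr(net, "config") <- config
  net
}
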