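#' Structure-search configuration
#'
#' Bundles the tunable parameters of the penalized-KGV score and the TABU
#' search.
#'
#' @param omega multiplicative weight on the BIC complexity term, >= 0.
#'   Larger omega prunes weaker dependencies and yields sparser networks;
#'   the published sweep runs 1.5 through 9.
#' @param kappa KGV regularization ridge, > 0.
#' @param tabu_tenure number of iterations the inverse of an applied move
#'   stays forbidden.
#' @param patience consecutive non-improving moves tolerated before the
#'   search stops.
#' @param max_iterations cap on total moves; default \code{10 * R^2} where R
#'   is the node count (resolved at search time when NULL).
#' @param max_parents optional cap on parent-set size (default unlimited).
#' @param restarts number of seeded perturb-and-reclimb rounds after the
#'   first greedy phase (iterated local search). Greedy ascent alone can
#'   lock in an early wrong edge orientation and the extra edges it then
#'   attracts; perturbing the incumbent with a few random legal moves and
#'   re-climbing escapes such traps. 0 gives a single purely deterministic
#'   phase.
#' @param perturb_moves random legal moves applied per restart.
#' @param seed integer seed driving the restart perturbations (and any
#'   other randomness); results are fully reproducible given the config.
#' @return a list of class \code{"search_config"}.
#' @export
search_config <- function(omega = 2, kappa = 0.01, tabu_tenure = 10L,
                          patience = 20L, max_iterations = NULL,
                          max_parents = Inf, restarts = 8L,
                          perturb_moves = 4L, seed = 1L) {
  stopifnot(omega >= 0, kappa > 0, tabu_tenure >= 0, patience >= 1,
            restarts >= 0, perturb_moves >= 1)
  structure(list(omega = omega, kappa = kappa,
                 tabu_tenure = as.integer(tabu_tenure),
                 patience = as.integer(patience),
                 max_iterations = max_iterations,
                 max_parents = max_parents,
                 restarts = as.integer(restarts),
                 perturb_moves = as.integer(perturb_moves),
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Precomputed KGV scorer for one dataset
#'
#' Builds, once, the full 2R x 2R centered feature covariance of all mutant
#' columns; every subsequent KGV evaluation for any variable subset is a
#' small-determinant computation on a submatrix, cached by subset. This is
#' what makes local scoring O(m^3) per call instead of O(N^3).
#'
#' @param data a \code{\link{perturbation_matrix}}.
#' @param kappa regularization ridge, > 0.
#' @return an environment of class \code{"kgv_scorer"} with fields
#'   \code{nodes}, \code{N}, \code{kappa}, \code{zero_variance} (logical per
#'   node) and function \code{kgv(vars)}.
#' @export
kgv_scorer <- function(data, kappa = 0.01) {
  validate_perturbation_matrix(data)
  if (kappa <= 0) stop("kappa must be positive")
  nodes <- colnames(data)
  N <- nrow(data)
  Phi <- do.call(cbind, lapply(seq_along(nodes),
                               function(j) feature_block(data[, j])))
  C <- crossprod(Phi) / N
  zero_variance <- vapply(seq_along(nodes),
                          function(j) all(data[, j] == 0L), logical(1))
  names(zero_variance) <- nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  cache <- new.env(parent = emptyenv())

  kgv <- function(vars) {
    if (!length(vars)) return(0)
    i <- sort(unname(idx[vars]))
    if (anyNA(i)) stop("unknown mutant label in variable set")
    if (length(i) == 1L) return(0)
    key <- paste(i, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cols <- as.vector(rbind(2L * i - 1L, 2L * i))
    val <- kgv_from_cov(C[cols, cols, drop = FALSE],
                        rep(2L, length(i)), kappa)
    cache[[key]] <- val
    val
  }

  env <- new.env(parent = emptyenv())
  env$nodes <- nodes
  env$N <- N
  env$kappa <- kappa
  env$zero_variance <- zero_variance
  env$kgv <- kgv
  class(env) <- "kgv_scorer"
  env
}

as_scorer <- function(data, config) {
  if (inherits(data, "kgv_scorer")) data else kgv_scorer(data, config$kappa)
}

#' Penalized local score of one node given a parent set
#'
#' The decomposable structure score: the data term is N times the KGV
#' multi-information gained by joining the child to its parents, minus an
#' omega-weighted BIC complexity term,
#' \deqn{N\,(\hat J(\{x\} \cup pa) - \hat J(pa)) - \omega\,\frac{d}{2}\,\log N,
#'   \qquad d = 4\,|pa|,}
#' where d counts the Gaussian regression parameters a parent contributes
#' in the rank-2 kernel feature space (2 child channels x 2 parent
#' channels). Charging the true model dimension matters: twice the data
#' term for a null parent is approximately chi-squared with 4 degrees of
#' freedom, so a lighter penalty would admit noise edges at any sample
#' size. Omega re-weights the term to control sparsity beyond the BIC
#' baseline. An empty parent set scores exactly 0.
#'
#' @param child mutant label of the node being scored.
#' @param parents character vector of parent labels (possibly empty).
#' @param data a \code{\link{perturbation_matrix}} or a prebuilt
#'   \code{\link{kgv_scorer}}.
#' @param config a \code{\link{search_config}} (omega and kappa are used).
#' @return the local score in nats.
#' @export
local_score <- function(child, parents, data, config = search_config()) {
  if (child %in% parents) stop("child must not be among its parents")
  if (!length(parents)) return(0)
  sc <- as_scorer(data, config)
  N <- sc$N
  N * (sc$kgv(c(child, parents)) - sc$kgv(parents)) -
    config$omega * 2 * length(parents) * log(N)
}

#' Total score of a directed network
#'
#' Sum of \code{\link{local_score}} over all nodes; the empty graph scores
#' 0.
#'
#' @param net a \code{"dm_network"} (must be acyclic).
#' @param data a \code{\link{perturbation_matrix}} or
#'   \code{\link{kgv_scorer}}.
#' @param config a \code{\link{search_config}}.
#' @return the network score in nats.
#' @export
network_score <- function(net, data, config = search_config()) {
  if (is.null(topological_order(net))) stop("network contains a directed cycle")
  sc <- as_scorer(data, config)
  ps <- parent_sets(net)
  sum(vapply(net$nodes,
             function(n) local_score(n, ps[[n]], sc, config), numeric(1)))
}
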