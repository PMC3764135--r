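#' Configuration of the planted-model simulator
#'
#' Defaults describe a small, sparse regulator panel of the kind the learner
#' is designed for: 10 regulators over 2,000 genes, a sparse planted DAG
#' (expected ~9 edges), ~40 direct targets per regulator, effects decaying
#' by 0.8 per causal step, and a 2% call-corruption rate.
#'
#' @param n_regulators number of perturbed regulators R (>= 2).
#' @param n_genes number of genes N in the expression matrix (>= R; the
#'   regulators themselves occupy the first R rows).
#' @param edge_probability per ordered pair probability of a planted edge,
#'   under a random topological order.
#' @param targets_per_regulator mean number of direct targets (Poisson).
#' @param propagation_decay probability, per causal step, that a
#'   descendant's direct effect shows up in an ancestor's deletion profile
#'   (in (0, 1]).
#' @param noise_flip probability an entry's call is replaced by a uniform
#'   draw from \{-1, 0, 1\}.
#' @param sign_mix probability a direct target is down- rather than
#'   up-regulated.
#' @param seed integer seed; the simulation is deterministic given the
#'   config.
#' @return a list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_regulators = 10L, n_genes = 2000L,
                              edge_probability = 0.2,
                              targets_per_regulator = 40,
                              propagation_decay = 0.8, noise_flip = 0.02,
                              sign_mix = 0.5, seed = 1L) {
  probs <- c(edge_probability, noise_flip, sign_mix)
  if (any(probs < 0 | probs > 1) || propagation_decay <= 0 || propagation_decay > 1)
    stop("probabilities must lie in [0, 1] (propagation_decay in (0, 1])")
  if (n_regulators < 2L) stop("need at least 2 regulators")
  if (n_genes < n_regulators) stop("n_genes must be >= n_regulators")
  structure(list(n_regulators = as.integer(n_regulators),
                 n_genes = as.integer(n_genes),
                 edge_probability = edge_probability,
                 targets_per_regulator = targets_per_regulator,
                 propagation_decay = propagation_decay,
                 noise_flip = noise_flip, sign_mix = sign_mix,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate deletion-mutant profiles over a planted regulator DAG
#'
#' Generates the causal scenario the learner assumes: a hidden regulator
#' DAG in which deleting an upstream regulator perturbs the transcriptional
#' programs of its downstream regulators. Concretely: (1) a random DAG over
#' R regulators is drawn from a random topological order with independent
#' edge inclusion; (2) each regulator gets a signed direct-target set over
#' the non-regulator genes (Poisson size, uniform genes, signs by
#' \code{sign_mix}); (3) columns are generated by ancestral sampling in
#' planted order, so that each mutant's profile is a stochastic function
#' of its regulators' profiles -- the learner's causal premise taken
#' literally: the column of regulator r starts from every nonzero
#' target-gene entry of each parent's \emph{observed} column retained
#' independently with probability \code{propagation_decay} (signs
#' unchanged), with r's own direct targets written on top. Retention
#' composes along edges, so a deep ancestor's influence reaches r with
#' probability about \code{propagation_decay^dist}, and conditioning on
#' the parents screens off all deeper ancestors exactly. (4) The
#' regulators are themselves genes: deleting r marks its own row -1, and
#' the row of each planted descendant regulator d is marked -1 with
#' probability \code{propagation_decay^dist(r, d)} (a deletion
#' dysregulates its downstream regulators), which is what gives the
#' template its one-way orientation evidence. (5) Each completed column is
#' corrupted entry-wise -- with probability \code{noise_flip} an entry is
#' replaced by a uniform draw from \{-1, 0, 1\} -- \emph{before} any child
#' inherits from it, keeping the observed columns Markov with respect to
#' the planted DAG.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param truth optional \code{"dm_network"} to plant instead of sampling a
#'   random DAG (its node set must be \code{reg01 ... regRR} for the
#'   configured R); used to study specific motifs such as chains.
#' @return a list with components \code{truth} (the planted
#'   \code{"dm_network"} over regulator labels), \code{matrix} (the
#'   \code{\link{perturbation_matrix}}, genes x regulators),
#'   \code{direct_targets} (named list of signed direct-target vectors) and
#'   \code{config}.
#' @export
simulate_planted_model <- function(config = simulation_config(), truth = NULL) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config")
  R <- config$n_regulators
  N <- config$n_genes
  regulators <- sprintf("reg%02d", seq_len(R))
  genes <- c(regulators,
             if (N > R) sprintf("g%05d", seq_len(N - R)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  # (1) planted DAG
  if (is.null(truth)) {
    ord <- sample.int(R)
    edges <- NULL
    for (i in seq_len(R - 1L)) for (j in (i + 1L):R) {
      if (stats::runif(1) < config$edge_probability)
        edges <- rbind(edges, c(regulators[ord[i]], regulators[ord[j]]))
    }
    truth <- dm_network(regulators, edges)
  } else {
    if (!setequal(truth$nodes, regulators))
      stop("planted truth must use node labels reg01..reg<R>")
    edges <- if (nrow(truth$edges)) truth$edges else NULL
  }

  # (2) direct targets over the non-regulator genes
  pool <- setdiff(genes, regulators)
  direct <- stats::setNames(vector("list", R), regulators)
  for (r in regulators) {
    k <- min(stats::rpois(1, config$targets_per_regulator), length(pool))
    tg <- sample(pool, k)
    sg <- ifelse(stats::runif(k) < config$sign_mix, -1L, 1L)
    direct[[r]] <- stats::setNames(sg, tg)
  }

  # (3)-(5) ancestral sampling in planted order: each column inherits a
  # decayed sample of its parents' observed (already corrupted) columns,
  # then is corrupted itself before any child sees it
  parents <- stats::setNames(replicate(R, character(0), simplify = FALSE),
                             regulators)
  if (!is.null(edges))
    for (k in seq_len(nrow(edges)))
      parents[[edges[k, 2L]]] <- c(parents[[edges[k, 2L]]], edges[k, 1L])

  # shortest planted path lengths, for the descendant-row marks
  dist <- matrix(Inf, R, R, dimnames = list(regulators, regulators))
  diag(dist) <- 0
  adj <- matrix(FALSE, R, R, dimnames = list(regulators, regulators))
  if (!is.null(edges)) adj[edges] <- TRUE
  for (r in seq_len(R)) {
    frontier <- which(adj[r, ]); step <- 1
    while (length(frontier)) {
      newly <- frontier[dist[r, frontier] > step]
      dist[r, newly] <- step
      frontier <- setdiff(which(colSums(adj[newly, , drop = FALSE]) > 0),
                          which(is.finite(dist[r, ])))
      step <- step + 1
    }
  }

  m <- matrix(0L, N, R, dimnames = list(genes, regulators))
  target_rows <- which(!genes %in% regulators)
  for (r in topological_order(truth)) {
    col <- rep(0L, N); names(col) <- genes
    for (p in sort(parents[[r]])) {
      nz <- target_rows[m[target_rows, p] != 0L]
      keep <- nz[stats::runif(length(nz)) < config$propagation_decay]
      col[keep] <- m[keep, p]
    }
    col[names(direct[[r]])] <- direct[[r]]   # own direct effects dominate
    ds <- regulators[is.finite(dist[r, ]) & dist[r, ] > 0]
    for (d in ds)
      if (stats::runif(1) < config$propagation_decay^dist[r, d])
        col[d] <- -1L
    col[r] <- -1L                            # the deleted gene itself
    flip <- which(stats::runif(N) < config$noise_flip)
    if (length(flip))
      col[flip] <- sample(c(-1L, 0L, 1L), length(flip), replace = TRUE)
    m[, r] <- col
  }

  list(truth = truth,
       matrix = perturbation_matrix(m, genes, regulators),
       direct_targets = direct,
       config = config)
}
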