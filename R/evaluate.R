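#' Collapse duplicate regulators across datasets
#'
#' A regulator profiled in two datasets keeps two network nodes
#' (\code{GENE@d1}, \code{GENE@d2}); for evaluation all such copies are
#' merged onto the bare gene name. However many parallel edges connect two
#' gene copies, the interaction counts once: if every member edge is
#' directed and all agree, the merged edge keeps that direction; any
#' disagreement, or any undirected member, yields one undirected edge.
#' Edges connecting two copies of the same gene are dropped. Idempotent.
#'
#' @param pdag a \code{"dm_pdag"} whose node labels may carry dataset tags.
#' @return a \code{"dm_pdag"} over bare gene names.
#' @export
collapse_duplicates <- function(pdag) {
  genes <- strip_dataset_tag(pdag$nodes)
  nodes <- unique(genes)
  edges <- rbind(
    if (nrow(pdag$directed))
      data.frame(a = strip_dataset_tag(pdag$directed[, 1L]),
                 b = strip_dataset_tag(pdag$directed[, 2L]),
                 directed = TRUE, stringsAsFactors = FALSE),
    if (nrow(pdag$undirected))
      data.frame(a = strip_dataset_tag(pdag$undirected[, 1L]),
                 b = strip_dataset_tag(pdag$undirected[, 2L]),
                 directed = FALSE, stringsAsFactors = FALSE))
  if (is.null(edges) || !nrow(edges)) return(dm_pdag(nodes))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  if (!nrow(edges)) return(dm_pdag(nodes))
  key <- pair_key(edges$a, edges$b)
  dir_out <- und_out <- NULL
  for (k in unique(key)) {
    grp <- edges[key == k, , drop = FALSE]
    ord <- paste(grp$a, grp$b)
    if (all(grp$directed) && length(unique(ord)) == 1L) {
      dir_out <- rbind(dir_out, c(grp$a[1L], grp$b[1L]))
    } else {
      und_out <- rbind(und_out, c(min(grp$a[1L], grp$b[1L]),
                                  max(grp$a[1L], grp$b[1L])))
    }
  }
  dm_pdag(nodes, directed = dir_out, undirected = und_out)
}

#' Precision and recall against reference interactions
#'
#' Matching ignores direction. \code{n_pred} is the number of edges in the
#' (duplicate-collapsed) network; \code{n_known} the number of reference
#' pairs whose both endpoints are network nodes; \code{n_tp} the predicted
#' pairs found in the reference. Precision is \code{n_tp / n_pred} (NA when
#' nothing is predicted) and recall \code{n_tp / n_known} (NA when no
#' reference pair applies).
#'
#' @param pdag a duplicate-collapsed \code{"dm_pdag"}.
#' @param ref an \code{\link{interaction_set}}.
#' @return a list of class \code{"evaluation_report"} with fields
#'   \code{n_tp}, \code{n_known}, \code{n_pred}, \code{precision},
#'   \code{recall}.
#' @export
precision_recall <- function(pdag, ref) {
  pred <- unique(c(
    if (nrow(pdag$directed)) pair_key(pdag$directed[, 1L], pdag$directed[, 2L]),
    if (nrow(pdag$undirected)) pair_key(pdag$undirected[, 1L], pdag$undirected[, 2L])))
  in_net <- ref$node_a %in% pdag$nodes & ref$node_b %in% pdag$nodes
  known <- unique(pair_key(ref$node_a[in_net], ref$node_b[in_net]))
  n_pred <- length(pred)
  n_known <- length(known)
  n_tp <- length(intersect(pred, known))
  structure(list(
    n_tp = n_tp, n_known = n_known, n_pred = n_pred,
    precision = if (n_pred > 0L) n_tp / n_pred else NA_real_,
    recall = if (n_known > 0L) n_tp / n_known else NA_real_),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("predicted %d edges, %d reference pairs among nodes, %d correct\n",
              x$n_pred, x$n_known, x$n_tp))
  cat(sprintf("precision %s, recall %s\n",
              format(x$precision, digits = 4), format(x$recall, digits = 4)))
  invisible(x)
}

#' Orientation precision of compelled edges
#'
#' Among the network's directed (compelled) edges whose gene pair appears in
#' a directed reference (in either direction), the fraction oriented the
#' same way as the reference, with an exact one-sided binomial test against
#' coin-flip orientation (success probability 0.5).
#'
#' @param pdag a \code{"dm_pdag"} (only its directed edges participate).
#' @param ref_pairs two-column (from, to) matrix of reference directed
#'   pairs, e.g. \code{\link{reference_orientation_pairs}}.
#' @return a list of class \code{"orientation_report"} with fields
#'   \code{n_total}, \code{n_correct}, \code{precision} (NA when no
#'   predicted edge overlaps the reference) and \code{binom_p}.
#' @export
orientation_precision <- function(pdag, ref_pairs) {
  ref_pairs <- as.matrix(ref_pairs)
  ref_ord <- if (nrow(ref_pairs)) paste(ref_pairs[, 1L], ref_pairs[, 2L], sep = "\r")
             else character()
  ref_und <- unique(pair_key(ref_pairs[, 1L], ref_pairs[, 2L]))
  d <- pdag$directed
  if (nrow(d)) {
    overlap <- pair_key(d[, 1L], d[, 2L]) %in% ref_und
    n_total <- sum(overlap)
    n_correct <- sum(paste(d[overlap, 1L], d[overlap, 2L], sep = "\r") %in% ref_ord)
  } else {
    n_total <- 0L; n_correct <- 0L
  }
  structure(list(
    n_total = n_total, n_correct = n_correct,
    precision = if (n_total > 0L) n_correct / n_total else NA_real_,
    binom_p = if (n_total > 0L) binomial_tail(n_correct, n_total) else 1),
    class = "orientation_report")
}

#' @export
print.orientation_report <- function(x, ...) {
  cat(sprintf("%d of %d overlapping directed edges correctly oriented (precision %s), binomial p = %s\n",
              x$n_correct, x$n_total, format(x$precision, digits = 4),
              format(x$binom_p, digits = 3)))
  invisible(x)
}

#' Exact one-sided binomial tail at p = 0.5
#'
#' P(X >= k) for X ~ Binomial(n, 1/2), computed as the exact sum
#' \eqn{\sum_{j=k}^n \binom{n}{j} / 2^n}. The binomial coefficients involved
#' are integers below 2^53 for the n used here, so the double-precision sum
#' is exact. This is the test of whether predicted edge orientations beat
#' coin tossing.
#'
#' @param k observed successes (correctly oriented edges), 0 <= k <= n.
#' @param n trials (overlapping edges), >= 1.
#' @return the upper-tail p-value in (0, 1].
#' @examples
#' binomial_tail(33, 37)  # 5.42e-07
#' binomial_tail(6, 7)    # 0.0625 = 8/128
#' @export
binomial_tail <- function(k, n) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n and n >= 1")
  sum(choose(n, k:n)) / 2^n
}

#' Directed reference pairs from the perturbation matrix itself
#'
#' The regulator-DEG reference: the ordered pair A -> B is a reference
#' causal pair iff regulator gene B is differentially expressed in mutant
#' A's deletion column. Double-deletion mutants contribute a pair when any
#' constituent gene of B responds; self pairs are excluded.
#'
#' @param m a \code{\link{perturbation_matrix}} whose rows include the
#'   regulator genes.
#' @param mutants mutant labels to consider (default all columns).
#' @return a two-column character matrix (from, to) of mutant labels.
#' @export
reference_orientation_pairs <- function(m, mutants = colnames(m)) {
  validate_perturbation_matrix(m)
  genes <- mutant_genes(mutants)
  out <- NULL
  for (a in seq_along(mutants)) {
    col <- m[, mutants[a]]
    for (b in seq_along(mutants)) {
      if (a == b) next
      gb <- intersect(genes[[b]], rownames(m))
      if (length(gb) && any(col[gb] != 0L))
        out <- rbind(out, c(mutants[a], mutants[b]))
    }
  }
  if (is.null(out)) out <- matrix(character(), 0L, 2L)
  colnames(out) <- c("from", "to")
  out
}

#' Jaccard similarity of two target-gene sets
#'
#' Intersection over union; the crude pairwise baseline the network learner
#' is compared against. Signs are ignored. Two empty sets score 0 by
#' convention.
#'
#' @param targets_a,targets_b character vectors of gene ids (or signed
#'   target vectors, whose names are used).
#' @return a value in [0, 1].
#' @export
jaccard_index <- function(targets_a, targets_b) {
  a <- if (is.null(names(targets_a))) unique(as.character(targets_a))
       else unique(names(targets_a))
  b <- if (is.null(names(targets_b))) unique(as.character(targets_b))
       else unique(names(targets_b))
  common <- length(intersect(a, b))
  denom <- length(a) + length(b) - common
  if (denom == 0L) 0 else common / denom
}

#' Jaccard-threshold baseline network
#'
#' Connects two mutants by an undirected edge whenever the Jaccard index of
#' their target-gene sets exceeds the threshold.
#'
#' @param targets named list of target vectors
#'   (\code{\link{extract_target_lists}}).
#' @param threshold Jaccard cutoff in [0, 1]; an edge requires JI strictly
#'   above it.
#' @return a \code{"dm_pdag"} with undirected edges only.
#' @export
jaccard_network <- function(targets, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  ids <- names(targets)
  R <- length(ids)
  out <- NULL
  if (R >= 2L) {
    for (i in seq_len(R - 1L)) for (j in (i + 1L):R) {
      if (jaccard_index(targets[[i]], targets[[j]]) > threshold)
        out <- rbind(out, c(ids[i], ids[j]))
    }
  }
  dm_pdag(ids, undirected = out)
}
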