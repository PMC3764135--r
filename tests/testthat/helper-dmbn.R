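# Shared fixtures and independent oracles for the dmbn test suite.
# Everything here is deliberately written from first principles (dense
# loops, explicit enumeration) so it cannot share a defect with the
# production code paths it checks.

random_calls <- function(n, p_up = 0.15, p_down = 0.15) {
  sample(c(-1L, 0L, 1L), n, replace = TRUE,
         prob = c(p_down, 1 - p_up - p_down, p_up))
}

random_perturbation_matrix <- function(n_genes, n_mutants,
                                       genes = sprintf("g%03d", seq_len(n_genes)),
                                       mutants = sprintf("m%02d", seq_len(n_mutants))) {
  perturbation_matrix(matrix(random_calls(n_genes * n_mutants),
                             n_genes, n_mutants), genes, mutants)
}

# Elementwise DM-kernel Gram matrix, no feature map involved.
brute_gram <- function(x, y = x) {
  outer(x, y, function(a, b) as.numeric(a == b & a != 0L))
}

# N-dimensional Gram-matrix formulation of the KGV, built purely from
# kernel evaluations: with centered Grams Ktil_i = H K_i H / N and the
# per-variable ridge lambda_i = kappa * tr(Ktil_i) / 2, the determinant
# ratio lifts to
#   J = -1/2 [ logdet(I_N + sum_i Ktil_i / lambda_i)
#              - sum_i logdet(I_N + Ktil_i / lambda_i) ].
gram_kgv <- function(columns, kappa = 0.01) {
  N <- length(columns[[1L]])
  H <- diag(N) - matrix(1 / N, N, N)
  Ks <- lapply(columns, function(x) H %*% brute_gram(x) %*% H / N)
  lams <- vapply(Ks, function(K) kappa * sum(diag(K)) / 2, numeric(1))
  live <- lams > 0
  if (sum(live) < 2L) return(0)
  Ks <- Ks[live]; lams <- lams[live]
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  scaled <- Map(function(K, l) K / l, Ks, lams)
  v <- -0.5 * (ld(diag(N) + Reduce(`+`, scaled)) -
                 sum(vapply(scaled, function(S) ld(diag(N) + S), numeric(1))))
  max(v, 0)
}

# Fresh depth-first-search cycle check, independent of acyclicity_guard.
dfs_has_cycle <- function(adj) {
  n <- nrow(adj)
  state <- integer(n)   # 0 unseen, 1 on stack, 2 done
  cyc <- FALSE
  visit <- function(i) {
    if (cyc) return()
    state[i] <<- 1L
    for (j in which(adj[i, ])) {
      if (state[j] == 1L) { cyc <<- TRUE; return() }
      if (state[j] == 0L) visit(j)
    }
    state[i] <<- 2L
  }
  for (i in seq_len(n)) if (state[i] == 0L) visit(i)
  cyc
}

# Enumerate every DAG on n labelled nodes as a vector of pair states
# (0 none, 1 low->high, 2 high->low over the C(n,2) node pairs), returning
# a list with adjacency matrices plus skeleton / v-structure signatures.
enumerate_dags <- function(n, nodes = LETTERS[seq_len(n)]) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  states <- as.matrix(expand.grid(rep(list(0:2), np)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    st <- states[r, ]
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    for (k in seq_len(np)) {
      if (st[k] == 1) adj[pairs[k, 1L], pairs[k, 2L]] <- TRUE
      if (st[k] == 2) adj[pairs[k, 2L], pairs[k, 1L]] <- TRUE
    }
    if (dfs_has_cycle(adj)) next
    skel <- paste(which(st != 0), collapse = ",")
    vkey <- vstructure_key(adj)
    out[[length(out) + 1L]] <- list(adj = adj, state = st,
                                    skel = skel, vkey = vkey)
  }
  out
}

vstructure_key <- function(adj) {
  n <- nrow(adj)
  skel <- adj | t(adj)
  vs <- character()
  for (c_ in seq_len(n)) {
    ps <- which(adj[, c_])
    if (length(ps) >= 2L)
      for (a in ps) for (b in ps)
        if (a < b && !skel[a, b])
          vs <- c(vs, sprintf("%d-%d>%d", a, b, c_))
  }
  paste(sort(vs), collapse = ";")
}

adj_to_network <- function(adj) {
  e <- which(adj, arr.ind = TRUE)
  dm_network(rownames(adj), cbind(rownames(adj)[e[, 1L]],
                                  colnames(adj)[e[, 2L]]))
}

# Unordered pair keys for skeleton comparisons.
skeleton_keys <- function(edges) {
  if (NROW(edges) == 0L) return(character())
  sort(paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L])))
}

pdag_directed_keys <- function(pdag) {
  if (!nrow(pdag$directed)) return(character())
  sort(paste(pdag$directed[, 1L], pdag$directed[, 2L]))
}

# Ten-node chain fixture used by search and synth tests.
chain_network <- function(R) {
  regs <- sprintf("reg%02d", seq_len(R))
  dm_network(regs, cbind(regs[-R], regs[-1L]))
}
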