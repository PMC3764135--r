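test_that("single edges are non-compelled and colliders are compelled", {
  g1 <- dm_network(c("A", "B"), rbind(c("A", "B")))
  p1 <- to_pdag(g1)
  expect_equal(nrow(p1$directed), 0L)
  expect_equal(unname(p1$undirected), cbind("A", "B"), ignore_attr = TRUE)

  g2 <- dm_network(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  p2 <- to_pdag(g2)
  expect_equal(nrow(p2$undirected), 0L)
  expect_setequal(pdag_directed_keys(p2), c("A C", "B C"))
})

test_that("background knowledge propagates through rule R1", {
  g <- dm_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_equal(nrow(to_pdag(g)$directed), 0L)   # chain class, nothing compelled
  p <- to_pdag(g, background = rbind(c("A", "B")))
  expect_setequal(pdag_directed_keys(p), c("A B", "B C"))
  expect_equal(nrow(p$undirected), 0L)
})

test_that("conflicting and absent background pairs error and warn respectively", {
  g <- dm_network(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  expect_error(to_pdag(g, background = rbind(c("C", "A"))), "conflict")
  expect_warning(p <- to_pdag(g, background = rbind(c("A", "B"))),
                 "no edge")
  expect_setequal(pdag_directed_keys(p), c("A C", "B C"))
})

test_that("the PDAG skeleton always equals the input skeleton", {
  set.seed(101)
  dags <- enumerate_dags(4)
  picks <- sample(length(dags), 40)
  for (k in picks) {
    net <- adj_to_network(dags[[k]]$adj)
    p <- to_pdag(net)
    expect_setequal(c(skeleton_keys(p$directed), skeleton_keys(p$undirected)),
                    skeleton_keys(net$edges))
    # every compelled edge keeps the input orientation
    for (r in seq_len(nrow(p$directed)))
      expect_true(dags[[k]]$adj[p$directed[r, 1L], p$directed[r, 2L]])
  }
})

test_that("compelled status matches equivalence-class enumeration on 4 nodes", {
  dags <- enumerate_dags(4)
  classes <- split(seq_along(dags),
                   vapply(dags, function(d) paste(d$skel, d$vkey, sep = "|"),
                          character(1)))
  for (cls in classes) {
    members <- lapply(dags[cls], `[[`, "state")
    rep_dag <- dags[[cls[1L]]]
    p <- to_pdag(adj_to_network(rep_dag$adj))
    # an edge is compelled iff its pair state is constant across the class
    states <- do.call(rbind, members)
    compelled_pairs <- character()
    nodes <- rownames(rep_dag$adj)
    pairs <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      st <- unique(states[, k])
      if (length(st) == 1L && st != 0)
        compelled_pairs <- c(compelled_pairs,
                             paste(nodes[pairs[k, 1L]], nodes[pairs[k, 2L]]))
    }
    got <- skeleton_keys(p$directed)
    expect_setequal(got, compelled_pairs)
  }
})

test_that("adding background never removes compelled edges", {
  set.seed(103)
  dags <- enumerate_dags(4)
  for (k in sample(length(dags), 25)) {
    net <- adj_to_network(dags[[k]]$adj)
    if (!nrow(net$edges)) next
    base <- pdag_directed_keys(to_pdag(net))
    bg_rows <- sample(nrow(net$edges), sample(nrow(net$edges), 1))
    p <- to_pdag(net, background = net$edges[bg_rows, , drop = FALSE])
    expect_true(all(base %in% pdag_directed_keys(p)))
  }
})

test_that("PDAG edge lists round-trip through TSV", {
  p <- dm_pdag(c("A", "B", "C", "D"),
               directed = rbind(c("A", "C"), c("B", "C")),
               undirected = rbind(c("D", "A")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pdag(p, path)
  q <- read_pdag(path, nodes = p$nodes)
  expect_setequal(pdag_directed_keys(q), pdag_directed_keys(p))
  expect_equal(q$undirected, rbind(c(from = "A", to = "D")), ignore_attr = TRUE)
  expect_error(dm_pdag("A", directed = rbind(c("A", "B")),
                       undirected = rbind(c("A", "B"))), "both")
})
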