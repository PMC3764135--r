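test_that("duplicate-gene collapsing merges parallel edges as documented", {
  p <- dm_pdag(c("A@d1", "B@d1", "A@d2", "B@d2", "C@d1"),
               directed = rbind(c("A@d1", "B@d1"), c("A@d2", "B@d2"),
                                c("A@d1", "C@d1")))
  got <- collapse_duplicates(p)
  expect_setequal(got$nodes, c("A", "B", "C"))
  expect_setequal(pdag_directed_keys(got), c("A B", "A C"))
  expect_equal(nrow(got$undirected), 0L)

  # conflicting directions collapse to one undirected edge
  q <- collapse_duplicates(dm_pdag(c("A@d1", "B@d1", "A@d2", "B@d2"),
                                   directed = rbind(c("A@d1", "B@d1"),
                                                    c("B@d2", "A@d2"))))
  expect_equal(nrow(q$directed), 0L)
  expect_equal(unname(q$undirected), cbind("A", "B"), ignore_attr = TRUE)

  # any undirected member forces undirected; self-pairs are dropped
  r <- collapse_duplicates(dm_pdag(c("A@d1", "A@d2", "B@d1"),
                                   directed = rbind(c("A@d1", "A@d2")),
                                   undirected = rbind(c("A@d1", "B@d1"))))
  expect_equal(nrow(r$directed), 0L)
  expect_equal(unname(r$undirected), cbind("A", "B"), ignore_attr = TRUE)

  # no duplicates: identity up to tag stripping, and idempotence
  s <- dm_pdag(c("X@k", "Y@k"), directed = rbind(c("X@k", "Y@k")))
  c1 <- collapse_duplicates(s)
  expect_identical(collapse_duplicates(c1), c1)
  expect_equal(unname(c1$directed), cbind("X", "Y"), ignore_attr = TRUE)
})

test_that("precision and recall follow the counting definitions", {
  net <- dm_pdag(c("A", "B", "C", "D"),
                 directed = rbind(c("A", "B")),
                 undirected = rbind(c("B", "C"), c("A", "D")))
  ref <- interaction_set(c("A", "B", "A", "C", "E"),
                         c("B", "C", "C", "D", "F"),
                         c("--", "->", "--", "--", "--"))
  rep <- precision_recall(net, ref)
  expect_equal(rep$n_pred, 3L)
  expect_equal(rep$n_known, 4L)   # E-F excluded: endpoints absent
  expect_equal(rep$n_tp, 2L)      # A-B and B-C, matching ignores direction
  expect_equal(rep$precision, 2 / 3)
  expect_equal(rep$recall, 1 / 2)

  # perfect prediction
  perfect <- dm_pdag(c("A", "B", "C", "D"),
                     undirected = rbind(c("A", "B"), c("B", "C"),
                                        c("A", "C"), c("C", "D")))
  rep2 <- precision_recall(perfect, ref)
  expect_equal(rep2$precision, 1)
  expect_equal(rep2$recall, 1)

  # empty network: zero recall, undefined precision
  rep3 <- precision_recall(dm_pdag(c("A", "B", "C", "D")), ref)
  expect_true(is.na(rep3$precision))
  expect_equal(rep3$recall, 0)

  # order invariance
  net_flip <- dm_pdag(c("A", "B", "C", "D"),
                      directed = rbind(c("A", "B")),
                      undirected = rbind(c("D", "A"), c("C", "B")))
  expect_equal(precision_recall(net_flip, ref)[c("n_tp", "precision")],
               rep[c("n_tp", "precision")])
})

test_that("orientation precision counts overlap regardless of direction", {
  ref <- rbind(c("A", "B"), c("B", "C"), c("C", "D"))
  net <- dm_pdag(c("A", "B", "C", "D"),
                 directed = rbind(c("A", "B"), c("C", "B"), c("A", "D")))
  rep <- orientation_precision(net, ref)
  expect_equal(rep$n_total, 2L)      # A->B and C->B overlap; A->D does not
  expect_equal(rep$n_correct, 1L)    # only A->B matches the reference
  expect_equal(rep$precision, 0.5)
  expect_equal(rep$binom_p, binomial_tail(1, 2))

  exact <- dm_pdag(c("A", "B", "C", "D"), directed = ref)
  expect_equal(orientation_precision(exact, ref)$precision, 1)

  empty <- orientation_precision(dm_pdag(c("A", "B")), ref)
  expect_true(is.na(empty$precision))
  expect_equal(empty$binom_p, 1)
})

test_that("random orientations center on one half", {
  set.seed(111)
  ref <- cbind(sprintf("u%02d", 1:20), sprintf("v%02d", 1:20))
  props <- vapply(1:500, function(i) {
    flip <- runif(20) < 0.5
    pred <- ref
    pred[flip, ] <- pred[flip, c(2, 1)]
    orientation_precision(dm_pdag(unique(as.vector(ref)), directed = pred),
                          ref)$precision
  }, numeric(1))
  se <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - 0.5), 3 * se + 1e-12)
})

test_that("binomial tails are exact and agree with pbinom", {
  expect_equal(binomial_tail(6, 7), 8 / 128)
  expect_equal(binomial_tail(0, 13), 1)
  expect_error(binomial_tail(5, 4), "k <= n")
  for (n in c(1, 7, 20, 37, 40)) {
    for (k in 0:n) {
      expect_equal(binomial_tail(k, n),
                   pbinom(k - 1, n, 0.5, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("Jaccard index and threshold networks behave as defined", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_equal(jaccard_index(character(), character()), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("a", "b", "d", "e")), 0.4)
  # signed target vectors: signs ignored, names used
  expect_equal(jaccard_index(c(a = 1L, b = -1L), c(a = -1L, b = 1L)), 1)

  set.seed(112)
  m <- random_perturbation_matrix(40, 6)
  tl <- extract_target_lists(m)
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.5, 1),
                   function(th) nrow(jaccard_network(tl, th)$undirected),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)   # threshold 1 is unreachable
  full <- jaccard_network(list(a = c(x = 1L), b = c(x = 1L), c = c(x = -1L)), 0)
  expect_equal(nrow(full$undirected), 3L)   # all-overlapping: complete graph
  expect_error(jaccard_network(tl, 2), "threshold")
})

test_that("regulator-DEG reference pairs equal a brute-force column scan", {
  sim <- simulate_planted_model(simulation_config(n_regulators = 5,
                                                  n_genes = 80, seed = 3))
  got <- reference_orientation_pairs(sim$matrix)
  m <- sim$matrix
  want <- NULL
  for (a in colnames(m)) for (b in colnames(m))
    if (a != b && m[b, a] != 0L) want <- rbind(want, c(a, b))
  expect_equal(unname(got), unname(want))

  empty <- perturbation_matrix(matrix(0L, 3, 2),
                               c("A", "B", "g1"), c("A", "B"))
  expect_equal(nrow(reference_orientation_pairs(empty)), 0L)
})
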