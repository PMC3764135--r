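test_that("perturbation matrix TSV round-trips preserve content and order", {
  m <- perturbation_matrix(matrix(c(1L, 0L, -1L, 0L, 1L, 0L), 3, 2),
                           c("g1", "g2", "g3"), c("mutA", "mutB"))
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(m["g3", "mutA"], -1L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_perturbation_matrix(m, path)
  expect_identical(read_perturbation_matrix(path), m)

  set.seed(11)
  for (i in 1:5) {
    r <- random_perturbation_matrix(sample(5:40, 1), sample(2:8, 1))
    write_perturbation_matrix(r, path)
    expect_identical(read_perturbation_matrix(path), r)
  }
})

test_that("matrix reader rejects malformed files with cell-level messages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmutA", "g1\t1", "g2\t2"), path)
  expect_error(read_perturbation_matrix(path), "g2.*mutA|mutA.*g2")
  writeLines(c("gene\tmutA", "g1\t1", "g1\t0"), path)
  expect_error(read_perturbation_matrix(path), "duplicate gene")
  writeLines(c("gene\tmutA", "g1\tx"), path)
  expect_error(read_perturbation_matrix(path), "non-integer")
  expect_error(read_perturbation_matrix(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("discretization matches the elementwise thresholding rule", {
  x <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_true(all(discretize_expression(x) == 0L))
  x[1, 1] <- 1.5
  expect_identical(discretize_expression(x, up = 1)[1, 1], 1L)

  set.seed(4)
  y <- matrix(rnorm(8, sd = 2), 4, 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  y[2, 2] <- NA
  got <- discretize_expression(y, up = 1.2, down = -0.8)
  manual <- ifelse(is.na(y), 0L, ifelse(y >= 1.2, 1L, ifelse(y <= -0.8, -1L, 0L)))
  expect_equal(unclass(got), manual, ignore_attr = TRUE)
  expect_error(discretize_expression(y, up = -1, down = -2), "down < 0 < up")
})

test_that("target lists are exactly the signed nonzero entries per column", {
  m <- perturbation_matrix(matrix(c(0L, 0L, 0L, 1L, 0L, -1L), 3, 2),
                           c("g1", "g2", "g3"), c("m1", "m2"))
  tl <- extract_target_lists(m)
  expect_length(tl$m1, 0)
  expect_identical(tl$m2, c(g1 = 1L, g3 = -1L))

  set.seed(7)
  r <- random_perturbation_matrix(50, 6)
  tl <- extract_target_lists(r)
  for (j in colnames(r)) {
    expect_identical(length(tl[[j]]), sum(r[, j] != 0L))
    expect_identical(unname(tl[[j]]), unname(r[r[, j] != 0L, j]))
  }
})

test_that("interaction sets normalize direction flags and duplicates", {
  s <- interaction_set(c("A", "B", "A"), c("B", "A", "B"),
                       c("--", "--", "->"))
  expect_equal(nrow(s), 2L)            # the two undirected rows collapse
  expect_setequal(s$direction, c("--", "->"))

  expect_error(interaction_set("A", "B", "=>"), "unknown direction")

  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- interaction_set(c("x", "y", "q", "y"), c("z", "x", "r", "x"),
                          c("--", "->", "--", "->"))
  expect_equal(nrow(rows), 3L)         # one logical duplicate dropped
  write_interaction_set(rows, path)
  expect_identical(read_interaction_set(path), rows)
})

test_that("mutant label grammar strips tags and splits double deletions", {
  expect_identical(strip_dataset_tag(c("YFG1@kinome", "YFG2")),
                   c("YFG1", "YFG2"))
  expect_identical(mutant_genes("ARK1+PRK1@chromatin")[[1L]],
                   c("ARK1", "PRK1"))
})

test_that("target lists export as GMT lines", {
  m <- perturbation_matrix(matrix(c(1L, -1L, 0L), 3, 1),
                           c("g1", "g2", "g3"), "mut")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_target_gmt(extract_target_lists(m), path)
  got <- read_gmt(path)
  expect_identical(got$mut, c("g1", "g2"))
})
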