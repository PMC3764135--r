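test_that("simulation is deterministic given the config seed", {
  cfg <- simulation_config(n_regulators = 6, n_genes = 200, seed = 17)
  s1 <- simulate_planted_model(cfg)
  s2 <- simulate_planted_model(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth$edges, s2$truth$edges)
  s3 <- simulate_planted_model(simulation_config(n_regulators = 6,
                                                 n_genes = 200, seed = 18))
  expect_false(identical(s1$matrix, s3$matrix))
})

test_that("without edges or noise every column is its own direct-target set", {
  sim <- simulate_planted_model(simulation_config(
    n_regulators = 5, n_genes = 150, edge_probability = 0,
    noise_flip = 0, seed = 2))
  expect_equal(nrow(sim$truth$edges), 0L)
  m <- sim$matrix
  for (r in colnames(m)) {
    nz <- rownames(m)[m[, r] != 0L]
    expect_setequal(nz, c(names(sim$direct_targets[[r]]), r))
    expect_identical(unname(m[r, r]), -1L)
  }
})

test_that("full-strength propagation nests profiles down a chain", {
  chain <- chain_network(4)
  sim <- simulate_planted_model(simulation_config(
    n_regulators = 4, n_genes = 200, propagation_decay = 1,
    noise_flip = 0, seed = 5), truth = chain)
  m <- sim$matrix
  target_rows <- setdiff(rownames(m), colnames(m))
  for (k in 1:3) {
    up <- which(m[target_rows, k] != 0L)
    down <- which(m[target_rows, k + 1L] != 0L)
    expect_true(all(up %in% down))   # child inherits everything upstream
    # signs propagate unchanged except where the child's own direct
    # targets take precedence
    own <- names(sim$direct_targets[[k + 1L]])
    inh <- setdiff(names(up), own)
    expect_true(all(m[inh, k] == m[inh, k + 1L]))
  }
  # every ancestor->descendant regulator row is marked at decay 1
  ref <- reference_orientation_pairs(m)
  keys <- paste(ref[, 1L], ref[, 2L])
  for (i in 1:3) for (j in (i + 1L):4)
    expect_true(paste(sprintf("reg%02d", i), sprintf("reg%02d", j)) %in% keys)
})

test_that("leaf-column density matches the closed-form expectation", {
  # chain r1 -> ... -> r5; for each non-regulator gene g the nonzero
  # probability follows u_j = 1{g in direct_j} else decay * q_{j-1},
  # q_j = (1 - nu) u_j + (2/3) nu; regulator rows follow decay^dist with
  # noise applied on top. Entries of the leaf column are independent given
  # the realized direct-target sets, so the aggregate z-score is exact.
  chain <- chain_network(5)
  nu <- 0.05; decay <- 0.7
  z_num <- 0; z_var <- 0
  for (s in 1:20) {
    sim <- simulate_planted_model(simulation_config(
      n_regulators = 5, n_genes = 300, targets_per_regulator = 25,
      propagation_decay = decay, noise_flip = nu, seed = s), truth = chain)
    m <- sim$matrix
    regs <- colnames(m)
    tg <- setdiff(rownames(m), regs)
    q <- rep(0, length(tg)); names(q) <- tg
    for (j in seq_along(regs)) {
      u <- decay * q
      u[names(sim$direct_targets[[regs[j]]])] <- 1
      q <- (1 - nu) * u + (2 / 3) * nu
    }
    # regulator rows in the leaf column: own row 1, ancestors decay^dist
    leaf <- regs[5]
    qr <- rep(0, 5)
    qr[5] <- 1
    # marks flow from a deletion to its descendants, so the leaf column
    # marks no other regulator rows beyond noise
    qr_noise <- (1 - nu) * qr + (2 / 3) * nu
    expected <- sum(q) + sum(qr_noise)
    observed <- sum(m[, leaf] != 0L)
    z_num <- z_num + (observed - expected)
    z_var <- z_var + sum(q * (1 - q)) + sum(qr_noise * (1 - qr_noise))
  }
  expect_lt(abs(z_num), 3 * sqrt(z_var))
})

test_that("a planted truth network can be supplied explicitly", {
  chain <- chain_network(6)
  sim <- simulate_planted_model(simulation_config(n_regulators = 6,
                                                  n_genes = 100, seed = 1),
                                truth = chain)
  expect_identical(sim$truth$edges, chain$edges)
  expect_error(simulate_planted_model(simulation_config(n_regulators = 4),
                                      truth = chain), "reg01")
})
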