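test_that("build_tpm reproduces hand-enumerable update rules", {
  # 1-node identity network
  id1 <- boolean_network(parents = list(0L), tables = list(c(0, 1)))
  expect_equal(build_tpm(id1)$probs, diag(2))

  # two nodes copying each other: permutation swapping states 01 and 10
  swap <- boolean_network(parents = list(1L, 0L),
                          tables = list(c(0, 1), c(0, 1)))
  P <- build_tpm(swap)$probs
  perm <- matrix(0, 4, 4)
  perm[1, 1] <- perm[4, 4] <- 1
  perm[2, 3] <- perm[3, 2] <- 1   # state 01 (index 1) <-> state 10 (index 2)
  expect_equal(P, perm)

  # node0 = XOR of both nodes, node1 = constant 0: exhaustive evaluation
  net <- boolean_network(parents = list(c(0L, 1L), integer(0)),
                         tables = list(c(0, 1, 1, 0), 0))
  P <- build_tpm(net)$probs
  for (x in 0:3) {
    b0 <- x %% 2; b1 <- x %/% 2
    y_expected <- xor(b0 == 1, b1 == 1) * 1
    expect_equal(P[x + 1, ], as.numeric(0:3 == y_expected))
  }
})

test_that("malformed networks are rejected with the offending node named", {
  expect_error(boolean_network(parents = list(c(0L, 1L)), tables = list(c(0, 1))),
               "node 0")
  expect_error(boolean_network(parents = list(5L), tables = list(c(0, 1))),
               "parent indices")
  expect_error(boolean_network(parents = list(0L), tables = list(c(0, 2))),
               "probabilities")
})

test_that("tpm validation enforces row-stochasticity with a tolerance band", {
  expect_error(tpm(matrix(c(1, 0, 0.4, 0.5), 2, 2, byrow = TRUE)), "row 1")
  expect_warning(x <- tpm(matrix(c(1, 1e-7, 0, 1), 2, 2, byrow = TRUE)),
                 "renormalising")
  expect_equal(rowSums(x$probs), c(1, 1))
  expect_error(tpm(matrix(1, 2, 3)), "square")
  expect_error(tpm(matrix(c(1.5, -0.5, 0, 1), 2, 2, byrow = TRUE)), "non-negative")
})

test_that("stationary distribution follows the largest recurrent class", {
  # doubly stochastic: uniform
  P <- matrix(1 / 4, 4, 4)
  expect_equal(as.numeric(stationary_distribution(tpm(P))), rep(0.25, 4))

  # two absorbing states plus a 3-cycle: the cycle is the largest class
  P <- matrix(0, 5, 5)
  P[1, 1] <- 1; P[2, 2] <- 1
  P[3, 4] <- 1; P[4, 5] <- 1; P[5, 3] <- 1
  pi0 <- as.numeric(stationary_distribution(tpm(P)))
  expect_equal(pi0, c(0, 0, 1, 1, 1) / 3)

  # random ergodic chain: agrees with the dominant left eigenvector
  set.seed(42)
  P <- matrix(runif(64) + 0.01, 8, 8); P <- P / rowSums(P)
  pi0 <- as.numeric(stationary_distribution(tpm(P)))
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  expect_equal(pi0, v / sum(v), tolerance = 1e-10)
  expect_lt(sum(abs(pi0 %*% P - pi0)), 1e-10)
})

test_that("stationary ties break toward the class with the lowest state", {
  P <- diag(4)   # four singleton attractors, all size 1
  pi0 <- as.numeric(stationary_distribution(tpm(P)))
  expect_equal(pi0, c(1, 0, 0, 0))
})

test_that("output and joint distributions compose as matrix products", {
  set.seed(7)
  P <- matrix(runif(16), 4, 4); P <- P / rowSums(P)
  x <- tpm(P)
  point <- state_distribution(c(0, 0, 1, 0))
  expect_equal(as.numeric(output_distribution(x, point)), P[3, ])

  u <- state_distribution(rep(1 / 4, 4))
  expect_equal(as.numeric(output_distribution(tpm(diag(4)[c(2, 3, 4, 1), ]), u)),
               rep(1 / 4, 4))

  # identity chain from uniform input: diagonal joint
  J <- joint_past_future(tpm(diag(2)), state_distribution(c(.5, .5)))
  expect_equal(J$probs, diag(2) / 2)

  # stationary input: future marginal equals past marginal
  pi0 <- stationary_distribution(x)
  J <- joint_past_future(x, pi0)
  expect_equal(colSums(J$probs), rowSums(J$probs), tolerance = 1e-12)
  expect_equal(sum(J$probs), 1)
})

test_that("temporal MI attains its known extremes", {
  # point attractor: zero information
  P <- matrix(0, 3, 3); P[, 1] <- 1
  J <- joint_past_future(tpm(P), stationary_distribution(tpm(P)))
  expect_equal(temporal_mutual_information(J), 0)

  # deterministic permutation visited uniformly: log2(n)
  for (n in c(4, 8)) {
    perm <- diag(n)[c(2:n, 1), ]
    J <- joint_past_future(tpm(perm), state_distribution(rep(1 / n, n)))
    expect_equal(temporal_mutual_information(J), log2(n))
  }
})

test_that("MI is bounded and respects the data-processing inequality", {
  set.seed(11)
  for (rep in 1:20) {
    P <- matrix(runif(64)^2 + 1e-6, 8, 8); P <- P / rowSums(P)
    x <- tpm(P, node_count = 3)
    pi0 <- stationary_distribution(x)
    J <- joint_past_future(x, pi0)
    mi <- temporal_mutual_information(J)
    expect_gte(mi, 0)
    expect_lte(mi, shannon_entropy_vec(rowSums(J$probs)) + 1e-12)
    expect_lte(mi, shannon_entropy_vec(colSums(J$probs)) + 1e-12)

    # lump both axes with a random partition: MI cannot increase
    map <- sample(0:2, 8, replace = TRUE)
    map <- as.integer(factor(map)) - 1L       # make it onto
    Jm <- rowsum(t(rowsum(J$probs, map)), map)
    px <- rowSums(Jm); py <- colSums(Jm)
    nz <- Jm > 0
    mi_macro <- sum(Jm[nz] * log2(Jm[nz] / outer(px, py)[nz]))
    expect_lte(mi_macro, mi + 1e-9)
  }
})

test_that("coarse-graining reduces to identity and trivial limits", {
  set.seed(3)
  P <- matrix(runif(16) + 0.05, 4, 4); P <- P / rowSums(P)
  x <- tpm(P, node_count = 2)

  ident <- state_partition(0:3)
  expect_equal(coarse_grain_tpm(x, ident)$probs, P, tolerance = 1e-12)

  one <- state_partition(rep(0L, 4))
  expect_equal(coarse_grain_tpm(x, one)$probs, matrix(1, 1, 1))

  # macro rows are stochastic under supplied and stationary weights
  part <- state_partition(c(0L, 0L, 1L, 1L), weights = c(.3, .7, .5, .5))
  cg <- coarse_grain_tpm(x, part)
  expect_equal(rowSums(cg$probs), c(1, 1), tolerance = 1e-12)
  expect_error(state_partition(c(0L, 2L)), "onto")
  expect_error(state_partition(c(0L, 1L), weights = c(0.4, 1)), "sum to 1")
})
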