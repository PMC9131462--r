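## classic two-input channels, built as 2-node past (bits A = node 0,
## B = node 1) with a binary future, under maximum-entropy inputs
channel_joint <- function(fn) {
  J <- matrix(0, 4, 2)
  for (x in 0:3) {
    a <- x %% 2; b <- x %/% 2
    J[x + 1, fn(a, b) + 1] <- 1 / 4
  }
  pidscales:::new_joint(J, node_count = 2L)
}
and_joint <- function() channel_joint(function(a, b) a * b)
xor_joint <- function() channel_joint(function(a, b) (a + b) %% 2)

test_that("specific information matches hand enumeration on the AND gate", {
  J <- and_joint()
  # y = 1 pins both inputs to 1: one full bit from either input
  expect_equal(specific_information("{0}", 1, J), 1, tolerance = 1e-12)
  # y = 0: 2/3 log2(4/3) + 1/3 log2(2/3)
  expect_equal(specific_information("{0}", 0, J),
               (2 / 3) * log2(4 / 3) + (1 / 3) * log2(2 / 3),
               tolerance = 1e-12)
  # the full collection resolves y = 1 completely (P(y)=1/4 -> 2 bits)
  expect_equal(specific_information("{01}", 1, J), 2, tolerance = 1e-12)
  expect_error(specific_information("{0}", 5, J), "out of range")
})

test_that("a source independent of the target has zero specific information", {
  set.seed(1)
  # future independent of everything: product distribution
  px <- runif(4); px <- px / sum(px)
  J <- pidscales:::new_joint(outer(px, c(0.3, 0.7)), node_count = 2L)
  for (y in 0:1)
    for (coll in c("{0}", "{1}", "{01}"))
      expect_equal(specific_information(coll, y, J), 0, tolerance = 1e-12)
})

test_that("Williams-Beer redundancy reproduces the classic worked values", {
  # duplicated source: redundancy equals the full mutual information
  J <- matrix(0, 4, 2)
  J[1, 1] <- 0.5; J[4, 2] <- 0.5        # B copies A, Y = A
  Jd <- pidscales:::new_joint(J, node_count = 2L)
  expect_equal(redundancy_iwb("{0}{1}", Jd), 1, tolerance = 1e-12)

  expect_equal(redundancy_iwb("{0}{1}", xor_joint()), 0, tolerance = 1e-12)

  red_and <- 0.25 * 1 + 0.75 * ((2 / 3) * log2(4 / 3) + (1 / 3) * log2(2 / 3))
  expect_equal(redundancy_iwb("{0}{1}", and_joint()), red_and, tolerance = 1e-12)
})

test_that("two-source decompositions recover the textbook XOR and AND atoms", {
  xor <- pid_atoms(xor_joint())
  expect_equal(unname(xor$atoms["{01}"]), 1, tolerance = 1e-9)
  expect_equal(unname(xor$atoms["{0}{1}"]), 0, tolerance = 1e-9)
  expect_equal(unname(xor$atoms["{0}"]), 0, tolerance = 1e-9)
  expect_equal(xor$total_mi, 1, tolerance = 1e-12)

  and <- pid_atoms(and_joint())
  red_and <- 0.25 * 1 + 0.75 * ((2 / 3) * log2(4 / 3) + (1 / 3) * log2(2 / 3))
  i_a <- 1.5 - 0.75 * log2(3)   # I(A;Y) = H(Y) - H(Y|A) for the AND gate
  expect_equal(unname(and$atoms["{0}{1}"]), red_and, tolerance = 1e-9)
  expect_equal(unname(and$atoms["{0}"]), i_a - red_and, tolerance = 1e-9)
  expect_equal(unname(and$atoms["{1}"]), i_a - red_and, tolerance = 1e-9)
  expect_equal(unname(and$atoms["{01}"]),
               and$total_mi - 2 * i_a + red_and, tolerance = 1e-9)
})

test_that("decomposition agrees with the naive reference implementation", {
  set.seed(101)
  worst <- 0
  for (rep in 1:40) {         # two-source systems, mixed future sizes
    J <- random_joint(2, n_future = sample(c(2, 3, 4), 1))
    joint <- pidscales:::new_joint(J, node_count = 2L)
    got <- pid_atoms(joint)$atoms
    want <- oracle_pid(J, 2)
    worst <- max(worst, max(abs(got[names(want)] - want)))
  }
  for (rep in 1:12) {         # three-source systems (18 atoms)
    J <- random_joint(3, n_future = sample(c(2, 4), 1))
    joint <- pidscales:::new_joint(J, node_count = 3L)
    got <- pid_atoms(joint)$atoms
    want <- oracle_pid(J, 3)
    worst <- max(worst, max(abs(got[names(want)] - want)))
  }
  expect_lt(worst, 1e-8)
})

test_that("decomposition invariants hold on random systems", {
  set.seed(55)
  for (rep in 1:15) {
    n <- sample(2:3, 1)
    joint <- pidscales:::new_joint(random_joint(n), node_count = n)
    pid <- pid_atoms(joint)
    L <- enumerate_lattice(n)
    # non-negativity and exact accounting
    expect_true(all(pid$atoms >= -1e-12))
    expect_equal(sum(pid$atoms), pid$total_mi, tolerance = 1e-9)
    # Red(alpha) is the down-set sum of atoms, and is monotone in the order
    for (j in seq_along(L$atoms)) {
      expect_equal(unname(pid$redundancy[j]),
                   sum(pid$atoms[c(L$down_sets[[j]], j)]), tolerance = 1e-9)
      for (i in L$down_sets[[j]])
        expect_lte(pid$redundancy[i], pid$redundancy[j] + 1e-12)
    }
  }
})

test_that("three-source system with a synergistic pair localises its atom", {
  # Y = XOR of nodes 0 and 1; node 2 pure noise
  J <- matrix(0, 8, 2)
  for (x in 0:7) {
    a <- x %% 2; b <- (x %/% 2) %% 2
    J[x + 1, (a + b) %% 2 + 1] <- 1 / 8
  }
  pid <- pid_atoms(pidscales:::new_joint(J, node_count = 3L))
  expect_equal(unname(pid$atoms["{01}"]), 1, tolerance = 1e-9)
  others <- pid$atoms[names(pid$atoms) != "{01}"]
  expect_true(all(abs(others) < 1e-9))
})

test_that("spectrum normalisation and bias limits behave", {
  xor <- pid_atoms(xor_joint())
  spec <- pi_spectrum(xor)
  expect_equal(spec$layer_mass, c(0, 0, 1))
  expect_equal(synergy_bias(spec), 1)
  expect_equal(redundancy_bias(spec), 0)
  expect_equal(sum(spec$layer_mass), 1, tolerance = 1e-9)

  # all mass at the bottom: duplicated source
  J <- matrix(0, 4, 2)
  J[1, 1] <- 0.5; J[4, 2] <- 0.5
  dup <- pid_atoms(pidscales:::new_joint(J, node_count = 2L))
  spec <- pi_spectrum(dup)
  expect_equal(spec$layer_mass, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(synergy_bias(spec), 0, tolerance = 1e-9)
  expect_equal(synergy_bias(spec) + redundancy_bias(spec), 1)

  # zero-MI systems have no spectrum
  px <- rep(0.25, 4)
  indep <- pid_atoms(pidscales:::new_joint(outer(px, c(.5, .5)), node_count = 2L))
  expect_error(pi_spectrum(indep), "zero")
})

test_that("redundancy measures plug in by function", {
  joint <- and_joint()
  base <- pid_atoms(joint)
  custom <- pid_atoms(joint, redundancy = function(masks, j, sources) {
    redundancy_iwb(masks, j, sources)
  })
  expect_equal(custom$atoms, base$atoms, tolerance = 1e-12)
  expect_error(pid_atoms(joint, redundancy = "imin2"), "unknown redundancy")
  expect_error(pid_atoms(pidscales:::new_joint(matrix(0.5, 2, 1), node_count = 1L)),
               "between 2 and 5")
})
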