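test_that("fixpoint counts equal the cycle-multiplicity product", {
  expect_equal(as.numeric(fixpointCount(1:2, c(3L, 3L))), 9)
  # swap on two 3-state bits: brute force over all 9 strings
  expect_equal(as.numeric(fixpointCount(c(2L, 1L), c(3L, 3L))),
               oracle_fixpoints(c(2L, 1L), c(3L, 3L)))
  expect_equal(as.numeric(fixpointCount(c(2L, 1L), c(3L, 3L))), 3)
  # 3-cycle plus a fixed bit: 2 * 5 = 10, confirmed by scanning all 40
  g <- c(2L, 3L, 1L, 4L)
  m <- c(2L, 2L, 2L, 5L)
  expect_equal(as.numeric(fixpointCount(g, m)), 10)
  expect_equal(oracle_fixpoints(g, m), 10)
  expect_error(fixpointCount(c(2L, 1L), c(2L, 3L)), "unequal multiplicity")
})

test_that("Burnside count reproduces the two-symmetric-torsions example", {
  sys_triv <- TabsSystem(c(3L, 3L))
  expect_equal(as.numeric(nTabsBurnside(sys_triv)), 9)
  sys <- fig2_system()
  expect_equal(as.numeric(nTabsBurnside(sys)), 6)
  expect_equal(as.numeric(nTabsNaive(sys)), 6)
  expect_equal(oracle_count_orbits(c(3L, 3L), list(1:2, c(2L, 1L))), 6)
  expect_equal(as.numeric(nTabsBurnside(TabsSystem(integer(0)))), 1)
})

test_that("naive enumeration handles the documented special cases", {
  triv <- TabsSystem(c(2L, 3L, 4L))
  expect_true(nTabsNaive(triv) == cardinality(triv))
  # all 6 permutations of 3 binary bits: multisets of size 3 over 2 values
  s3 <- SymmetryGroup(list(c(2L, 1L, 3L), c(1L, 3L, 2L)), nBits = 3)
  expect_equal(groupOrder(s3), 6)
  sys <- TabsSystem(c(2L, 2L, 2L), s3)
  expect_equal(as.numeric(nTabsNaive(sys)), 4)
  expect_equal(as.numeric(nTabsBurnside(sys)), 4)
  expect_error(nTabsNaive(TabsSystem(rep(10L, 9))), "safety cap")
})

test_that("Burnside equals exhaustive enumeration on random systems", {
  set.seed(202)
  for (rep in 1:60) {
    sys <- randomTabsSystem(nGenerators = sample(0:3, 1))
    expect_true(nTabsBurnside(sys) == nTabsNaive(sys))
  }
  # and against the fully independent oracle on smaller systems
  set.seed(203)
  for (rep in 1:12) {
    sys <- randomTabsSystem(nBitsRange = c(1L, 4L),
                            multiplicityRange = c(1L, 3L),
                            nGenerators = sample(0:2, 1))
    els <- lapply(groupElements(sys), function(p) p@mapping)
    expect_equal(as.numeric(nTabsBurnside(sys)),
                 oracle_count_orbits(multiplicities(sys), els))
  }
})

test_that("Burnside bounds and divisibility hold", {
  set.seed(303)
  for (rep in 1:30) {
    sys <- randomTabsSystem(nGenerators = sample(0:3, 1))
    M <- cardinality(sys)
    nt <- nTabsBurnside(sys)
    expect_true(nt >= tabscount:::biDivModSmall(M, groupOrder(sys))$quotient)
    expect_true(M >= nt)
    # sum of fixpoints divisible by |G| (nTabsBurnside asserts exactness)
    fixsum <- Reduce(tabscount:::biAdd,
                     lapply(groupElements(sys),
                            function(g) fixpointCount(g, multiplicities(sys))),
                     bigInteger(0))
    expect_equal(tabscount:::biDivModSmall(fixsum, groupOrder(sys))$remainder, 0)
  }
})

test_that("stabilizers contain the identity and satisfy orbit-stabilizer", {
  swap <- SymmetryGroup(list(c(2L, 1L)), nBits = 2)
  expect_equal(length(tabsStabilizer(c(2L, 2L), swap)), 2)
  expect_equal(length(tabsStabilizer(c(1L, 2L), swap)), 1)
  triv <- SymmetryGroup(list(), nBits = 2)
  expect_equal(length(tabsStabilizer(c(1L, 2L), triv)), 1)
  set.seed(404)
  for (rep in 1:20) {
    sys <- randomTabsSystem(nBitsRange = c(1L, 5L),
                            nGenerators = sample(0:3, 1))
    s <- vapply(multiplicities(sys), function(mi) sample.int(mi, 1L),
                integer(1))
    expect_equal(nrow(tabsOrbit(s, sys)) * length(tabsStabilizer(s, sys)),
                 groupOrder(sys))
  }
})

test_that("a corrupted non-closed group is caught by the exactness check", {
  # forge a non-closed element set {I, (1 2), (2 3)} past the validators
  bad <- SymmetryGroup(list(), nBits = 3)
  attr(bad, "elements") <- list(1:3, c(2L, 1L, 3L), c(1L, 3L, 2L))
  expect_error(validObject(bad), "not closed")
  sys <- TabsSystem(c(2L, 2L, 2L))
  attr(sys, "group") <- bad
  expect_error(nTabsBurnside(sys), "not divisible|corrupted")
})
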