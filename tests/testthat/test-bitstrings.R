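test_that("cardinality is the exact product of multiplicities", {
  expect_equal(as.numeric(cardinality(TabsSystem(c(3, 3)))), 9)
  expect_equal(as.numeric(cardinality(TabsSystem(integer(0)))), 1)
  expect_equal(as.numeric(cardinality(TabsSystem(c(2, 3, 4)))), 24)
  # arbitrary precision: 6^30 exceeds 2^53
  big <- TabsSystem(rep(6L, 30))
  expect_identical(as.character(cardinality(big)), "221073919720733357899776")
})

test_that("enumeration yields S exactly once, lexicographically", {
  e1 <- enumerateRawTabs(TabsSystem(2L))
  expect_identical(e1, matrix(c(1L, 2L), ncol = 1))
  e2 <- enumerateRawTabs(fig2_system())
  expect_equal(nrow(e2), 9)
  expect_identical(e2[1, ], c(1L, 1L))
  expect_identical(e2[9, ], c(3L, 3L))
  expect_identical(e2, oracle_enumerate(c(3L, 3L)))
  e3 <- enumerateRawTabs(TabsSystem(c(2L, 3L)))
  expect_identical(e3, oracle_enumerate(c(2L, 3L)))
  expect_equal(anyDuplicated(apply(e3, 1, paste, collapse = "-")), 0L)
  expect_error(enumerateRawTabs(TabsSystem(rep(10L, 9)), cap = 1e7),
               "exceeds the safety cap")
})

test_that("the group action follows the stated left-action convention", {
  expect_identical(applyPermutation(c(2L, 1L), c(2L, 1L)), c(1L, 2L))
  expect_identical(applyPermutation(c(1L, 1L), c(2L, 1L)), c(1L, 1L))
  expect_identical(applyPermutation(c(1L, 2L, 3L), c(2L, 3L, 1L)),
                   c(3L, 1L, 2L))
  expect_identical(applyPermutation(c(5L, 7L, 9L), 1:3), c(5L, 7L, 9L))
  expect_error(applyPermutation(c(1L, 2L), c(2L, 3L, 1L)), "dimensions")
})

test_that("canonicalization picks the lexicographic orbit minimum", {
  swap <- SymmetryGroup(list(c(2L, 1L)), nBits = 2)
  expect_identical(canonicalTabs(c(2L, 1L), swap), c(1L, 2L))
  expect_identical(canonicalTabs(c(1L, 1L), swap), c(1L, 1L))
  cyc <- SymmetryGroup(list(c(2L, 3L, 1L)), nBits = 3)
  expect_identical(canonicalTabs(c(3L, 1L, 2L), cyc), c(1L, 2L, 3L))
  # idempotence
  expect_identical(canonicalTabs(canonicalTabs(c(3L, 1L, 2L), cyc), cyc),
                   canonicalTabs(c(3L, 1L, 2L), cyc))
})

test_that("orbits match the definition and divide the group order", {
  swap <- SymmetryGroup(list(c(2L, 1L)), nBits = 2)
  o <- tabsOrbit(c(1L, 2L), swap)
  expect_identical(o, matrix(c(1L, 2L, 2L, 1L), 2, byrow = TRUE))
  expect_identical(tabsOrbit(c(2L, 2L), swap), matrix(c(2L, 2L), 1))
  triv <- SymmetryGroup(list(), nBits = 3)
  expect_identical(tabsOrbit(c(3L, 1L, 2L), triv), matrix(c(3L, 1L, 2L), 1))
})

test_that("canonicalTabs is a class function and counts orbits", {
  set.seed(101)
  for (rep in 1:25) {
    sys <- randomTabsSystem(nBitsRange = c(1L, 4L),
                            multiplicityRange = c(1L, 3L),
                            nGenerators = sample(0:3, 1))
    g_els <- lapply(groupElements(sys), function(p) p@mapping)
    m <- multiplicities(sys)
    s <- vapply(m, function(mi) sample.int(mi, 1L), integer(1))
    g <- g_els[[sample.int(length(g_els), 1L)]]
    expect_identical(canonicalTabs(applyPermutation(s, g), sys),
                     canonicalTabs(s, sys))
    # canonical form agrees with the independent oracle
    expect_identical(canonicalTabs(s, sys), oracle_canonical(s, g_els))
    # distinct canonical forms over S == Burnside count (small M only)
    if (as.numeric(cardinality(sys)) <= 200) {
      S <- enumerateRawTabs(sys)
      canon <- unique(apply(S, 1, function(r) {
        formatTabs(canonicalTabs(as.integer(r), sys))
      }))
      expect_equal(length(canon), as.numeric(nTabsBurnside(sys)))
    }
  }
})

test_that("serialization round-trips 1-based hyphen strings", {
  expect_identical(formatTabs(c(1L, 3L, 2L)), "1-3-2")
  expect_identical(parseTabs("1-3-2"), c(1L, 3L, 2L))
  expect_identical(parseTabs(formatTabs(integer(0))), integer(0))
})
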