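test_that("shipped library loads, validates, and covers the full circle", {
  lib <- defaultTorsionLibrary()
  expect_s4_class(lib, "TorsionLibrary")
  expect_gte(length(lib@patterns), 5)
  expect_equal(lib@patterns[[length(lib@patterns)]]@id, "generic")
  for (p in lib@patterns) {
    bnd <- p@boundaries
    expect_false(is.unsorted(bnd, strictly = TRUE))
    # bin arc lengths tile the folded circle exactly, hence (copied
    # 360/period times) the full 360 degrees
    arcs <- if (length(bnd) == 1L) p@period else
      c(diff(bnd), p@period - diff(range(bnd)))
    expect_equal(sum(arcs) * 360 / p@period, 360)
    expect_equal(patternMultiplicity(p), length(bnd))
  }
})

test_that("rotatability follows the non-ring / heavy-neighbor rule", {
  expect_equal(nBits(findRotatableTorsions(parseSmiles("CC"))), 0)
  bits <- findRotatableTorsions(parseSmiles("CCCC"))
  expect_equal(nBits(bits), 1)
  expect_setequal(as.vector(bits@bonds[1, ]), c(2L, 3L))
  expect_equal(nBits(findRotatableTorsions(parseSmiles("c1ccccc1"))), 0)
  # propane: central atom flanked by terminal methyls only
  expect_equal(nBits(findRotatableTorsions(parseSmiles("CCC"))), 0)
})

test_that("pattern matching picks the most specific pattern first", {
  lib <- defaultTorsionLibrary()
  but <- parseSmiles("CCCC")
  p <- matchPattern(but, c(2L, 3L), lib)
  expect_equal(p@id, "sp3-sp3")
  expect_equal(patternMultiplicity(p), 3)
  biphenyl <- parseSmiles("c1ccccc1-c2ccccc2")
  bits <- findRotatableTorsions(biphenyl, lib)
  expect_equal(nBits(bits), 1)
  expect_equal(bits@patternId, "aromatic-aromatic")
  amide <- parseSmiles("CC(=O)NC")  # N-methylacetamide
  bits <- findRotatableTorsions(amide, lib)
  expect_true("amide" %in% bits@patternId)
  # a single catch-all library matches anything rotatable
  onlygen <- new("TorsionLibrary",
                 patterns = lib@patterns[length(lib@patterns)])
  expect_equal(matchPattern(but, c(2L, 3L), onlygen)@id, "generic")
  # removing the fallback can leave bonds unmatched
  nofall <- new("TorsionLibrary", patterns = lib@patterns[1])
  expect_error(matchPattern(but, c(2L, 3L), nofall), "no pattern matches")
})

test_that("bin assignment is total, surjective and boundary-deterministic", {
  b3 <- c(-120, 0, 120)
  expect_equal(assignBin(60, b3), 2)
  expect_equal(assignBin(180, b3), 3)   # wrap bin holds 180
  expect_equal(assignBin(-120, b3), 3)  # half-open: boundary belongs below
  expect_equal(assignBin(0, b3), 1)
  expect_equal(assignBin(120, b3), 2)
  expect_equal(assignBin(33, 170), 1)   # 1-bin pattern is constant
  expect_error(assignBin(200, b3), "not normalized")
  expect_error(assignBin(-180, b3), "not normalized")
  # surjectivity of every shipped pattern over a fine angle sweep
  angles <- seq(-179.9, 180, by = 0.1)
  for (p in defaultTorsionLibrary()@patterns) {
    bins <- vapply(angles, assignBin, numeric(1), pattern = p)
    expect_setequal(unique(bins), seq_len(patternMultiplicity(p)))
  }
})

test_that("bit layout is invariant under atom relabeling", {
  mol <- parseSmiles("CC(=O)Oc1ccccc1C(=O)O", name = "aspirin")
  bits <- findRotatableTorsions(mol)
  set.seed(5)
  for (rep in 1:5) {
    sigma <- sample(nrow(mol@atoms))
    mol2 <- relabel_molecule(mol, sigma)
    bits2 <- findRotatableTorsions(mol2)
    expect_equal(nBits(bits2), nBits(bits))
    expect_identical(sort(bits2@patternId), sort(bits@patternId))
    expect_identical(bits2@multiplicity, bits@multiplicity)
    # bonds correspond through sigma, in the same canonical order
    mapped <- matrix(sigma[bits@bonds], ncol = 2)
    key <- function(b) paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    expect_identical(key(bits2@bonds), key(mapped))
  }
})

test_that("user libraries are read from JSON with validation", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"id":"twofold","priority":1,
    "atoms":[{"elem":"*"},{"elem":"*"},{"elem":"*"},{"elem":"*"}],
    "boundaries":[-90, 90]}]', path)
  lib <- readTorsionLibrary(path)
  expect_equal(length(lib@patterns), 1)
  expect_equal(patternMultiplicity(lib@patterns[[1]]), 2)
  bits <- findRotatableTorsions(parseSmiles("CCCC"), lib)
  expect_equal(bits@multiplicity, 2L)
  writeLines('[{"id":"bad","atoms":[{},{}],"boundaries":[0]}]', path)
  expect_error(readTorsionLibrary(path), "4 atoms")
})
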