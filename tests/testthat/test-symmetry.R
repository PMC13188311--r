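test_that("automorphism counts match exhaustive expectations", {
  expect_length(atomAutomorphisms(parseSmiles("CCCC")), 2)   # path flip
  expect_length(atomAutomorphisms(parseSmiles("c1ccccc1")), 12)  # dihedral D6
  expect_length(atomAutomorphisms(parseSmiles("CCO")), 1)    # distinct labels
  expect_length(atomAutomorphisms(parseSmiles("c1ccccc1CCc2ccccc2")), 8)
  expect_length(atomAutomorphisms(parseSmiles("CC(=O)Oc1ccccc1C(=O)O")), 1)
  # neopentane heavy graph: S4 on the four methyls
  expect_length(atomAutomorphisms(parseSmiles("CC(C)(C)C")), 24)
})

test_that("automorphism counts agree with the igraph oracle", {
  for (smi in c("CCCC", "c1ccccc1", "c1ccccc1CCc2ccccc2", "CC(C)(C)C",
                "C1CCC2CCCCC2C1")) {
    mol <- parseSmiles(smi)
    # igraph color automorphisms; encode bond labels by edge subdivision:
    # insert a colored pseudo-vertex on every edge
    nb <- nrow(mol@bonds); na <- nrow(mol@atoms)
    akey <- paste(mol@atoms$element, mol@atoms$aromatic, mol@atoms$charge,
                  mol@atoms$nH)
    bkey <- paste("bond", mol@bonds$order, mol@bonds$aromatic)
    colors <- as.integer(factor(c(akey, bkey)))
    edges <- rbind(cbind(mol@bonds$from, na + seq_len(nb)),
                   cbind(mol@bonds$to, na + seq_len(nb)))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    cnt <- igraph::count_automorphisms(g, colors = colors)$group_size
    expect_equal(length(atomAutomorphisms(mol)), as.numeric(cnt),
                 info = smi)
  }
})

test_that("every automorphism preserves atom types and bond labels", {
  mol <- parseSmiles("c1ccccc1CCc2ccccc2")
  bm <- tabscount:::.bond_map(mol)
  for (g in atomAutomorphisms(mol)) {
    expect_identical(mol@atoms$element[g], mol@atoms$element)
    for (k in seq_len(nrow(mol@bonds))) {
      from <- g[mol@bonds$from[k]]; to <- g[mol@bonds$to[k]]
      key <- paste(min(from, to), max(from, to), sep = ":")
      orig <- paste(mol@bonds$from[k], mol@bonds$to[k], sep = ":")
      expect_identical(bm[[key]], bm[[orig]])
    }
  }
})

test_that("projection to bits is the induced bond permutation", {
  mol <- parseSmiles("CCCC")
  bits <- findRotatableTorsions(mol)
  auts <- atomAutomorphisms(mol)
  for (g in auts) {
    # single central bond always maps to itself
    expect_identical(projectToBits(g, bits)@mapping, 1L)
  }
  dpe <- parseSmiles("c1ccccc1CCc2ccccc2")
  dbits <- findRotatableTorsions(dpe)
  projected <- lapply(atomAutomorphisms(dpe),
                      function(g) projectToBits(g, dbits)@mapping)
  keys <- vapply(projected, paste, character(1), collapse = ",")
  # 8 atom automorphisms collapse onto exactly 2 bit permutations,
  # one of which transposes the two phenyl-CH2 bits
  expect_equal(length(unique(keys)), 2)
  expect_true(any(vapply(projected, function(p) any(p != seq_along(p)),
                         logical(1))))
})

test_that("projection is a group homomorphism", {
  dpe <- parseSmiles("c1ccccc1CCc2ccccc2")
  bits <- findRotatableTorsions(dpe)
  auts <- atomAutomorphisms(dpe)
  set.seed(8)
  for (rep in 1:10) {
    g <- auts[[sample.int(length(auts), 1)]]
    h <- auts[[sample.int(length(auts), 1)]]
    gh <- g[h]  # composition of atom permutations
    lhs <- projectToBits(gh, bits)@mapping
    rhs <- composePermutations(projectToBits(g, bits),
                               projectToBits(h, bits))@mapping
    expect_identical(lhs, rhs)
  }
})

test_that("the image group is deduplicated, closed, with identity", {
  for (fx in moleculeFixtures()) {
    mol <- parseSmiles(fx$smiles)
    bits <- findRotatableTorsions(mol)
    grp <- buildBitGroup(mol, bits)
    expect_equal(groupOrder(grp), fx$bitGroupOrder)
    expect_true(validObject(grp))  # validity re-checks closure + identity
  }
  # symmetry among non-torsion atoms only: para-xylene's two methyls are
  # equivalent but neither C-CH3 bond is a torsion bit, and the single
  # non-trivial... (both exocyclic bonds are non-rotatable: methyl side)
  px <- parseSmiles("Cc1ccc(C)cc1")
  expect_gt(length(atomAutomorphisms(px)), 1)
  bits <- findRotatableTorsions(px)
  expect_equal(nBits(bits), 0)
  expect_equal(groupOrder(buildBitGroup(px, bits)), 1)
})

test_that("an oversized automorphism group is a hard error", {
  # C60-like blowup is unnecessary: use a tiny cap instead
  expect_error(atomAutomorphisms(parseSmiles("c1ccccc1"), maxOrder = 5),
               "exceeds maxOrder")
})
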