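test_that("SMILES parsing yields correct heavy-atom graphs", {
  benzene <- parse_smiles("c1ccccc1")
  expect_equal(nrow(benzene$atoms), 6)
  expect_equal(nrow(benzene$bonds), 6)
  expect_true(all(benzene$bonds$aromatic))

  heptanol <- parse_smiles("CCCCCCCO")
  expect_equal(nrow(heptanol$atoms), 8)
  expect_equal(nrow(heptanol$bonds), 7)
  expect_equal(count_element(heptanol, "O"), 1)

  gallic <- parse_smiles("OC(=O)c1cc(O)c(O)c(O)c1")
  expect_equal(count_element(gallic, "O"), 5)
  syringic <- parse_smiles("COc1cc(C(=O)O)cc(OC)c1O")
  expect_equal(count_element(syringic, "O"), 5)
  expect_equal(count_element(benzene, "O"), 0)

  expect_error(parse_smiles("not(a(smiles"), "parse failure")
})

test_that("topological distances match a Floyd-Warshall oracle", {
  mols <- list(chain8 = parse_smiles("CCCCCCCO"),
               benzene = parse_smiles("c1ccccc1"),
               menthol = parse_smiles("CC(C)C1CCC(C)CC1O"),
               camphor = parse_smiles("CC1(C)C2CCC1(C)C(=O)C2"))
  for (g in mols) {
    expect_equal(distance_matrix(g), fw_distances(g),
                 ignore_attr = TRUE, tolerance = 0)
  }
  expect_equal(max(distance_matrix(mols$chain8)), 7)
  expect_equal(max(distance_matrix(mols$benzene)), 3)

  disconnected <- molecular_graph(c("C", "C", "C"),
                                  data.frame(i = 1, j = 2, order = 1))
  expect_error(distance_matrix(disconnected), "disconnected")
})

test_that("ring counting enumerates the full cycle space", {
  eucalyptol <- parse_smiles("CC12CCC(CC1)C(C)(C)O2")
  # bicyclo[2.2.2] core: three distinct 6-cycles, not the 2 of a ring basis
  expect_equal(rings_of_size(eucalyptol, 6), 3)
  naphthalene <- parse_smiles("c1ccc2ccccc2c1")
  expect_equal(rings_of_size(naphthalene, 6), 2)
  expect_equal(rings_of_size(naphthalene, 10), 1)
  expect_equal(rings_of_size(parse_smiles("CCCCCCCO"), 6), 0)

  # total simple-cycle count agrees with the independent ChemmineR
  # enumeration for small ring systems
  for (smi in c("CC12CCC(CC1)C(C)(C)O2", "CC1(C)C2CCC1(C)C(=O)C2",
                "c1ccc2ccccc2c1", "C1CC1", "C1CCC2(CC1)CCCC2")) {
    n_own <- length(cdbind:::enumerate_simple_cycles(parse_smiles(smi)))
    sdf <- ChemmineR::smiles2sdf(smi)[[1]]
    n_ref <- length(ChemmineR::rings(sdf, type = "all", arom = FALSE))
    expect_equal(n_own, n_ref, info = smi)
  }
})

test_that("3D embedding is deterministic and geometrically sane", {
  benzene <- parse_smiles("c1ccccc1")
  c1 <- embed_3d(benzene, seed = 1)
  c2 <- embed_3d(benzene, seed = 1)
  expect_identical(c1$xyz, c2$xyz)

  # aromatic planarity: smallest principal extent below 0.1 A
  M <- scale(c1$xyz, scale = FALSE)
  expect_lt(svd(M)$d[3], 0.1)

  menthol <- parse_smiles("CC(C)C1CCC(C)CC1O")
  conf <- embed_3d(menthol, seed = 1)
  blen <- sqrt(rowSums((conf$xyz[menthol$bonds$i, ] -
                          conf$xyz[menthol$bonds$j, ])^2))
  expect_true(all(blen > 1.2 & blen < 1.7))

  expect_false(identical(embed_3d(menthol, seed = 2)$xyz, conf$xyz))
})

test_that("all 20 packaged ligands parse, are connected, and embed", {
  lig <- cd_ligands(parse = TRUE)
  expect_equal(nrow(lig), 20)
  for (k in seq_len(20)) {
    g <- lig$graph[[k]]
    expect_true(cdbind:::is_connected_graph(g), info = lig$name[k])
    conf <- embed_3d(g, seed = 1)
    expect_true(all(is.finite(conf$xyz)), info = lig$name[k])
    expect_equal(nrow(conf$xyz), nrow(g$atoms))
  }
})

test_that("explicit-hydrogen graphs extend the heavy graph consistently", {
  ethanol <- parse_smiles("CCO")
  expect_equal(count_element(ethanol, "H"), 6)
  gh <- add_hydrogens(ethanol)
  expect_equal(nrow(gh$atoms), 9)
  expect_equal(nrow(gh$bonds), 8)
  expect_equal(count_element(gh, "H"), 6)
  expect_true(cdbind:::is_connected_graph(gh))
})
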