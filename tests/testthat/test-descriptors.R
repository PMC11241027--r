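test_that("Broto-Moreau autocorrelation matches pair enumeration", {
  chain8 <- carbon_chain(8)
  expect_equal(ats_autocorrelation(chain8, 4, "unit", log_form = FALSE), 4)
  expect_equal(ats_autocorrelation(chain8, 4, "unit"), log(5))

  benzene <- parse_smiles("c1ccccc1")
  expect_equal(ats_autocorrelation(benzene, 4, "mass"), 0)
  expect_equal(ats_autocorrelation(benzene, 1, "unit"), log(7))

  # brute-force oracle over an exhaustive double loop, mass weights
  for (smi in c("CC(C)C1CCC(C)CC1O", "OC(=O)c1cc(O)c(O)c(O)c1")) {
    g <- parse_smiles(smi)
    D <- fw_distances(g)
    w <- g$atoms$mass / 12.011
    for (lag in 1:5) {
      raw <- 0
      for (i in seq_len(nrow(D) - 1)) for (j in (i + 1):nrow(D)) {
        if (D[i, j] == lag) raw <- raw + w[i] * w[j]
      }
      expect_equal(ats_autocorrelation(g, lag, "mass"), log1p(raw),
                   tolerance = 1e-12)
    }
  }
})

test_that("Burden eigenvalues match an independently constructed matrix", {
  two <- carbon_chain(2)
  expect_error(burden_eigenvalue(two, 3), "exceeds atom count")

  benzene <- parse_smiles("c1ccccc1")
  B <- matrix(0.001, 6, 6)
  for (e in 1:6) {
    i <- e; j <- if (e == 6) 1 else e + 1
    B[i, j] <- B[j, i] <- 0.15  # aromatic bond, no terminal augmentation
  }
  diag(B) <- 1
  ev <- sort(eigen(B, symmetric = TRUE)$values)
  expect_equal(burden_eigenvalue(benzene, 1, "lowest", "unit"), ev[1],
               tolerance = 1e-10)
  expect_equal(burden_eigenvalue(benzene, 3, "lowest", "unit"), ev[3],
               tolerance = 1e-10)

  # trace identity: full spectrum sums to the diagonal
  for (smi in c("CCO", "CC(C)C1CCC(C)CC1O")) {
    g <- parse_smiles(smi)
    Bm <- cdbind:::burden_matrix(g, "electronegativity")
    ev_all <- eigen(Bm, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev_all), sum(diag(Bm)), tolerance = 1e-9)
  }
})

test_that("Kier alpha-modified 3-path shape index follows the closed form", {
  expect_equal(kier_shape_3(carbon_chain(5)), 4.0)
  expect_equal(kier_shape_3(carbon_chain(7)), 6.0)
  expect_error(kier_shape_3(carbon_chain(3)), "at least 4")

  # aromatic molecules score below same-size aliphatic chains
  expect_lt(kier_shape_3(parse_smiles("c1ccccc1")),
            kier_shape_3(carbon_chain(6)))
  expect_lt(kier_shape_3(parse_smiles("OC(=O)c1cc(O)c(O)c(O)c1")),
            kier_shape_3(carbon_chain(12)))
})

test_that("edge-adjacency eigenvalues match a dense eigensolver oracle", {
  expect_error(edge_adjacency_eigenvalue(carbon_chain(2), 3),
               "exceeds edge count")

  benzene <- parse_smiles("c1ccccc1")
  E <- matrix(0, 6, 6)
  bonds <- benzene$bonds
  for (f in 1:5) for (h in (f + 1):6) {
    if (length(intersect(c(bonds$i[f], bonds$j[f]),
                         c(bonds$i[h], bonds$j[h])))) {
      E[f, h] <- E[h, f] <- 1.5  # aromatic-aromatic contact
    }
  }
  ev <- sort(eigen(E, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(edge_adjacency_eigenvalue(benzene, 1), ev[1], tolerance = 1e-10)
  expect_equal(edge_adjacency_eigenvalue(benzene, 3), ev[3], tolerance = 1e-10)

  # higher branching raises the spectrum on matched-size graphs
  star <- parse_smiles("CC(C)(C)CC")     # neopentane-like, branched
  chain <- carbon_chain(6)
  expect_gt(edge_adjacency_eigenvalue(star, 1),
            edge_adjacency_eigenvalue(chain, 1))
})

test_that("GETAWAY influence matrix satisfies its rank identities", {
  # non-planar toy tetrahedron: trace = 3, so unit-weight lag 0 sums to 3
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  g4 <- molecular_graph(rep("C", 4),
                        data.frame(i = c(1, 1, 1), j = 2:4, order = 1))
  conf <- toy_conformer(xyz)
  expect_equal(getaway_h_autocorrelation(g4, conf, 0, "unit"), 3,
               tolerance = 1e-9)

  # planar molecule: rank-2 projector, trace 2
  benzene <- parse_smiles("c1ccccc1")
  cb <- embed_3d(benzene, seed = 1)
  expect_equal(sum(diag(cdbind:::influence_matrix(cb))), 2, tolerance = 1e-6)

  # linear geometry: rank 1
  xyz_lin <- cbind(0:2, 0, 0)
  g3 <- carbon_chain(3)
  expect_equal(sum(diag(cdbind:::influence_matrix(toy_conformer(xyz_lin)))),
               1, tolerance = 1e-9)

  # degenerate: all atoms coincide
  expect_error(cdbind:::influence_matrix(toy_conformer(matrix(1, 3, 3))),
               "rank 0")
})

test_that("Geary autocorrelation follows its formula and conventions", {
  heptanol <- parse_smiles("CCCCCCCO")
  expect_equal(geary_autocorrelation(heptanol, 8, "electronegativity"), 0)
  expect_equal(geary_autocorrelation(carbon_chain(6), 3, "mass"), 0)

  # 10-atom chain with alternating C/N atoms: hand-evaluate the ratio of the
  # lag-1 squared-difference term to the weight variance term
  gNC <- molecular_graph(rep(c("C", "N"), 5),
                         data.frame(i = 1:9, j = 2:10, order = 1))
  w <- gNC$atoms$sanderson / 2.746
  num <- sum((w[1:9] - w[2:10])^2) / (2 * 9)
  den <- sum((w - mean(w))^2) / 9
  expect_equal(geary_autocorrelation(gNC, 1, "electronegativity"),
               num / den, tolerance = 1e-12)
})

test_that("3D-MoRSE signals reduce to their sinc limits and brute force", {
  benzene <- parse_smiles("c1ccccc1")
  conf <- embed_3d(benzene, seed = 1)
  expect_equal(morse_signal(conf, 1), 15)  # 6*5/2 at s = 0

  diatomic <- toy_conformer(rbind(c(0, 0, 0), c(pi / 9, 0, 0)))
  expect_equal(morse_signal(diatomic, 10), 0, tolerance = 1e-12)

  # brute-force double loop over the 15 benzene pairs at signal 10
  R <- as.matrix(dist(conf$xyz))
  acc <- 0
  for (i in 1:5) for (j in (i + 1):6) acc <- acc + sin(9 * R[i, j]) / (9 * R[i, j])
  expect_equal(morse_signal(conf, 10), acc, tolerance = 1e-12)
})

test_that("TPSA sums Ertl fragment contributions over N/O fragments", {
  expect_equal(tpsa(parse_smiles("C=Cc1ccccc1")), 0)   # styrene
  expect_equal(tpsa(parse_smiles("c1ccccc1")), 0)
  # gallic acid: 3 phenol OH + carboxylic acid (=O + OH)
  expect_equal(tpsa(parse_smiles("OC(=O)c1cc(O)c(O)c(O)c1")),
               3 * 20.23 + 17.07 + 20.23, tolerance = 1e-9)
  # ether + carbonyl (ester): isoamyl acetate
  expect_equal(tpsa(parse_smiles("CC(C)CCOC(C)=O")), 9.23 + 17.07,
               tolerance = 1e-9)
  # aniline NH2 and pyridine n
  expect_equal(tpsa(parse_smiles("Nc1ccccc1")), 26.02, tolerance = 1e-9)
  expect_equal(tpsa(parse_smiles("c1ccncc1")), 12.89, tolerance = 1e-9)
})

test_that("descriptors are invariant under atom reindexing", {
  set.seed(42)
  for (smi in c("CC(C)C1CCC(C)CC1O", "OC(=O)C=Cc1ccc(O)c(O)c1",
                "CC12CCC(CC1)C(C)(C)O2")) {
    g <- parse_smiles(smi)
    n <- nrow(g$atoms)
    conf <- embed_3d(g, seed = 1)
    for (rep_ in 1:3) {
      perm <- sample(n)
      gp <- permute_graph(g, perm)
      confp <- toy_conformer(conf$xyz[perm, , drop = FALSE])
      expect_equal(rings_of_size(gp, 6), rings_of_size(g, 6))
      expect_equal(ats_autocorrelation(gp, 4, "mass"),
                   ats_autocorrelation(g, 4, "mass"), tolerance = 1e-10)
      expect_equal(burden_eigenvalue(gp, 3, "lowest", "electronegativity"),
                   burden_eigenvalue(g, 3, "lowest", "electronegativity"),
                   tolerance = 1e-10)
      expect_equal(kier_shape_3(gp), kier_shape_3(g), tolerance = 1e-10)
      expect_equal(edge_adjacency_eigenvalue(gp, 3),
                   edge_adjacency_eigenvalue(g, 3), tolerance = 1e-10)
      expect_equal(geary_autocorrelation(gp, 8, "electronegativity"),
                   geary_autocorrelation(g, 8, "electronegativity"),
                   tolerance = 1e-10)
      expect_equal(tpsa(gp), tpsa(g), tolerance = 1e-10)
      expect_equal(
        getaway_h_autocorrelation(gp, confp, 0, "electronegativity"),
        getaway_h_autocorrelation(g, conf, 0, "electronegativity"),
        tolerance = 1e-10)
      expect_equal(morse_signal(confp, 10), morse_signal(conf, 10),
                   tolerance = 1e-10)
    }
  }
})

test_that("descriptor matrices are complete, ordered, and normalizable", {
  smis <- c(benzene = "c1ccccc1", menthol = "CC(C)C1CCC(C)CC1O",
            gallic = "OC(=O)c1cc(O)c(O)c(O)c1",
            pinellic = "CCCCCC(O)C(O)C=CC(O)CCCCCCCC(=O)O",
            sinapic = "COc1cc(C=CC(=O)O)cc(OC)c1O",
            ferulic = "COc1cc(C=CC(=O)O)ccc1O")
  m <- compute_descriptor_matrix(smis, seed = 1)
  expect_equal(dim(m$values), c(6, 9))
  expect_false(anyNA(m$values))
  expect_equal(colnames(m$values),
               c("nR06", "ATS4m", "BEle3", "S3K", "EEig03r", "H0e",
                 "GATS8e", "Mor10u", "TPSA"))
  expect_equal(m$values["benzene", "nR06"], 1)
  expect_equal(m$values["benzene", "TPSA"], 0)

  z <- normalize_descriptors(m)
  expect_true(all(abs(colMeans(z$values)) < 1e-9))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-9))

  # round trip
  back <- denormalize_descriptors(z)
  expect_equal(back$values, m$values, tolerance = 1e-9)

  # training-reference normalization leaves non-reference rows off-center
  ref_ids <- c("benzene", "gallic", "pinellic", "sinapic")
  z2 <- normalize_descriptors(m, reference = ref_ids)
  ref <- z2$values[ref_ids, ]
  expect_true(all(abs(colMeans(ref)) < 1e-9))
  expect_true(all(abs(apply(ref, 2, sd) - 1) < 1e-9))

  # constant column on the reference subset errors by name
  m_const <- m
  m_const$values[, "nR06"] <- 2
  expect_error(normalize_descriptors(m_const), "nR06")
})
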