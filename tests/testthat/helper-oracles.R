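# Independent oracles and small fixtures shared across test files.

# Floyd-Warshall all-pairs shortest paths, independent of the BFS
# implementation under test.
fw_distances <- function(g) {
  n <- nrow(g$atoms)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (b in seq_len(nrow(g$bonds))) {
    D[g$bonds$i[b], g$bonds$j[b]] <- 1
    D[g$bonds$j[b], g$bonds$i[b]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# permute atom order of a molecular graph (descriptors must be invariant)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  bonds <- g$bonds
  bonds$i <- inv[g$bonds$i]
  bonds$j <- inv[g$bonds$j]
  molecular_graph(g$atoms$symbol[perm], bonds,
                  hydrogen_mode = g$hydrogen_mode,
                  implicit_h = g$atoms$implicit_h[perm])
}

# a path graph of n carbons without going through SMILES parsing
carbon_chain <- function(n) {
  molecular_graph(rep("C", n),
                  data.frame(i = seq_len(n - 1), j = 2:n, order = 1,
                             aromatic = FALSE))
}

fixture_smiles <- function() {
  path <- system.file("extdata", "cd_ligands.smi", package = "cdbind")
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(raw[[1]], raw[[2]])
}

# hand-built conformer for toy-geometry tests
toy_conformer <- function(xyz, seed = 0L) {
  structure(list(xyz = xyz, seed = as.integer(seed)), class = "conformer3d")
}

# share one fixture-pipeline run across test files (it is deterministic)
.pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(response = "LogBSA", seed = 1L) {
  key <- paste(response, seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_pipeline(response, seed = seed)
  }
  .pipeline_cache[[key]]
}
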