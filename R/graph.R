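# Molecular graph construction and topological utilities.
#
# A molecular_graph is the substrate for every 2D descriptor: a labeled
# undirected graph over heavy atoms (optionally with explicit hydrogens),
# carrying per-atom mass, Sanderson electronegativity and covalent radius,
# and per-bond order with an aromaticity flag.

#' Construct a molecular graph
#'
#' Low-level constructor; most users will call [parse_smiles()] instead.
#'
#' @param symbols character vector of element symbols
#' @param bonds data frame with integer columns `i`, `j`, numeric `order`
#'   (1, 2, 3) and logical `aromatic`
#' @param hydrogen_mode `"heavy"` (hydrogen-depleted) or `"explicit-h"`
#' @param implicit_h integer vector of implicit hydrogen counts (heavy mode)
#' @return object of class `molecular_graph`
#' @export
molecular_graph <- function(symbols, bonds, hydrogen_mode = "heavy",
                            implicit_h = NULL) {
  stopifnot(is.character(symbols), length(symbols) >= 1)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    if (any(bonds$i < 1 | bonds$i > length(symbols) |
            bonds$j < 1 | bonds$j > length(symbols))) {
      stop("bond indices out of range")
    }
    if (any(bonds$i == bonds$j)) stop("self-bond not allowed")
  } else {
    bonds <- data.frame(i = integer(), j = integer(),
                        order = numeric(), aromatic = logical())
  }
  el <- .element_row(symbols)
  atoms <- data.frame(
    symbol = symbols,
    mass = el$mass,
    sanderson = el$sanderson,
    radius = el$radius,
    stringsAsFactors = FALSE
  )
  if (is.null(implicit_h)) implicit_h <- rep(0L, length(symbols))
  atoms$implicit_h <- as.integer(implicit_h)
  g <- structure(
    list(atoms = atoms, bonds = bonds, hydrogen_mode = hydrogen_mode),
    class = "molecular_graph"
  )
  g$atoms$aromatic <- .aromatic_atoms(g)
  g$atoms$hyb <- .hybridization(g)
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph: %d atoms (%s), %d bonds>\n",
              nrow(x$atoms), x$hydrogen_mode, nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

adjacency_list <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

adjacency_matrix <- function(g) {
  n <- n_atoms(g)
  A <- matrix(0L, n, n)
  if (nrow(g$bonds)) {
    A[cbind(g$bonds$i, g$bonds$j)] <- 1L
    A[cbind(g$bonds$j, g$bonds$i)] <- 1L
  }
  A
}

.aromatic_atoms <- function(g) {
  ar <- rep(FALSE, n_atoms(g))
  if (nrow(g$bonds)) {
    ab <- g$bonds[g$bonds$aromatic, , drop = FALSE]
    ar[unique(c(ab$i, ab$j))] <- TRUE
  }
  ar
}

# sp if any triple bond (or two cumulated doubles); sp2 if any double or
# aromatic bond; else sp3.
.hybridization <- function(g) {
  n <- n_atoms(g)
  hyb <- rep("sp3", n)
  if (nrow(g$bonds) == 0) return(hyb)
  for (a in seq_len(n)) {
    rows <- g$bonds$i == a | g$bonds$j == a
    ords <- g$bonds$order[rows]
    arom <- g$bonds$aromatic[rows]
    if (any(ords == 3) || sum(ords == 2) >= 2) hyb[a] <- "sp"
    else if (any(ords == 2) || any(arom)) hyb[a] <- "sp2"
  }
  hyb
}

# conventional bond order: aromatic bonds count 1.5 regardless of the
# kekulized order stored in `order`.
conventional_order <- function(g) {
  ifelse(g$bonds$aromatic, 1.5, g$bonds$order)
}

#' Parse a SMILES string into a molecular graph
#'
#' Parsing, kekulization and aromatic-ring perception are delegated to
#' ChemmineR/ChemmineOB (OpenBabel). The result is a hydrogen-depleted
#' graph; implicit hydrogen counts are derived from standard valences
#' and retained so that an explicit-hydrogen graph can be requested with
#' [add_hydrogens()].
#'
#' @param smiles a single SMILES string
#' @return a `molecular_graph` with `hydrogen_mode = "heavy"`
#' @examples
#' g <- parse_smiles("c1ccccc1")  # benzene: 6 atoms, 6 aromatic bonds
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)[[1]]),
    error = function(e) stop("SMILES parse failure for '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  .graph_from_sdf(sdf)
}

.graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  symbols <- gsub("_.*$", "", rownames(ab))
  if (length(symbols) == 0) stop("empty molecule")
  keep <- symbols != "H"
  if (!all(keep)) {
    # drop explicit hydrogens; remember them as implicit counts
    idx_map <- cumsum(keep)
    h_on <- integer(sum(keep))
    bonds_keep <- NULL
    if (nrow(bb)) {
      for (r in seq_len(nrow(bb))) {
        i <- bb[r, 1]; j <- bb[r, 2]
        if (keep[i] && keep[j]) {
          bonds_keep <- rbind(bonds_keep, bb[r, , drop = FALSE])
        } else if (keep[i] && !keep[j]) {
          h_on[idx_map[i]] <- h_on[idx_map[i]] + 1L
        } else if (!keep[i] && keep[j]) {
          h_on[idx_map[j]] <- h_on[idx_map[j]] + 1L
        }
      }
    }
    bb <- bonds_keep
    symbols <- symbols[keep]
    remap <- function(x) idx_map[x]
    bonds <- if (is.null(bb)) {
      data.frame(i = integer(), j = integer(), order = numeric())
    } else {
      data.frame(i = remap(bb[, 1]), j = remap(bb[, 2]), order = as.numeric(bb[, 3]))
    }
    extra_h <- h_on
    map_idx <- idx_map
  } else {
    bonds <- if (nrow(bb)) {
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.numeric(bb[, 3]))
    } else {
      data.frame(i = integer(), j = integer(), order = numeric())
    }
    extra_h <- integer(length(symbols))
    map_idx <- seq_along(symbols)
  }

  # aromatic bond perception via ring detection on the kekulized graph
  bonds$aromatic <- FALSE
  rr <- tryCatch(
    ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = FALSE),
    error = function(e) list(RINGS = list(), AROMATIC = logical())
  )
  if (length(rr$RINGS)) {
    for (k in seq_along(rr$RINGS)) {
      if (!isTRUE(rr$AROMATIC[[k]])) next
      ring_idx <- map_idx[as.integer(gsub("^[^_]*_", "", rr$RINGS[[k]]))]
      m <- length(ring_idx)
      for (e in seq_len(m)) {
        a <- ring_idx[e]; b <- ring_idx[if (e == m) 1 else e + 1]
        hit <- (bonds$i == a & bonds$j == b) | (bonds$i == b & bonds$j == a)
        bonds$aromatic[hit] <- TRUE
      }
    }
  }

  # implicit hydrogens from standard valences on the kekulized orders
  el <- .element_row(symbols)
  deg_order <- numeric(length(symbols))
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      deg_order[bonds$i[r]] <- deg_order[bonds$i[r]] + bonds$order[r]
      deg_order[bonds$j[r]] <- deg_order[bonds$j[r]] + bonds$order[r]
    }
  }
  implicit_h <- pmax(0L, as.integer(round(el$valence - deg_order))) + extra_h

  molecular_graph(symbols, bonds, hydrogen_mode = "heavy",
                  implicit_h = implicit_h)
}

#' Add explicit hydrogens to a heavy-atom graph
#'
#' Appends one atom per implicit hydrogen, bonded by a single bond to its
#' heavy atom. Some autocorrelation descriptors are conventionally computed
#' with polar hydrogens retained; this provides the full explicit-H variant.
#'
#' @param g a heavy-atom `molecular_graph`
#' @return a `molecular_graph` with `hydrogen_mode = "explicit-h"`
#' @export
add_hydrogens <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  if (g$hydrogen_mode != "heavy") return(g)
  nh <- g$atoms$implicit_h
  symbols <- c(g$atoms$symbol, rep("H", sum(nh)))
  bonds <- g$bonds[, c("i", "j", "order", "aromatic")]
  nxt <- n_atoms(g)
  for (a in seq_len(n_atoms(g))) {
    if (nh[a] > 0) {
      for (k in seq_len(nh[a])) {
        nxt <- nxt + 1
        bonds <- rbind(bonds, data.frame(i = a, j = nxt, order = 1,
                                         aromatic = FALSE))
      }
    }
  }
  molecular_graph(symbols, bonds, hydrogen_mode = "explicit-h",
                  implicit_h = rep(0L, length(symbols)))
}

#' Topological distance matrix
#'
#' Shortest bond-path length between every atom pair, by breadth-first
#' search from each atom.
#'
#' @param g a `molecular_graph`; must be connected
#' @return integer matrix, `d[i, j]` = number of bonds on the shortest path
#' @export
distance_matrix <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  if (anyNA(D)) stop("graph is disconnected; topological distances undefined")
  D
}

is_connected_graph <- function(g) {
  n <- n_atoms(g)
  if (n == 1) return(TRUE)
  adj <- adjacency_list(g)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; nxt <- c(nxt, w) }
    frontier <- nxt
  }
  all(seen)
}

# Enumerate all simple cycles of an undirected graph, returned as a list of
# vertex vectors. Anchored DFS: each cycle is generated once with its
# smallest vertex first. Intended for molecular-sized graphs.
enumerate_simple_cycles <- function(g) {
  adj <- adjacency_list(g)
  n <- n_atoms(g)
  cycles <- list()
  path <- integer(0)
  on_path <- rep(FALSE, n)
  dfs <- function(v, start) {
    path[length(path) + 1] <<- v
    on_path[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 3) {
        # close the cycle; keep one orientation only (second vertex < last)
        if (path[2] < path[length(path)]) {
          cycles[[length(cycles) + 1]] <<- path
        }
      } else if (!on_path[w] && w > start) {
        dfs(w, start)
      }
    }
    on_path[v] <<- FALSE
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  cycles
}

#' Count rings of a given size
#'
#' Counts distinct simple cycles with exactly `size` vertices, enumerated
#' over the full cycle space of the graph rather than a minimal ring basis.
#' Fused bridged systems therefore count every circuit: the
#' 2-oxabicyclo[2.2.2]octane core of eucalyptol contains three distinct
#' 6-membered rings even though a minimal basis holds only two.
#'
#' @param g a `molecular_graph`
#' @param size ring size (>= 3)
#' @return integer count
#' @export
rings_of_size <- function(g, size) {
  stopifnot(inherits(g, "molecular_graph"), size >= 3)
  cyc <- enumerate_simple_cycles(g)
  sum(vapply(cyc, length, integer(1)) == size)
}

#' Count atoms of a given element
#'
#' @param g a `molecular_graph`
#' @param symbol element symbol, e.g. `"O"`
#' @return integer count (heavy-atom graphs count only heavy atoms; request
#'   hydrogens via [add_hydrogens()] first if needed)
#' @export
count_element <- function(g, symbol) {
  stopifnot(inherits(g, "molecular_graph"), is.character(symbol))
  if (symbol == "H" && g$hydrogen_mode == "heavy") {
    return(sum(g$atoms$implicit_h))
  }
  sum(g$atoms$symbol == symbol)
}
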