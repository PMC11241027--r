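# The nine model descriptors and their parameterized families.
#
# All topological descriptors operate on the hydrogen-depleted graph by
# default; autocorrelations accept any lag and weighting scheme, the
# spectral descriptors any eigenvalue index, so each of the nine published
# descriptors is one point of a family.

#' Broto-Moreau autocorrelation (ATS)
#'
#' Sums the products of atomic weights over all unordered atom pairs at a
#' given topological distance (the lag). The reported value is
#' `log(1 + ATS)`, the "(log function)" form in which the mass-weighted
#' lag-4 value (ATS4m) enters the binding-score model.
#'
#' @param g a connected `molecular_graph`
#' @param lag topological distance (>= 1) at which atoms are paired
#' @param scheme weighting scheme, see [atom_weights()]
#' @param log_form return `log(1 + raw)` (default) or the raw sum
#' @return numeric value; 0 when no atom pair exists at the lag
#' @export
ats_autocorrelation <- function(g, lag,
                                scheme = c("unit", "mass", "electronegativity"),
                                log_form = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(lag >= 1)
  w <- atom_weights(g, scheme)
  D <- distance_matrix(g)
  idx <- which(D == lag & upper.tri(D), arr.ind = TRUE)
  raw <- if (nrow(idx)) sum(w[idx[, 1]] * w[idx[, 2]]) else 0
  if (log_form) log1p(raw) else raw
}

# Burden matrix constants (Burden 1989 / Dragon convention): bonded
# off-diagonal entries code the conventional bond order, terminal bonds are
# augmented, all non-bonded entries carry a small constant.
.BURDEN_OFFDIAG_SCALE <- 0.1   # times conventional bond order (aromatic 1.5)
.BURDEN_TERMINAL_AUG <- 0.01
.BURDEN_NONBONDED <- 0.001

# exposed for construction-level testing
burden_matrix <- function(g, scheme = c("unit", "mass", "electronegativity")) {
  scheme <- match.arg(scheme)
  n <- n_atoms(g)
  B <- matrix(.BURDEN_NONBONDED, n, n)
  deg <- tabulate(c(g$bonds$i, g$bonds$j), n)
  ord <- conventional_order(g)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    v <- .BURDEN_OFFDIAG_SCALE * ord[b]
    if (deg[i] == 1 || deg[j] == 1) v <- v + .BURDEN_TERMINAL_AUG
    B[i, j] <- v; B[j, i] <- v
  }
  diag(B) <- atom_weights(g, scheme)
  B
}

#' Burden (BCUT) eigenvalue descriptor
#'
#' Eigenvalue of the Burden connectivity matrix: diagonal = atomic weights,
#' bonded off-diagonal = 0.1 x conventional bond order (+0.01 for terminal
#' bonds), non-bonded = 0.001. `BEle3` is the third-lowest eigenvalue with
#' Sanderson-electronegativity weights.
#'
#' @inheritParams ats_autocorrelation
#' @param index which eigenvalue, counted from the requested `end`
#' @param end `"lowest"` or `"highest"` end of the sorted spectrum
#' @return numeric eigenvalue
#' @export
burden_eigenvalue <- function(g, index, end = c("lowest", "highest"),
                              scheme = c("unit", "mass", "electronegativity")) {
  end <- match.arg(end)
  n <- n_atoms(g)
  if (index > n) {
    stop("eigenvalue index ", index, " exceeds atom count ", n)
  }
  B <- burden_matrix(g, scheme)
  ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
  if (end == "lowest") ev[index] else rev(ev)[index]
}

# number of distinct simple 3-edge paths: for each central edge (j,k),
# choose i in N(j)\{k}, l in N(k)\{j}, i != l; each path counted once.
count_paths3 <- function(g) {
  adj <- adjacency_list(g)
  total <- 0L
  for (b in seq_len(nrow(g$bonds))) {
    j <- g$bonds$i[b]; k <- g$bonds$j[b]
    Ni <- setdiff(adj[[j]], k)
    Nl <- setdiff(adj[[k]], j)
    if (length(Ni) && length(Nl)) {
      total <- total + length(Ni) * length(Nl) - length(intersect(Ni, Nl))
    }
  }
  total
}

.kier_alpha <- function(g) {
  r <- mapply(function(sym, hyb) {
    tab <- .KIER_RADII[[sym]]
    if (is.null(tab)) stop("no Kier radius for element ", sym)
    unname(tab[hyb])
  }, g$atoms$symbol, g$atoms$hyb)
  sum(r / .R_CSP3 - 1)
}

#' Kier alpha-modified 3-path shape index (S3K)
#'
#' `(A + a - 1)(A + a - 3)^2 / (P3 + a)^2` for odd heavy-atom count A,
#' `(A + a - 3)(A + a - 2)^2 / (P3 + a)^2` for even A, where P3 is the
#' number of distinct 3-edge simple paths and the alpha term sums
#' `r_i / r_Csp3 - 1` over Kier's hybridization-dependent covalent radii.
#' Aromatic systems combine many 3-paths with sub-sp3 radii, which is what
#' pushes ring-rich molecules below same-size aliphatic chains.
#'
#' @param g a `molecular_graph` with at least 4 heavy atoms
#' @return numeric shape index
#' @export
kier_shape_3 <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  A <- n_atoms(g)
  if (A < 4) stop("S3K needs at least 4 heavy atoms")
  alpha <- .kier_alpha(g)
  P3 <- count_paths3(g)
  den <- (P3 + alpha)^2
  if (den == 0) stop("degenerate S3K denominator (P3 + alpha = 0)")
  if (A %% 2 == 1) {
    (A + alpha - 1) * (A + alpha - 3)^2 / den
  } else {
    (A + alpha - 3) * (A + alpha - 2)^2 / den
  }
}

# bond resonance weights for the "r"-suffixed edge-adjacency descriptors
.BOND_RESONANCE <- c(`1` = 1, `1.5` = 1.5, `2` = 2, `3` = 3)

# exposed for construction-level testing
edge_adjacency_matrix <- function(g) {
  m <- nrow(g$bonds)
  E <- matrix(0, m, m)
  if (m == 0) return(E)
  w <- .BOND_RESONANCE[as.character(conventional_order(g))]
  for (f in seq_len(m - 1)) {
    for (h in (f + 1):m) {
      shared <- length(intersect(c(g$bonds$i[f], g$bonds$j[f]),
                                 c(g$bonds$i[h], g$bonds$j[h]))) > 0
      if (shared) {
        v <- sqrt(w[f] * w[h])
        E[f, h] <- v; E[h, f] <- v
      }
    }
  }
  E
}

#' Edge-adjacency eigenvalue descriptor (EEig)
#'
#' Eigenvalue of the bond-resonance-weighted edge adjacency matrix: bonds
#' are nodes; two bonds sharing an atom are connected with weight
#' `sqrt(w_f w_h)` where w is the conventional bond order (single 1,
#' aromatic 1.5, double 2, triple 3). `EEig03r` is the third-largest
#' eigenvalue; it grows with branching, which the binding-affinity model
#' reads as a positive driver of complexation.
#'
#' @param g a `molecular_graph`
#' @param index which eigenvalue, counted from the top of the spectrum
#' @return numeric eigenvalue
#' @export
edge_adjacency_eigenvalue <- function(g, index) {
  m <- nrow(g$bonds)
  if (m < index) stop("eigenvalue index ", index, " exceeds edge count ", m)
  E <- edge_adjacency_matrix(g)
  ev <- sort(eigen(E, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[index]
}

# molecular influence (leverage) matrix from centered coordinates; planar
# and linear geometries are handled through the pseudo-inverse by dropping
# singular directions below a relative tolerance.
influence_matrix <- function(conf, tol = 1e-3) {
  M <- scale(conf$xyz, center = TRUE, scale = FALSE)
  sv <- svd(M)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) stop("degenerate geometry: all atoms coincide (rank 0)")
  U <- sv$u[, keep, drop = FALSE]
  U %*% t(U)
}

#' GETAWAY H autocorrelation
#'
#' Computed from the molecular influence matrix
#' `H = M (M'M)^-1 M'` of the centered atomic coordinates `M`. Lag 0 sums
#' `h_ii w_i^2` over atoms (H0e with Sanderson weights); lag k >= 1 sums
#' `h_ij w_i w_j` over atom pairs at topological distance k with positive
#' `h_ij`.
#'
#' @inheritParams ats_autocorrelation
#' @param conf a `conformer3d` aligned with `g`
#' @param lag integer >= 0
#' @return numeric value
#' @export
getaway_h_autocorrelation <- function(g, conf, lag = 0,
                                      scheme = c("unit", "mass", "electronegativity")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(conf, "conformer3d"), nrow(conf$xyz) == n_atoms(g),
            lag >= 0)
  H <- influence_matrix(conf)
  w <- atom_weights(g, scheme)
  if (lag == 0) {
    return(sum(diag(H) * w^2))
  }
  D <- distance_matrix(g)
  idx <- which(D == lag & upper.tri(D), arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  h <- H[idx]
  sum(ifelse(h > 0, h, 0) * w[idx[, 1]] * w[idx[, 2]])
}

#' Geary autocorrelation (GATS)
#'
#' `c(k) = [sum_{d_ij = k} (w_i - w_j)^2 / (2 N_k)] /
#' [sum_i (w_i - wbar)^2 / (A - 1)]` with `N_k` the number of atom pairs at
#' topological distance k. Defined as 0 when no pair exists at the lag or
#' when all weights are equal, so small molecules never yield missing
#' values.
#'
#' @inheritParams ats_autocorrelation
#' @return numeric value
#' @export
geary_autocorrelation <- function(g, lag,
                                  scheme = c("unit", "mass", "electronegativity")) {
  scheme <- match.arg(scheme)
  stopifnot(lag >= 1)
  w <- atom_weights(g, scheme)
  A <- length(w)
  denom <- sum((w - mean(w))^2) / (A - 1)
  if (denom == 0) return(0)
  D <- distance_matrix(g)
  idx <- which(D == lag & upper.tri(D), arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  num <- sum((w[idx[, 1]] - w[idx[, 2]])^2) / (2 * nrow(idx))
  num / denom
}

#' 3D-MoRSE signal
#'
#' `Mor(s) = sum_{i<j} w_i w_j sin(s r_ij) / (s r_ij)` over interatomic
#' distances `r_ij`, with scattering parameter `s = signal - 1` (1/Angstrom;
#' signal 1 is s = 0, where every term is 1 by the sinc limit). `Mor10u`
#' uses signal 10 (s = 9) with unit weights.
#'
#' @param conf a `conformer3d`
#' @param signal signal index >= 1 (standard 32-signal convention)
#' @param g the parent `molecular_graph` (needed for non-unit weights)
#' @param scheme weighting scheme
#' @return numeric value
#' @export
morse_signal <- function(conf, signal, g = NULL,
                         scheme = c("unit", "mass", "electronegativity")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(conf, "conformer3d"), signal >= 1)
  n <- nrow(conf$xyz)
  stopifnot(n >= 2)
  w <- if (scheme == "unit") rep(1, n) else atom_weights(g, scheme)
  s <- signal - 1
  R <- as.matrix(stats::dist(conf$xyz))
  idx <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[idx]
  sinc <- if (s == 0) rep(1, length(r)) else sin(s * r) / (s * r)
  sum(w[idx[, 1]] * w[idx[, 2]] * sinc)
}

# Ertl (2000) polar-fragment surface contributions, N/O neutral fragments.
.TPSA_O <- list(
  aromatic = 13.14,  # o in aromatic ring
  hydroxyl = 20.23,  # -OH
  ether    = 9.23,   # -O-
  carbonyl = 17.07   # =O
)
.TPSA_N <- list(
  aromatic2 = 12.89,  # :n: two ring bonds
  aromatic3 = 4.41,   # :n(:)(:) three aromatic bonds
  aromaticH = 15.79,  # :nH:
  tertiary  = 3.24,   # N(-)(-)-
  secondary = 12.03,  # NH(-)-
  primary   = 26.02,  # NH2-
  imine     = 12.36,  # =N-
  imineH    = 23.85,  # =NH
  nitrile   = 23.79   # #N
)

#' Topological polar surface area (TPSA)
#'
#' Sum of Ertl fragment surface contributions over nitrogen- and
#' oxygen-centered polar fragments, matched on element, aromaticity,
#' hydrogen count and bonding pattern. Molecules without N or O score 0.
#'
#' @param g a `molecular_graph`
#' @return numeric value in Angstrom^2 (>= 0)
#' @export
tpsa <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  total <- 0
  for (a in seq_len(n_atoms(g))) {
    sym <- g$atoms$symbol[a]
    if (!sym %in% c("N", "O")) next
    rows <- g$bonds$i == a | g$bonds$j == a
    ords <- g$bonds$order[rows]
    arom <- g$bonds$aromatic[rows]
    nb_heavy <- sum(rows)
    nh <- g$atoms$implicit_h[a] +
      sum(g$atoms$symbol[c(g$bonds$j[rows & g$bonds$i == a],
                           g$bonds$i[rows & g$bonds$j == a])] == "H")
    if (sym == "O") {
      contrib <-
        if (any(arom)) .TPSA_O$aromatic
        else if (any(ords == 2)) .TPSA_O$carbonyl
        else if (nh >= 1) .TPSA_O$hydroxyl
        else .TPSA_O$ether
    } else {
      n_arom <- sum(arom)
      contrib <-
        if (n_arom >= 2 && nh >= 1) .TPSA_N$aromaticH
        else if (n_arom >= 3) .TPSA_N$aromatic3
        else if (n_arom >= 2) .TPSA_N$aromatic2
        else if (any(ords == 3)) .TPSA_N$nitrile
        else if (any(ords == 2)) { if (nh >= 1) .TPSA_N$imineH else .TPSA_N$imine }
        else if (nh >= 2) .TPSA_N$primary
        else if (nh == 1) .TPSA_N$secondary
        else .TPSA_N$tertiary
    }
    total <- total + contrib
  }
  total
}
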