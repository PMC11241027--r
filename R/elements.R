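# Element property tables used by descriptor weighting schemes.
#
# Masses: IUPAC 2021 standard atomic weights.
# Sanderson electronegativities: Sanderson (1983), J. Chem. Educ. 65, 112;
#   descriptor weights are conventionally scaled relative to carbon.
# Covalent radii: single-bond radii from Pauling/CRC tables, in Angstrom.
.ELEMENTS <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  mass   = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998,
             28.085, 30.974, 32.06, 35.45, 79.904, 126.904),
  sanderson = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000,
                2.138, 2.515, 2.957, 3.475, 3.219, 2.778),
  radius = c(0.37, 0.82, 0.77, 0.75, 0.73, 0.71,
             1.11, 1.06, 1.02, 0.99, 1.14, 1.33),
  valence = c(1, 3, 4, 3, 2, 1, 4, 3, 2, 1, 1, 1),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

# Kier covalent radii (Angstrom) by hybridization, used by the alpha
# modification of the kappa shape indices (Kier 1986). NA falls back to
# the sp3 value for elements where Kier tabulates a single radius.
.KIER_RADII <- list(
  C  = c(sp3 = 0.77, sp2 = 0.67, sp = 0.60),
  N  = c(sp3 = 0.74, sp2 = 0.62, sp = 0.55),
  O  = c(sp3 = 0.74, sp2 = 0.62, sp = 0.62),
  S  = c(sp3 = 1.04, sp2 = 0.94, sp = 0.94),
  P  = c(sp3 = 1.10, sp2 = 1.00, sp = 1.00),
  F  = c(sp3 = 0.72, sp2 = 0.72, sp = 0.72),
  Cl = c(sp3 = 0.99, sp2 = 0.99, sp = 0.99),
  Br = c(sp3 = 1.14, sp2 = 1.14, sp = 1.14),
  I  = c(sp3 = 1.33, sp2 = 1.33, sp = 1.33),
  H  = c(sp3 = 0.37, sp2 = 0.37, sp = 0.37)
)
.R_CSP3 <- 0.77

.element_row <- function(symbol) {
  row <- .ELEMENTS[match(symbol, .ELEMENTS$symbol), ]
  if (anyNA(row$symbol)) {
    bad <- unique(symbol[!symbol %in% .ELEMENTS$symbol])
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
  }
  row
}

#' Atomic weights for a descriptor weighting scheme
#'
#' Returns per-atom weights scaled relative to carbon, the convention used
#' by topological autocorrelation and eigenvalue descriptors.
#'
#' @param g a `molecular_graph`
#' @param scheme one of `"unit"`, `"mass"` (relative atomic mass / carbon
#'   mass) or `"electronegativity"` (Sanderson electronegativity / carbon
#'   value)
#' @return numeric vector, one weight per atom
#' @export
atom_weights <- function(g, scheme = c("unit", "mass", "electronegativity")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(g, "molecular_graph"))
  switch(scheme,
    unit = rep(1, nrow(g$atoms)),
    mass = g$atoms$mass / .ELEMENTS["C", "mass"],
    electronegativity = g$atoms$sanderson / .ELEMENTS["C", "sanderson"]
  )
}
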