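# Synthetic descriptor/response data with the statistical structure the
# modeling pipeline assumes: an equicorrelated Gaussian descriptor pool and
# a linear response in a small true subset plus Gaussian noise.

#' Specification for a synthetic data set
#'
#' @param n number of compounds
#' @param p descriptor pool size
#' @param k size of the true signal subset (`k <= p`)
#' @param beta coefficient vector of length `k` (recycled if scalar)
#' @param sigma response noise standard deviation (>= 0)
#' @param rho pairwise descriptor correlation in `[0, 1)`; equicorrelated
#'   Gaussian columns, the simplest structure exhibiting the collinearity
#'   that makes subset selection nontrivial
#' @param intercept response intercept
#' @param seed integer seed
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n = 100, p = 30, k = 3, beta = 1, sigma = 0.5,
                           rho = 0.3, intercept = 0, seed = 1L) {
  stopifnot(k <= p, sigma >= 0, rho >= 0, rho < 1, n >= 3)
  beta <- rep_len(beta, k)
  structure(list(n = n, p = p, k = k, beta = beta, sigma = sigma,
                 rho = rho, intercept = intercept, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor/response data set
#'
#' Columns are standard Gaussian with pairwise correlation `rho`
#' (equicorrelated factor construction); the response is
#' `intercept + X[, subset] %*% beta + N(0, sigma)`. The true subset is the
#' first `k` pool columns under a deterministic name shuffle, returned
#' explicitly for recovery experiments. Deterministic given the seed.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `X` (n x p matrix, named columns), `y`,
#'   `true_subset` (column names), `beta` (named), `spec`
#' @export
gen_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  n <- spec$n; p <- spec$p
  # equicorrelated Gaussian: X_j = sqrt(rho) Z0 + sqrt(1 - rho) Z_j
  Z0 <- stats::rnorm(n)
  X <- sqrt(spec$rho) * matrix(Z0, n, p) +
    sqrt(1 - spec$rho) * matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- sprintf("D%02d", seq_len(p))
  subset <- colnames(X)[seq_len(spec$k)]
  beta <- stats::setNames(spec$beta, subset)
  y <- spec$intercept + drop(X[, subset, drop = FALSE] %*% beta) +
    stats::rnorm(n, sd = spec$sigma)
  list(X = X, y = y, true_subset = subset, beta = beta, spec = spec)
}

#' Generate a synthetic complex table with a binding-energy column
#'
#' Produces a 20-row table with the schema of the packaged complex table
#' plus a synthetic `binding_energy_kjmol` column, enabling end-to-end
#' binding-energy (Model-3-style) workflows: the packaged data carry no
#' binding-energy values. HOMO/LUMO/gap are internally consistent; binding
#' energies are negative with `log10(|BE|)` in the 1-2 magnitude regime of
#' the packaged affinities.
#'
#' @param seed integer seed
#' @param n number of rows (default 20)
#' @return data frame; all columns synthetic
#' @export
gen_complex_table <- function(seed = 1L, n = 20) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  homo <- stats::runif(n, -10.3, -8.9)
  lumo <- stats::runif(n, -1.5, 0.2)
  be <- -10^stats::runif(n, 1.3, 1.95)   # |BE| between ~20 and ~90 kJ/mol
  data.frame(
    id = seq_len(n),
    complex = sprintf("Synthetic ligand %02d-%s", seq_len(n),
                      sample(c("in", "up"), n, replace = TRUE)),
    homo_ev = round(homo, 4),
    lumo_ev = round(lumo, 4),
    gap_ev = round(homo, 4) - round(lumo, 4),
    binding_score_kjmol = round(stats::runif(n, -5.0, -2.8), 1),
    binding_affinity_kjmol = round(-10^stats::runif(n, 1.4, 1.96), 4),
    binding_energy_kjmol = round(be, 4),
    stringsAsFactors = FALSE
  )
}
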