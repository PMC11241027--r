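# Descriptor matrix assembly and z-score normalization.

DESCRIPTOR_NAMES <- c("nR06", "ATS4m", "BEle3", "S3K", "EEig03r",
                      "H0e", "GATS8e", "Mor10u", "TPSA")

#' Compute the nine model descriptors for one molecule
#'
#' @param g a connected `molecular_graph` (hydrogen-depleted)
#' @param conf optional `conformer3d`; generated with [embed_3d()] and
#'   `seed` when missing
#' @param seed seed for conformer generation when `conf` is missing
#' @return named numeric vector over `nR06, ATS4m, BEle3, S3K, EEig03r,
#'   H0e, GATS8e, Mor10u, TPSA`
#' @export
descriptor_vector <- function(g, conf = NULL, seed = 1L) {
  stopifnot(inherits(g, "molecular_graph"))
  if (is.null(conf)) conf <- embed_3d(g, seed = seed)
  v <- c(
    nR06 = as.numeric(rings_of_size(g, 6)),
    ATS4m = ats_autocorrelation(g, 4, "mass"),
    BEle3 = burden_eigenvalue(g, 3, "lowest", "electronegativity"),
    S3K = kier_shape_3(g),
    EEig03r = edge_adjacency_eigenvalue(g, 3),
    H0e = getaway_h_autocorrelation(g, conf, 0, "electronegativity"),
    GATS8e = geary_autocorrelation(g, 8, "electronegativity"),
    Mor10u = morse_signal(conf, 10),
    TPSA = tpsa(g)
  )
  if (!all(is.finite(v))) {
    stop("non-finite descriptor value(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  }
  v
}

#' Compute a descriptor matrix for a set of molecules
#'
#' @param mols named list of `molecular_graph` objects (names become
#'   compound ids), or a character vector of SMILES
#' @param seed seed passed to conformer generation (one deterministic
#'   conformer per molecule, offset by position)
#' @return object of class `descriptor_matrix`: list with `values`
#'   (compounds x descriptors matrix), `ids` and `normalization`
#' @export
compute_descriptor_matrix <- function(mols, seed = 1L) {
  if (is.character(mols)) {
    nm <- if (is.null(names(mols))) as.character(seq_along(mols)) else names(mols)
    mols <- lapply(mols, parse_smiles)
    names(mols) <- nm
  }
  ids <- if (is.null(names(mols))) as.character(seq_along(mols)) else names(mols)
  rows <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    rows[[k]] <- tryCatch(
      descriptor_vector(mols[[k]], seed = seed + k - 1L),
      error = function(e) stop("descriptor computation failed for '",
                               ids[k], "': ", conditionMessage(e),
                               call. = FALSE)
    )
  }
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  structure(list(values = values, ids = ids, normalization = NULL),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix: %d compounds x %d descriptors%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$normalization)) "" else ", z-scored"))
  print(utils::head(x$values, 6))
  invisible(x)
}

#' Z-score normalize a descriptor matrix
#'
#' Column means and standard deviations are estimated on a designated
#' reference subset (the training compounds) and applied to every row, the
#' standard autoscaling step that precedes model fitting. Parameters are
#' stored so models can be applied to new molecules on the same scale.
#'
#' @param m a `descriptor_matrix`
#' @param reference compound ids defining the reference subset; defaults to
#'   all compounds
#' @return normalized `descriptor_matrix` with `normalization` populated
#' @export
normalize_descriptors <- function(m, reference = NULL) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (!is.null(m$normalization)) stop("matrix is already normalized")
  if (is.null(reference)) reference <- m$ids
  miss <- setdiff(reference, m$ids)
  if (length(miss)) stop("unknown reference ids: ", paste(miss, collapse = ", "))
  ref <- m$values[reference, , drop = FALSE]
  mu <- colMeans(ref)
  sdv <- apply(ref, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance column(s) on reference subset: ",
         paste(colnames(ref)[sdv == 0], collapse = ", "))
  }
  vals <- sweep(sweep(m$values, 2, mu), 2, sdv, "/")
  structure(list(values = vals, ids = m$ids,
                 normalization = list(mean = mu, sd = sdv,
                                      reference = reference)),
            class = "descriptor_matrix")
}

#' Undo z-score normalization
#'
#' @param m a normalized `descriptor_matrix`
#' @return `descriptor_matrix` on the original scale
#' @export
denormalize_descriptors <- function(m) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (is.null(m$normalization)) stop("matrix is not normalized")
  vals <- sweep(sweep(m$values, 2, m$normalization$sd, "*"),
                2, m$normalization$mean, "+")
  structure(list(values = vals, ids = m$ids, normalization = NULL),
            class = "descriptor_matrix")
}

#' Apply stored normalization parameters to new descriptor values
#'
#' @param values matrix or named vector of raw descriptor values
#' @param normalization the `normalization` element of a normalized
#'   `descriptor_matrix`
#' @return values on the z-score scale of the reference subset
#' @export
apply_normalization <- function(values, normalization) {
  if (is.null(dim(values))) values <- matrix(values, 1,
                                             dimnames = list(NULL, names(values)))
  cols <- names(normalization$mean)
  miss <- setdiff(cols, colnames(values))
  if (length(miss)) stop("missing descriptor column(s): ",
                         paste(miss, collapse = ", "))
  sweep(sweep(values[, cols, drop = FALSE], 2, normalization$mean),
        2, normalization$sd, "/")
}

#' Export a descriptor matrix as CSV
#'
#' Header = descriptor names, first column = compound id, full double
#' precision.
#'
#' @param m a `descriptor_matrix`
#' @param path output file path
#' @export
write_descriptor_csv <- function(m, path) {
  df <- data.frame(compound = m$ids, m$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
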