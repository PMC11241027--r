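# Packaged 20-complex data set, response transforms and the rank-based
# train/test split.

.CD_COMPLEXES_MD5 <- "6e0002e7636c0d7090d0ff6e5c8603be"

#' Load the packaged beta-CD complex table
#'
#' Twenty beta-cyclodextrin-phenolic complexes with HOMO/LUMO energies and
#' gap (eV), the docking binding score and the semi-empirical binding
#' affinity (both kJ/mol, negative = favorable). The loader verifies the
#' file checksum and the internal consistency gap = HOMO - LUMO.
#'
#' @return data frame with columns `id`, `complex`, `name`, `orientation`,
#'   `homo_ev`, `lumo_ev`, `gap_ev`, `binding_score_kjmol`,
#'   `binding_affinity_kjmol`
#' @export
cd_complexes <- function() {
  path <- system.file("extdata", "cd_complexes.csv", package = "cdbind",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .CD_COMPLEXES_MD5)) {
    stop("packaged complex table is corrupted (checksum mismatch)")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) != 20) stop("expected 20 complex records, got ", nrow(df))
  if (any(abs(df$gap_ev - (df$homo_ev - df$lumo_ev)) > 1e-4)) {
    stop("gap/HOMO/LUMO inconsistency in packaged table")
  }
  df$name <- sub("-(in|up)$", "", df$complex)
  df$orientation <- sub("^.*-", "", df$complex)
  df[, c("id", "complex", "name", "orientation", "homo_ev", "lumo_ev",
         "gap_ev", "binding_score_kjmol", "binding_affinity_kjmol")]
}

#' Load the packaged ligand structures
#'
#' Line-notation (SMILES) structures for the 20 named ligands, with the
#' docking orientation tag carried as metadata.
#'
#' @param parse parse each structure into a `molecular_graph`?
#' @return data frame with `id`, `name`, `orientation`, `smiles` and, when
#'   `parse = TRUE`, a list-column `graph`
#' @export
cd_ligands <- function(parse = FALSE) {
  path <- system.file("extdata", "cd_ligands.smi", package = "cdbind",
                      mustWork = TRUE)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(raw) <- c("smiles", "name", "orientation")
  df <- data.frame(id = seq_len(nrow(raw)), name = raw$name,
                   orientation = raw$orientation, smiles = raw$smiles,
                   stringsAsFactors = FALSE)
  if (nrow(df) != 20) stop("expected 20 ligand structures, got ", nrow(df))
  if (parse) df$graph <- lapply(df$smiles, parse_smiles)
  df
}

#' Log-transformed binding response
#'
#' Binding quantities are negative (favorable); the modeling response is
#' `log10(|value|)` of the kJ/mol quantity. `LogBSA` transforms the docking
#' binding score, `LogBA` the semi-empirical binding affinity. `LogBE`
#' (binding energy, the third model's response) is not part of the packaged
#' table; supply synthetic records from [gen_complex_table()] for BE
#' workflows.
#'
#' @param records data frame as returned by [cd_complexes()]
#' @param kind one of `"LogBSA"`, `"LogBA"`, `"LogBE"`
#' @return object of class `response_vector`: named numeric (names =
#'   compound ids) with attribute `kind`
#' @export
log_response <- function(records, kind = c("LogBSA", "LogBA", "LogBE")) {
  kind <- match.arg(kind)
  col <- switch(kind,
                LogBSA = "binding_score_kjmol",
                LogBA = "binding_affinity_kjmol",
                LogBE = "binding_energy_kjmol")
  if (!col %in% names(records)) {
    stop("response column '", col, "' not present; the packaged table ",
         "carries no binding-energy values (use synthetic records)")
  }
  src <- records[[col]]
  if (any(src == 0)) stop("zero binding value cannot be log-transformed")
  y <- log10(abs(src))
  names(y) <- as.character(records$id)
  structure(y, kind = kind, class = c("response_vector", "numeric"))
}

#' Rank-based train/test split
#'
#' Sorts compounds by ascending response and assigns every `period`-th
#' compound (ranks `period`, `2*period`, ...) to the test set, the standard
#' systematic 4:1 split when `period = 5`. Ties are broken by compound id
#' so the split depends only on the values, not on input order.
#'
#' @param y a `response_vector` (or named numeric)
#' @param period assignment period (default 5, i.e. 80/20)
#' @return list with character vectors `train` and `test` of compound ids,
#'   plus `rank` (ids in ascending response order)
#' @export
rank_split <- function(y, period = 5) {
  stopifnot(length(y) >= period, period >= 2)
  ids <- names(y)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  tie <- suppressWarnings(as.numeric(ids))
  if (anyNA(tie)) tie <- rank(ids)
  ord <- order(unclass(y), tie)
  ranked <- ids[ord]
  test_pos <- seq(period, length(y), by = period)
  list(train = ranked[-test_pos], test = ranked[test_pos], rank = ranked)
}
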