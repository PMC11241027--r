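# End-to-end pipeline over the packaged fixtures, and figure generation.

#' Run the full fixture pipeline
#'
#' Loads the packaged 20-complex table and ligand structures, computes the
#' nine-descriptor matrix, applies the rank-based 4:1 split on the chosen
#' response, z-scores descriptors on the training subset, refits the
#' published descriptor subset by OLS, assembles the validation battery and
#' the Williams-plot applicability-domain report, and evaluates the frozen
#' published equation on the normalized descriptors.
#'
#' @param response `"LogBSA"` (Model 1 descriptors) or `"LogBA"` (Model 2
#'   descriptors)
#' @param seed seed for conformer generation
#' @return list with `descriptors` (raw `descriptor_matrix`), `normalized`,
#'   `split`, `model` (refitted), `published` (frozen equation),
#'   `validation` (`validation_report`), `ad` (`ad_report`),
#'   `published_predictions`
#' @export
run_pipeline <- function(response = c("LogBSA", "LogBA"), seed = 1L) {
  response <- match.arg(response)
  records <- cd_complexes()
  ligands <- cd_ligands()
  smis <- stats::setNames(ligands$smiles, as.character(ligands$id))
  desc <- compute_descriptor_matrix(smis, seed = seed)

  y <- log_response(records, response)
  split <- rank_split(y, period = 5)
  norm <- normalize_descriptors(desc, reference = split$train)

  model_no <- if (response == "LogBSA") 1 else 2
  pub <- published_model(model_no)
  X_tr <- norm$values[split$train, pub$descriptors, drop = FALSE]
  X_te <- norm$values[split$test, pub$descriptors, drop = FALSE]
  y_tr <- unclass(y)[split$train]
  y_te <- unclass(y)[split$test]

  model <- fit_mlr(X_tr, y_tr)
  model$normalization <- norm$normalization
  validation <- validation_report(model, X_tr, y_tr, X_te, y_te)
  ad <- williams_report(model, X_tr, y_tr, X_te, y_te)
  pub_pred <- predict_mlr(pub, norm$values)

  list(descriptors = desc, normalized = norm, split = split,
       response = y, model = model, published = pub,
       validation = validation, ad = ad,
       published_predictions = pub_pred)
}

#' Significance bar plot
#'
#' Bars are model coefficients ordered by decreasing magnitude, signed.
#'
#' @param model an `mlr_model` or `published_model`
#' @return a ggplot object
#' @export
plot_significance <- function(model) {
  prof <- significance_profile(model)
  prof$descriptor <- factor(prof$descriptor, levels = prof$descriptor)
  ggplot2::ggplot(prof,
                  ggplot2::aes(x = .data$descriptor, y = .data$coefficient,
                               fill = .data$sign)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "coefficient",
                  title = "Descriptor significance") +
    ggplot2::theme_minimal()
}

#' Observed-vs-predicted scatter plot
#'
#' @param y_obs,y_pred aligned observed and predicted responses
#' @param set character vector of set labels (`"train"`/`"test"`)
#' @return a ggplot object (includes the identity line)
#' @export
plot_obs_pred <- function(y_obs, y_pred, set = rep("train", length(y_obs))) {
  df <- data.frame(obs = y_obs, pred = y_pred, set = set)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$obs, y = .data$pred,
                                   colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "observed", y = "predicted",
                  title = "Observed vs predicted") +
    ggplot2::theme_minimal()
}

#' Williams plot
#'
#' Standardized residuals against leverage with the +-sigma bounds and the
#' vertical h* threshold.
#'
#' @param report an `ad_report` from [williams_report()]
#' @return a ggplot object
#' @export
plot_williams <- function(report) {
  pts <- report$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$leverage,
                                    y = .data$std_residual,
                                    colour = .data$set)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(-report$sigma_bound,
                                       report$sigma_bound), linetype = 2) +
    ggplot2::geom_vline(xintercept = report$h_star, linetype = 2) +
    ggplot2::labs(x = "leverage h", y = "standardized residual",
                  title = sprintf("Williams plot (h* = %.3f)", report$h_star)) +
    ggplot2::theme_minimal()
}
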