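# Applicability domain: leverages, standardized residuals, Williams plot
# data.

#' Leverages of query compounds against a training design
#'
#' `h = x (X'X)^-1 x'` with an intercept column included, the hat-diagonal
#' distance of a compound from the centroid of the training design. Test
#' compounds are evaluated against the training design (the Williams-plot
#' convention), so structurally unusual queries exceed the training-based
#' threshold.
#'
#' @param X_train training design matrix (without intercept column)
#' @param X_query query rows on the same descriptor scale; defaults to the
#'   training rows themselves
#' @return numeric leverage vector
#' @export
leverages <- function(X_train, X_query = X_train) {
  if (inherits(X_train, "descriptor_matrix")) X_train <- X_train$values
  if (inherits(X_query, "descriptor_matrix")) X_query <- X_query$values
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  Xa <- cbind(1, X_train)
  XtX <- crossprod(Xa)
  inv <- tryCatch(solve(XtX),
                  error = function(e) stop("singular training design: ",
                                           conditionMessage(e), call. = FALSE))
  Qa <- cbind(1, X_query)
  rowSums((Qa %*% inv) * Qa)
}

#' Warning leverage threshold
#'
#' `h* = 3 (k + 1) / n_train`; leverages above it mark compounds outside
#' the structural applicability domain. For a 3-descriptor model trained on
#' 16 compounds, `h* = 0.75`.
#'
#' @param k number of descriptors in the model
#' @param n_train number of training compounds
#' @return numeric threshold
#' @export
leverage_threshold <- function(k, n_train) {
  stopifnot(n_train > 0, k >= 0)
  3 * (k + 1) / n_train
}

#' Standardized residuals
#'
#' Residuals divided by their standard deviation; values beyond
#' `sigma_bound` (3 by default) flag response outliers. The alternative
#' `"studentized"` form additionally divides by `sqrt(1 - h)` when
#' leverages are supplied. An all-zero-variance residual vector returns
#' all zeros with no flags.
#'
#' @param y_obs observed responses
#' @param y_pred predicted responses
#' @param type `"sd"` (default) or `"studentized"`
#' @param h leverages, required for the studentized form
#' @param sigma_bound outlier bound in sigma units
#' @return list with `values` and logical `outlier`
#' @export
standardized_residuals <- function(y_obs, y_pred, type = c("sd", "studentized"),
                                   h = NULL, sigma_bound = 3) {
  type <- match.arg(type)
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3)
  res <- y_obs - y_pred
  s <- stats::sd(res)
  if (s == 0) {
    return(list(values = rep(0, length(res)),
                outlier = rep(FALSE, length(res))))
  }
  std <- if (type == "studentized") {
    if (is.null(h)) stop("studentized residuals need leverages h")
    res / (s * sqrt(pmax(1e-12, 1 - h)))
  } else {
    res / s
  }
  list(values = std, outlier = abs(std) > sigma_bound)
}

#' Williams-plot applicability-domain report
#'
#' Combines leverages (against the training design), standardized
#' residuals, the warning threshold `h* = 3(k+1)/n` and the 3-sigma bound
#' for the training and (optionally) test compounds of a fitted model.
#'
#' @param model an `mlr_model`
#' @param X_train,y_train training design and response
#' @param X_test,y_test optional test design and response
#' @param sigma_bound response-outlier bound (default 3)
#' @return object of class `ad_report`: data frame `points` (id, set,
#'   leverage, std_residual, leverage_outlier, response_outlier) plus
#'   `h_star` and `sigma_bound`
#' @export
williams_report <- function(model, X_train, y_train,
                            X_test = NULL, y_test = NULL, sigma_bound = 3) {
  if (inherits(X_train, "descriptor_matrix")) X_train <- X_train$values
  X_train <- as.matrix(X_train)[, model$descriptors, drop = FALSE]
  k <- length(model$coefficients)
  n <- nrow(X_train)
  h_star <- leverage_threshold(k, n)

  h_tr <- leverages(X_train)
  pred_tr <- predict_mlr(model, X_train)
  ids_tr <- rownames(X_train)
  if (is.null(ids_tr)) ids_tr <- paste0("train", seq_len(n))

  if (!is.null(X_test)) {
    if (inherits(X_test, "descriptor_matrix")) X_test <- X_test$values
    X_test <- as.matrix(X_test)[, model$descriptors, drop = FALSE]
    h_te <- leverages(X_train, X_test)
    pred_te <- predict_mlr(model, X_test)
    ids_te <- rownames(X_test)
    if (is.null(ids_te)) ids_te <- paste0("test", seq_len(nrow(X_test)))
    y_all <- c(y_train, y_test)
    pred_all <- c(pred_tr, pred_te)
    h_all <- c(h_tr, h_te)
    set <- c(rep("train", n), rep("test", nrow(X_test)))
    ids <- c(ids_tr, ids_te)
  } else {
    y_all <- y_train; pred_all <- pred_tr; h_all <- h_tr
    set <- rep("train", n); ids <- ids_tr
  }
  sr <- standardized_residuals(y_all, pred_all, sigma_bound = sigma_bound)
  points <- data.frame(
    id = ids, set = set,
    leverage = unname(h_all),
    std_residual = unname(sr$values),
    leverage_outlier = unname(h_all) > h_star,
    response_outlier = unname(sr$outlier),
    stringsAsFactors = FALSE
  )
  structure(list(points = points, h_star = h_star,
                 sigma_bound = sigma_bound, k = k, n_train = n),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report: h* = %.3f (k = %d, n = %d), %d/%d leverage/response outliers>\n",
              x$h_star, x$k, x$n_train,
              sum(x$points$leverage_outlier), sum(x$points$response_outlier)))
  invisible(x)
}

#' Export Williams-plot data as CSV
#'
#' @param report an `ad_report`
#' @param path output path
#' @export
write_ad_csv <- function(report, path) {
  utils::write.csv(report$points, path, row.names = FALSE)
  invisible(path)
}
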