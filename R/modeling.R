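# MLR fitting, the QSAR validation-statistic battery, and the three frozen
# published model equations.

#' Fit an ordinary least-squares model on selected descriptors
#'
#' Thin wrapper around `stats::lm.fit` that keeps descriptor names and the
#' normalization parameters of the design matrix alongside the
#' coefficients.
#'
#' @param X numeric matrix (compounds x descriptors) or a
#'   `descriptor_matrix`
#' @param y response vector aligned with the rows of `X`
#' @param descriptors optional column subset to fit on
#' @return object of class `mlr_model`: `intercept`, named `coefficients`,
#'   `descriptors`, `normalization` (if `X` carried one), `fitted`,
#'   `residuals`
#' @export
fit_mlr <- function(X, y, descriptors = NULL) {
  norm <- NULL
  if (inherits(X, "descriptor_matrix")) {
    norm <- X$normalization
    X <- X$values
  }
  X <- as.matrix(X)
  if (!is.null(descriptors)) X <- X[, descriptors, drop = FALSE]
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1) stop("need n > k + 1 observations to fit ", k,
                       " descriptors (n = ", n, ")")
  Xa <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xa)
  if (qrX$rank < ncol(Xa)) {
    dropped <- colnames(Xa)[qrX$pivot[(qrX$rank + 1):ncol(Xa)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(Xa, as.numeric(y))
  beta <- fit$coefficients
  structure(list(
    intercept = unname(beta[1]),
    coefficients = beta[-1],
    descriptors = colnames(X),
    normalization = norm,
    fitted = unname(fit$fitted.values),
    residuals = unname(fit$residuals),
    y = as.numeric(y)
  ), class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("<mlr_model>\n  intercept:", format(x$intercept, digits = 4), "\n")
  for (d in x$descriptors) {
    cat(sprintf("  %-10s % .4f\n", d, x$coefficients[[d]]))
  }
  invisible(x)
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y_obs - y_pred)^2) / sum((y_obs - mean(y_obs))^2)`.
#'
#' @param y_obs observed responses
#' @param y_pred predicted responses
#' @return numeric value (<= 1)
#' @export
r_squared <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2)
  tss <- sum((y_obs - mean(y_obs))^2)
  if (tss == 0) stop("zero variance in observed responses")
  1 - sum((y_obs - y_pred)^2) / tss
}

#' Root mean square error
#' @inheritParams r_squared
#' @return numeric value (>= 0)
#' @export
rmse <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 1)
  sqrt(mean((y_obs - y_pred)^2))
}

#' Mean absolute error
#' @inheritParams r_squared
#' @return numeric value (>= 0)
#' @export
mae <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred))
  mean(abs(y_obs - y_pred))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(o, p) / (var(o) + var(p) + (mean(o) - mean(p))^2)` with
#' population (1/n) moment estimators. Penalizes both scale and location
#' disagreement, so a constant shift lowers CCC even at Pearson r = 1.
#'
#' @inheritParams r_squared
#' @return numeric value in `[-1, 1]`
#' @export
ccc <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2)
  n <- length(y_obs)
  mo <- mean(y_obs); mp <- mean(y_pred)
  vo <- mean((y_obs - mo)^2); vp <- mean((y_pred - mp)^2)
  cv <- mean((y_obs - mo) * (y_pred - mp))
  den <- vo + vp + (mo - mp)^2
  if (den == 0) stop("degenerate variance: both vectors constant and equal")
  2 * cv / den
}

#' F statistic of a fitted regression
#'
#' `F = (R2 / k) / ((1 - R2) / (n - k - 1))`. A perfect fit returns `Inf`.
#'
#' @inheritParams r_squared
#' @param k number of descriptors in the model
#' @return numeric value
#' @export
f_statistic <- function(y_obs, y_pred, k) {
  n <- length(y_obs)
  stopifnot(n > k + 1)
  r2 <- r_squared(y_obs, y_pred)
  if (r2 >= 1) return(Inf)
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Leave-one-out cross-validation (Q2 and companions)
#'
#' Removes one compound at a time, refits, and predicts the held-out
#' compound. `Q2 = 1 - PRESS / sum((y - mean(y))^2)` with the mean taken
#' over the full training set (the usual QSAR convention). The default
#' computation uses the exact OLS identity `e_i / (1 - h_ii)` for the
#' deleted residuals; `method = "refit"` runs the explicit n-fold refit
#' loop (identical result, used as a cross-check).
#'
#' @inheritParams fit_mlr
#' @param method `"shortcut"` (hat-matrix identity) or `"refit"`
#' @return list with `q2`, `rmse_cv`, `mae_cv`, `ccc_cv`, `predictions`
#' @export
q2_loo <- function(X, y, descriptors = NULL,
                   method = c("shortcut", "refit")) {
  method <- match.arg(method)
  if (inherits(X, "descriptor_matrix")) X <- X$values
  X <- as.matrix(X)
  if (!is.null(descriptors)) X <- X[, descriptors, drop = FALSE]
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2) stop("need n > k + 2 for leave-one-out validation")
  Xa <- cbind(1, X)
  if (method == "shortcut") {
    qrX <- qr(Xa)
    if (qrX$rank < ncol(Xa)) stop("rank-deficient design in LOO")
    fit <- stats::lm.fit(Xa, y)
    h <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
    pred <- y - fit$residuals / (1 - h)
  } else {
    pred <- numeric(n)
    for (i in seq_len(n)) {
      qri <- qr(Xa[-i, , drop = FALSE])
      if (qri$rank < ncol(Xa)) stop("rank-deficient design in LOO fold ", i)
      beta <- qr.coef(qri, y[-i])
      pred[i] <- drop(Xa[i, ] %*% beta)
    }
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss,
       rmse_cv = rmse(y, pred),
       mae_cv = mae(y, pred),
       ccc_cv = ccc(y, pred),
       predictions = pred)
}

#' Full validation report for a fitted model
#'
#' Training statistics (R2, RMSE, MAE, CCC, F), leave-one-out
#' cross-validation statistics (Q2, RMSE_cv, MAE_cv, CCC_cv) and, when a
#' test set is supplied, external statistics (R2, RMSE, MAE).
#'
#' @param model an `mlr_model` from [fit_mlr()]
#' @param X_train,y_train the training design and response used at fit time
#' @param X_test,y_test optional external test design and response
#' @return object of class `validation_report` (a list of named statistics)
#' @export
validation_report <- function(model, X_train, y_train,
                              X_test = NULL, y_test = NULL) {
  if (inherits(X_train, "descriptor_matrix")) X_train <- X_train$values
  X_train <- as.matrix(X_train)[, model$descriptors, drop = FALSE]
  pred_tr <- predict_mlr(model, X_train)
  k <- length(model$coefficients)
  cv <- q2_loo(X_train, y_train)
  rep <- list(
    n_train = length(y_train), k = k,
    r2_train = r_squared(y_train, pred_tr),
    rmse_train = rmse(y_train, pred_tr),
    mae_train = mae(y_train, pred_tr),
    ccc_train = ccc(y_train, pred_tr),
    f = f_statistic(y_train, pred_tr, k),
    q2_loo = cv$q2, rmse_cv = cv$rmse_cv,
    mae_cv = cv$mae_cv, ccc_cv = cv$ccc_cv
  )
  if (!is.null(X_test)) {
    if (inherits(X_test, "descriptor_matrix")) X_test <- X_test$values
    X_test <- as.matrix(X_test)[, model$descriptors, drop = FALSE]
    pred_te <- predict_mlr(model, X_test)
    rep$n_test <- length(y_test)
    rep$r2_test <- r_squared(y_test, pred_te)
    rep$rmse_test <- rmse(y_test, pred_te)
    rep$mae_test <- mae(y_test, pred_te)
  }
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  training (n = %d, k = %d): R2 %.3f RMSE %.4f MAE %.4f CCC %.3f F %.2f\n",
              x$n_train, x$k, x$r2_train, x$rmse_train, x$mae_train,
              x$ccc_train, x$f))
  cat(sprintf("  LOO cross-validation:      Q2 %.3f RMSE %.4f MAE %.4f CCC %.3f\n",
              x$q2_loo, x$rmse_cv, x$mae_cv, x$ccc_cv))
  if (!is.null(x$r2_test)) {
    cat(sprintf("  external test (n = %d):     R2 %.3f RMSE %.4f MAE %.4f\n",
                x$n_test, x$r2_test, x$rmse_test, x$mae_test))
  }
  invisible(x)
}

#' Predict from a fitted or published model
#'
#' Evaluates `intercept + sum(coefficient * value)` row-wise. Descriptor
#' values must already be on the scale the model was fitted on (the
#' published equations operate on z-scored descriptors; see
#' [apply_normalization()]).
#'
#' @param model an `mlr_model` or `published_model`
#' @param X matrix or named vector of descriptor values
#' @return numeric vector of predictions
#' @export
predict_mlr <- function(model, X) {
  if (inherits(X, "descriptor_matrix")) X <- X$values
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  miss <- setdiff(model$descriptors, colnames(X))
  if (length(miss)) stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  Xs <- as.matrix(X[, model$descriptors, drop = FALSE])
  drop(model$intercept + Xs %*% model$coefficients[model$descriptors])
}

#' @rdname predict_mlr
#' @param x descriptor values for a single compound (named vector)
#' @export
apply_model <- function(model, x) {
  unname(predict_mlr(model, x))
}

# ---- published models -------------------------------------------------

.published <- function(name, response, coefs, intercept) {
  structure(list(name = name, response = response,
                 intercept = intercept,
                 coefficients = coefs,
                 descriptors = names(coefs),
                 normalization = NULL),
            class = c("published_model", "mlr_model"))
}

#' The three frozen published model equations
#'
#' Model 1 (binding score affinity, Log BSA):
#'   `0.078 nR06 + 0.353 ATS4m - 0.294 BEle3 + 0.494`.
#' Model 2 (binding affinity, Log BA):
#'   `-0.116 S3K + 0.127 EEig03r + 0.145 H0e + 1.064`.
#' Model 3 (binding energy, Log BE):
#'   `-0.214 GATS8e - 0.301 Mor10u + 0.248 TPSA + 1.798`.
#' The coefficients apply to z-score-normalized descriptor values.
#'
#' @param which model number 1, 2 or 3
#' @return a `published_model` (immutable coefficient set)
#' @export
published_model <- function(which) {
  stopifnot(which %in% 1:3)
  switch(as.character(which),
    "1" = .published("Model 1", "LogBSA",
                     c(nR06 = 0.078, ATS4m = 0.353, BEle3 = -0.294), 0.494),
    "2" = .published("Model 2", "LogBA",
                     c(S3K = -0.116, EEig03r = 0.127, H0e = 0.145), 1.064),
    "3" = .published("Model 3", "LogBE",
                     c(GATS8e = -0.214, Mor10u = -0.301, TPSA = 0.248), 1.798)
  )
}

#' Descriptor significance profile
#'
#' Coefficients with signs ordered by decreasing magnitude, the data behind
#' the model significance bar plot.
#'
#' @param model an `mlr_model` or `published_model`
#' @return data frame with `descriptor`, `coefficient`, `sign`
#' @export
significance_profile <- function(model) {
  co <- model$coefficients
  ord <- order(-abs(co))
  data.frame(descriptor = names(co)[ord],
             coefficient = unname(co[ord]),
             sign = ifelse(co[ord] >= 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Serialize a model to a plain-text file
#'
#' @param model an `mlr_model`
#' @param path output path
#' @export
write_model <- function(model, path) {
  lines <- c(
    paste0("intercept\t", format(model$intercept, digits = 17)),
    vapply(model$descriptors, function(d) {
      paste0(d, "\t", format(model$coefficients[[d]], digits = 17))
    }, character(1))
  )
  if (!is.null(model$normalization)) {
    lines <- c(lines, vapply(names(model$normalization$mean), function(d) {
      paste0("norm\t", d, "\t",
             format(model$normalization$mean[[d]], digits = 17), "\t",
             format(model$normalization$sd[[d]], digits = 17))
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path file written by [write_model()]
#' @return an `mlr_model`
#' @export
read_model <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  coefs <- c(); intercept <- NA_real_
  nmu <- c(); nsd <- c()
  for (ln in lines) {
    if (ln[1] == "intercept") intercept <- as.numeric(ln[2])
    else if (ln[1] == "norm") {
      nmu[ln[2]] <- as.numeric(ln[3]); nsd[ln[2]] <- as.numeric(ln[4])
    } else coefs[ln[1]] <- as.numeric(ln[2])
  }
  norm <- if (length(nmu)) list(mean = nmu, sd = nsd) else NULL
  structure(list(intercept = intercept, coefficients = coefs,
                 descriptors = names(coefs), normalization = norm),
            class = "mlr_model")
}
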