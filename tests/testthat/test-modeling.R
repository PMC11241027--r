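test_that("OLS fitting reproduces the normal-equation solution", {
  set.seed(11)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(10, sd = 0.1)
  m <- fit_mlr(X, y)
  Xa <- cbind(1, X)
  beta_ref <- solve(t(Xa) %*% Xa) %*% t(Xa) %*% y
  expect_equal(m$intercept, beta_ref[1], tolerance = 1e-8)
  expect_equal(unname(m$coefficients), unname(beta_ref[-1]),
               tolerance = 1e-8)

  # exact linear response: zero residuals, R2 = 1
  y_exact <- 3 - X[, 1] + 0.5 * X[, 2]
  m2 <- fit_mlr(X, y_exact)
  expect_equal(max(abs(m2$residuals)), 0, tolerance = 1e-10)
  expect_equal(r_squared(y_exact, m2$fitted), 1, tolerance = 1e-12)

  # duplicated column is rejected by name
  Xd <- cbind(X, a2 = X[, "a"])
  expect_error(fit_mlr(Xd, y), "collinear")
  expect_error(fit_mlr(X[1:3, ], y[1:3]), "n > k")
})

test_that("validation statistics follow their closed forms", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(rep(1, 3), y), "variance")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(5, 8), 3)
  expect_equal(rmse(c(1, 0, 1, 0), c(0, 1, 0, 1)), 1)

  expect_equal(mae(y, y), 0)
  expect_equal(mae(c(0, 0), c(1, -3)), 2)

  expect_equal(ccc(y, y), 1)
  # location shift keeps Pearson r = 1 but lowers concordance
  expect_lt(ccc(y, y + 1), 1)
  expect_equal(cor(y, y + 1), 1)

  expect_true(is.infinite(f_statistic(c(1, 2, 3, 4), c(1, 2, 3, 4), 1)))
  # agreement with the standard anova F of lm on a random problem
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  yy <- X %*% c(1, -1, 0.5) + rnorm(20)
  fit <- lm(yy ~ X)
  f_ref <- summary(fit)$fstatistic[["value"]]
  expect_equal(f_statistic(yy, fitted(fit), 3), f_ref, tolerance = 1e-9)
})

test_that("concordance is bounded by Pearson correlation", {
  set.seed(99)
  for (rep_ in 1:1000) {
    a <- rnorm(8); b <- rnorm(8) + 0.3 * a
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
})

test_that("leave-one-out shortcut equals the explicit refit loop", {
  set.seed(21)
  for (rep_ in 1:25) {
    n <- sample(10:30, 1); k <- sample(1:4, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- X %*% rnorm(k) + rnorm(n)
    a <- q2_loo(X, y, method = "shortcut")
    b <- q2_loo(X, y, method = "refit")
    expect_equal(a$predictions, b$predictions, tolerance = 1e-9)
    expect_equal(a$q2, b$q2, tolerance = 1e-9)
  }
})

test_that("Q2 never exceeds R2 and reaches 1 on exact data", {
  X <- matrix(rnorm(40), 20, 2)
  y_exact <- 2 + X %*% c(1, -2)
  expect_equal(q2_loo(X, y_exact)$q2, 1, tolerance = 1e-9)

  set.seed(5)
  for (rep_ in 1:50) {
    X <- matrix(rnorm(90), 30, 3)
    y <- rnorm(30)  # pure noise
    m <- fit_mlr(X, y)
    r2 <- r_squared(y, m$fitted)
    q2 <- q2_loo(X, y)$q2
    expect_lte(q2, r2 + 1e-12)
  }
})

test_that("published equations evaluate exactly at reference points", {
  m1 <- published_model(1)
  expect_equal(apply_model(m1, c(nR06 = 0, ATS4m = 0, BEle3 = 0)), 0.494)
  m2 <- published_model(2)
  expect_equal(apply_model(m2, c(S3K = 0, EEig03r = 0, H0e = 0)), 1.064)
  m3 <- published_model(3)
  expect_equal(apply_model(m3, c(GATS8e = 1, Mor10u = 0, TPSA = 0)),
               1.798 - 0.214, tolerance = 1e-12)
  expect_error(apply_model(m1, c(nR06 = 0, ATS4m = 0)), "BEle3")
})

test_that("significance profiles order and sign coefficients correctly", {
  p1 <- significance_profile(published_model(1))
  expect_equal(p1$descriptor[1], "ATS4m")            # largest magnitude
  expect_equal(p1$descriptor[3], "nR06")             # smallest
  expect_equal(p1$sign[p1$descriptor == "nR06"], "+")
  expect_equal(p1$sign[p1$descriptor == "ATS4m"], "+")
  expect_equal(p1$sign[p1$descriptor == "BEle3"], "-")

  p3 <- significance_profile(published_model(3))
  expect_equal(p3$sign[p3$descriptor == "TPSA"], "+")
  expect_equal(p3$sign[p3$descriptor == "GATS8e"], "-")
  expect_equal(p3$sign[p3$descriptor == "Mor10u"], "-")
})

test_that("validation reports satisfy their internal inequalities", {
  set.seed(8)
  for (rep_ in 1:10) {
    X <- matrix(rnorm(80), 20, 4,
                dimnames = list(NULL, paste0("d", 1:4)))
    y <- X %*% rnorm(4) + rnorm(20, sd = 0.5)
    m <- fit_mlr(X, y)
    rep <- validation_report(m, X, y)
    expect_lte(rep$mae_train, rep$rmse_train)
    expect_lte(rep$mae_cv, rep$rmse_cv)
    expect_lte(rep$q2_loo, rep$r2_train + 1e-12)
    expect_lte(rep$r2_train, 1)
    expect_gte(rep$ccc_train, -1); expect_lte(rep$ccc_train, 1)
    # R2 equals squared Pearson correlation for OLS with intercept
    expect_equal(rep$r2_train, cor(as.numeric(y), m$fitted)^2,
                 tolerance = 1e-9)
  }
})

test_that("model serialization round-trips", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- rnorm(10)
  m <- fit_mlr(X, y)
  m$normalization <- list(mean = setNames(rnorm(4), paste0("d", 1:4)),
                          sd = setNames(runif(4, 0.5, 2), paste0("d", 1:4)))
  path <- tempfile(fileext = ".tsv")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$normalization$mean, m$normalization$mean)
  Xnew <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, paste0("d", 1:4)))
  expect_equal(predict_mlr(m2, Xnew), predict_mlr(m, Xnew))
})
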