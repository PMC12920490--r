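test_that("PLSR at K = p reproduces OLS predictions", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- as.numeric(X %*% rnorm(5) + rnorm(50))
    f <- plsr_fit(X, y, K = 5)
    ols <- fitted(lm(y ~ X))
    expect_lt(max(abs(predict(f, X) - ols)), 1e-6)
  }
})

test_that("PLSR matches an independent SIMPLS implementation", {
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- as.numeric(X %*% rnorm(6) + rnorm(40))
  f <- plsr_fit(X, y, K = 3)
  m <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  pm <- predict(m, X)$predict[, 1, 3]
  expect_lt(max(abs(predict(f, X, K = 3) - pm)), 1e-8)
})

test_that("structural identities: rank-1, orthonormal X, duplicates", {
  set.seed(21)
  w <- rnorm(5)
  Xr <- outer(rnorm(20), w)
  colnames(Xr) <- paste0("x", 1:5)
  yr <- as.numeric(Xr %*% rnorm(5))
  fr <- plsr_fit(Xr, yr, K = 1)
  expect_lt(sqrt(sum((predict(fr, Xr) - yr)^2)), 1e-8)

  # orthonormal centred columns: raw-scale weights at K = p proportional to
  # the marginal covariances cov(x_j, y)
  M <- matrix(rnorm(30 * 4), 30, 4)
  Q <- qr.Q(qr(scale(M, scale = FALSE)))
  colnames(Q) <- paste0("q", 1:4)
  yq <- as.numeric(Q %*% c(2, -1, 0.5, 0) + rnorm(30, sd = 0.1))
  fq <- plsr_fit(Q, yq, K = 4)
  covs <- as.numeric(cov(Q, yq))
  ratio <- (fq$weights / apply(Q, 2, sd)) / covs
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)

  # duplicated predictors share their weight symmetrically
  set.seed(22)
  x1 <- rnorm(40); x2 <- rnorm(40)
  Xd <- cbind(a = x1, b = x1, c = x2)
  yd <- x1 + 0.5 * x2 + rnorm(40, sd = 0.2)
  fd <- plsr_fit(Xd, yd, K = 2)
  expect_lt(abs(fd$weights["a"] - fd$weights["b"]), 1e-8)

  # weight sign follows the marginal covariance
  set.seed(23)
  xs <- rnorm(40)
  Xs <- cbind(s = xs, n = rnorm(40))
  ys <- -2 * xs + rnorm(40, sd = 0.1)
  fs <- plsr_fit(Xs, ys, K = 1)
  expect_lt(fs$weights["s"], 0)
})

test_that("input validation: constant columns, rank, K bounds", {
  X <- cbind(a = rnorm(20), b = rep(3, 20))
  expect_error(plsr_fit(X, rnorm(20), K = 1), "b")
  X2 <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(plsr_fit(X2, rnorm(20), K = 4), "K exceeds")
  Xr <- outer(rnorm(20), rnorm(4)) + 0  # rank 1
  colnames(Xr) <- paste0("x", 1:4)
  expect_error(plsr_fit(Xr, rnorm(20), K = 3), "effective rank")
})

test_that("nested LOO CV selects parsimoniously and never leaks", {
  set.seed(31)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- as.numeric(X[, 1] - X[, 2] + rnorm(30, sd = 0.5))
  cv <- nested_loo_cv(X, y, K_max = 6)
  expect_length(cv$predictions, 30)
  expect_true(all(cv$chosen_k >= 1 & cv$chosen_k <= 6))

  # leakage: changing the held-out response must not move its prediction
  for (i in c(1, 17, 30)) {
    y2 <- y
    y2[i] <- y2[i] + 100
    cv2 <- nested_loo_cv(X, y2, K_max = 6)
    expect_equal(cv2$predictions[i], cv$predictions[i], tolerance = 1e-10)
  }

  # r is invariant to affine rescaling of y
  cv3 <- nested_loo_cv(X, 3 * y + 11, K_max = 6)
  expect_equal(cv3$r, cv$r, tolerance = 1e-10)

  expect_error(nested_loo_cv(X[1:8, ], y[1:8]), "n >= 10")
})

test_that("a leaked response column drives r to 1", {
  set.seed(32)
  y <- rnorm(25)
  X <- cbind(leak = y, noise = rnorm(25))
  expect_gte(nested_loo_cv(X, y, K_max = 2)$r, 0.99)
})

test_that("modal K rule: mode, tie toward smallest, all-distinct median", {
  expect_equal(bodysense:::modal_k(c(2, 2, 3, 1)), 2L)
  expect_equal(bodysense:::modal_k(c(1, 1, 2, 2, 5)), 1L)
  expect_equal(bodysense:::modal_k(c(1, 2, 3, 4)), 2L)
})

test_that("permutation inference: add-one p-value and null behaviour", {
  set.seed(41)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1, -1, 0.5))  # noiseless
  pi0 <- permutation_inference(X, y, K_max = 3, n_perm = 200, seed = 5)
  expect_gte(pi0$r, 0.99)
  expect_equal(pi0$p_perm, 1 / 201)

  expect_error(permutation_inference(X, y, n_perm = 100, seed = 5), "200")
  expect_error(permutation_inference(X, y, n_perm = 500), "seed")

  # same seed -> identical result; different seed -> same observed r
  pi1 <- permutation_inference(X, y, K_max = 3, n_perm = 200, seed = 5)
  expect_identical(pi0$weights, pi1$weights)
  expect_identical(pi0$p_perm, pi1$p_perm)
})

test_that("missing predictor cells are median-imputed inside folds", {
  set.seed(51)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- as.numeric(X[, 1] + rnorm(30, sd = 0.3))
  Xm <- X
  Xm[c(3, 11), 2] <- NA
  cv <- nested_loo_cv(Xm, y, K_max = 3)
  expect_true(all(is.finite(cv$predictions)))
  expect_gt(cv$r, 0.5)
})

test_that("planted sparse support is flagged, strong effects recovered", {
  set.seed(61)
  X <- matrix(rnorm(60 * 10), 60, 10, dimnames = list(NULL, paste0("v", 1:10)))
  y <- as.numeric(1.2 * X[, 7] + rnorm(60, sd = 0.8))
  pi <- permutation_inference(X, y, K_max = 6, n_perm = 300, seed = 9)
  expect_true(pi$significant["v7"])
  expect_lte(sum(pi$significant[-7]), 2)
  expect_lt(pi$p_perm, 0.05)
})
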