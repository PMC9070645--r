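test_that("standardization uses training statistics and flags fixed markers", {
  x <- matrix(c(0, 1, 2, 1, 1, 1), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  std <- standardizeDosages(x)
  expect_equal(std$centers[["a"]], 1)
  expect_equal(sum(std$X[, "a"]), 0)
  expect_equal(std$sds[["a"]], sqrt(mean((x[, "a"] - 1)^2)))  # population sd
  expect_true(std$zeroSd[["b"]])
  expect_true(all(std$X[, "b"] == 0))
  # applying training statistics back reproduces the matrix
  again <- standardizeDosages(x, std$centers, std$sds)
  expect_identical(again$X, std$X)
  # a validation column identical to a training column maps identically
  xv <- x[c(1, 1, 2, 3), ]
  sv <- standardizeDosages(xv, std$centers, std$sds)
  expect_identical(sv$X[2:4, "a"], std$X[, "a"])
})

test_that("ridge coordinate descent matches the closed form on 20 problems", {
  for (s in 1:20) {
    set.seed(s)
    n <- 30; p <- 50
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("m%02d", 1:p)))
    y <- rnorm(n)
    std <- standardizeDosages(X)
    lam <- runif(1, 0.05, 1)
    m <- fitPenalized(std$X, y, "RR", lam, std, tol = 1e-10)
    closed <- solve(crossprod(std$X) / n + lam * diag(p),
                    crossprod(std$X, y - mean(y)) / n)
    expect_lt(max(abs(m@effects - closed)), 1e-6)
    expect_equal(m@intercept, mean(y))
  }
})

test_that("LASSO reduces to soft-thresholding on orthonormal designs", {
  set.seed(30)
  n <- 40; p <- 8
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  X <- sqrt(n) * Q                       # X'X / n = I exactly
  colnames(X) <- sprintf("m%d", 1:p)
  y <- rnorm(n)
  lam <- 0.1
  m <- fitPenalized(X, y, "LASSO", lam, tol = 1e-12)
  z <- as.numeric(crossprod(X, y - mean(y))) / n
  soft <- sign(z) * pmax(abs(z) - lam, 0)
  expect_lt(max(abs(m@effects - soft)), 1e-8)
  # lambda >= lambda_max nulls every effect
  m0 <- fitPenalized(X, y, "LASSO", max(abs(z)) * 1.0001)
  expect_true(all(m0@effects == 0))
  expect_equal(m0@nZero, p)
})

test_that("LASSO solutions satisfy the KKT conditions", {
  set.seed(31)
  n <- 60; p <- 120
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("m%d", 1:p)))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n)
  std <- standardizeDosages(X)
  lam <- 0.08
  m <- fitPenalized(std$X, y, "LASSO", lam, std, tol = 1e-10)
  r <- y - mean(y) - std$X %*% m@effects
  g <- abs(as.numeric(crossprod(std$X, r)) / n)
  expect_true(all(g[m@effects == 0] <= lam + 1e-6))
  expect_true(all(abs(g[m@effects != 0] - lam) <= 1e-6))
})

test_that("the coordinate-descent objective never increases", {
  set.seed(32)
  n <- 50; p <- 80
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("m%d", 1:p)))
  y <- rnorm(n)
  std <- standardizeDosages(X)
  for (meth in c("RR", "LASSO")) {
    m <- fitPenalized(std$X, y, meth, 0.05, std)
    obj <- attr(m, "objective")
    expect_true(all(diff(obj) <= 1e-12))
  }
})

test_that("ridge predictions shrink toward the mean as lambda grows", {
  set.seed(33)
  n <- 40; p <- 25
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("m%d", 1:p)))
  y <- X[, 1] + rnorm(n)
  std <- standardizeDosages(X)
  vars <- sapply(c(0.01, 0.1, 1, 10), function(l) {
    m <- fitPenalized(std$X, y, "RR", l, std, tol = 1e-9)
    var(as.numeric(std$X %*% m@effects))
  })
  expect_true(all(diff(vars) <= 1e-10))
})

test_that("near-zero shrinkage on n > p data reproduces least squares", {
  set.seed(34)
  n <- 80; p <- 12
  X <- matrix(sample(0:2, n * p, TRUE), n, p,
              dimnames = list(sprintf("i%d", 1:n), sprintf("m%d", 1:p)))
  y <- as.numeric(X %*% rnorm(p)) + rnorm(n)
  std <- standardizeDosages(X)
  m <- fitPenalized(std$X, y, "RR", 1e-9, std, tol = 1e-12,
                    maxIter = 100000)
  fitted <- as.numeric(std$X %*% m@effects) + m@intercept
  ols <- lm.fit(cbind(1, std$X), y)$fitted.values
  expect_lt(max(abs(fitted - ols)), 1e-5)
})

test_that("our penalized fits agree with glmnet as an independent check", {
  set.seed(35)
  n <- 50; p <- 70
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("m%d", 1:p)))
  y <- X[, 3] + rnorm(n)
  std <- standardizeDosages(X)
  # LASSO against glmnet (the ridge path has its exact closed-form oracle
  # above; glmnet's alpha = 0 mode rescales lambda internally and is not a
  # like-for-like comparison at a single penalty value)
  ml <- fitPenalized(std$X, y, "LASSO", 0.07, std, tol = 1e-11)
  gl <- glmnet::glmnet(std$X, y, alpha = 1, lambda = 0.07,
                       standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(as.numeric(gl$beta) - ml@effects)), 1e-4)
})

test_that("lambda calibration is seeded, noise-averse and signal-seeking", {
  set.seed(36)
  X <- matrix(rnorm(100 * 50), 100, 50,
              dimnames = list(NULL, sprintf("m%d", 1:50)))
  std <- standardizeDosages(X)
  y <- rnorm(100)
  c1 <- calibrateLambda(std$X, y, "RR", seed = 4, gridSize = 40)
  c2 <- calibrateLambda(std$X, y, "RR", seed = 4, gridSize = 40)
  expect_identical(c1$folds, c2$folds)
  expect_identical(c1$lambda, c2$lambda)
  # pure noise: selected lambda in the largest decile of the grid
  topDecile <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    yn <- rnorm(100)
    cal <- calibrateLambda(std$X, yn, "RR", seed = s, gridSize = 40)
    if (match(cal$lambda, cal$grid) <= 4) topDecile <- topDecile + 1
  }
  expect_gte(topDecile, 40)
  # strong sparse signal: CV error at the selected lambda beats the null
  wins <- 0
  for (s in 1:50) {
    set.seed(2000 + s)
    Xs <- matrix(rnorm(300 * 100), 300, 100)
    colnames(Xs) <- sprintf("m%d", 1:100)
    ys <- as.numeric(Xs[, 1:5] %*% rep(2, 5)) + rnorm(300)
    stds <- standardizeDosages(Xs)
    cal <- calibrateLambda(stds$X, ys, "LASSO", seed = s, gridSize = 30)
    if (min(cal$cvError) < var(ys)) wins <- wins + 1
  }
  expect_gte(wins, 48)
})

test_that("prediction applies the training standardization and is affine", {
  set.seed(37)
  n <- 40; p <- 15
  X <- matrix(sample(0:2, n * p, TRUE), n, p,
              dimnames = list(sprintf("i%d", 1:n), sprintf("m%d", 1:p)))
  y <- rnorm(n)
  m <- trainMarkerModel(X, setNames(y, rownames(X)), "RR", gridSize = 10,
                        seed = 1)
  # parental-average linearity: exact by the affine prediction map
  d1 <- X[1, ]; d2 <- X[2, ]
  avg <- matrix((d1 + d2) / 2, 1, dimnames = list("avg", colnames(X)))
  pr <- predict(m, X[1:2, ])
  expect_equal(unname(predict(m, avg)), unname(mean(pr)),
               tolerance = 1e-12)
  # all-zero effects predict the intercept
  m0 <- m; m0@effects[] <- 0
  expect_true(all(predict(m0, X) == m0@intercept))
  # marker mismatch errors with the missing ids
  expect_error(predict(m, X[, 1:5]), "missing")
  expect_error(fitPenalized(standardizeDosages(X)$X, y, "RR", -1), "lambda")
})
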