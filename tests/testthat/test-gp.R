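test_that("the ARD kernel matches its closed form and the loop oracle", {
  hp <- gpHyperparams(1.5, c(2, 0.5), 0.1)
  x <- matrix(c(0.3, -1.2), 1, 2)
  expect_equal(as.numeric(ardKernel(x, x, hp)), 1.5)

  K <- ardKernel(matrix(c(0, 1e6), 1, 2), matrix(c(0, 0), 1, 2), hp)
  expect_true(is.finite(K) && K >= 0 && K < 1e-300)

  set.seed(4)
  X1 <- matrix(rnorm(6), 3, 2)
  X2 <- matrix(rnorm(6), 3, 2)
  expect_equal(ardKernel(X1, X2, hp),
               ardKernelOracle(X1, X2, 1.5, c(2, 0.5)),
               tolerance = 1e-12)
  expect_error(ardKernel(X1, matrix(0, 2, 3), hp), "mismatch")
})

test_that("kernel matrices are symmetric positive semi-definite", {
  set.seed(11)
  for (i in 1:10) {
    X <- matrix(rnorm(40 * 3), 40, 3)
    hp <- gpHyperparams(exp(runif(1, -1, 2)), exp(runif(3, -1, 1)), 0.1)
    K <- ardKernel(X, X, hp)
    expect_equal(K, t(K), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(K)))
  }
})

test_that("the log marginal likelihood matches closed forms and finite differences", {
  # n = 1, y = 0: -1/2 log(sf2 + sn2) - 1/2 log 2 pi
  hp <- gpHyperparams(2, 1, 0.5)
  got <- logMarginalLikelihood(matrix(0, 1, 1), 0, hp)
  expect_equal(got$value, -0.5 * log(2.5) - 0.5 * log(2 * pi),
               tolerance = 1e-12)

  # analytic gradient vs central differences on a 10-point set
  set.seed(5)
  X <- matrix(rnorm(20), 10, 2)
  y <- sin(X[, 1]) + 0.1 * rnorm(10)
  p0 <- c(0.3, -0.2, 0.4, -2)
  asHp <- function(p) gpHyperparams(exp(p[1]), exp(p[2:3]), exp(p[4]))
  g <- logMarginalLikelihood(X, y, asHp(p0))$gradient
  h <- 1e-5
  for (j in seq_along(p0)) {
    pp <- p0; pp[j] <- pp[j] + h
    pm <- p0; pm[j] <- pm[j] - h
    fd <- (logMarginalLikelihood(X, y, asHp(pp))$value -
           logMarginalLikelihood(X, y, asHp(pm))$value) / (2 * h)
    expect_lt(abs(g[j] - fd), 1e-5)
  }

  # duplicated training point with identical target: jitter path, finite
  Xd <- rbind(X, X[1, , drop = FALSE])
  yd <- c(y, y[1])
  hpTight <- gpHyperparams(1, c(1, 1), 1e-12)
  expect_true(is.finite(logMarginalLikelihood(Xd, yd, hpTight)$value))
})

test_that("a noise-free smooth function is interpolated at training points", {
  x <- matrix(seq(-2, 2, length.out = 15), ncol = 1)
  y <- 1.3 * x[, 1]^2 - 0.5 * x[, 1]
  m <- gpFit(x, y, seed = 2)
  p <- gpPredict(m, x)
  expect_lt(max(abs(p$mean - y)), 1e-6)
  # optimizer trace: objective non-decreasing across accepted steps
  expect_true(all(diff(m@trace) >= 0))
})

test_that("hyperparameters are recovered on data simulated from a known GP", {
  set.seed(20)
  n <- 200
  X <- matrix(runif(n * 2, -3, 3), n, 2)
  truth <- gpHyperparams(1, c(1, 1), 0.01)
  K <- ardKernel(X, X, truth) + diag(0.01, n)
  y <- as.numeric(t(chol(K)) %*% rnorm(n))
  m <- gpFit(X, y, seed = 3, standardize = FALSE)
  hp <- hyperparams(m)
  expect_lt(abs(log(hp@signalVariance) - log(1)), 0.5)
  expect_lt(max(abs(log(hp@lengthScales) - 0)), 0.5)
  expect_lt(abs(log(hp@noiseVariance) - log(0.01)), 0.5)
})

test_that("predictions revert to the prior far from the data and match the dense oracle", {
  set.seed(6)
  X <- matrix(rnorm(10), 5, 2)
  y <- 5 + rnorm(5)
  hp <- gpHyperparams(1.2, c(0.8, 1.1), 0.05)
  m <- gpFit(X, y, hp = hp, standardize = FALSE)

  far <- matrix(c(50, -60), 1, 2)
  p <- gpPredict(m, far)
  expect_equal(p$mean, mean(y), tolerance = 1e-9)
  expect_equal(p$variance, 1.2, tolerance = 1e-9)

  Xs <- matrix(rnorm(8), 4, 2)
  got <- gpPredict(m, Xs)
  want <- gpPredictOracle(X, y - mean(y), Xs, hp)
  expect_equal(got$mean, want$mean + mean(y), tolerance = 1e-10)
  expect_equal(got$variance, want$variance, tolerance = 1e-10)

  # query at a training point with vanishing noise reproduces the target
  hp0 <- gpHyperparams(1, c(1, 1), 1e-10)
  m0 <- gpFit(X, y, hp = hp0, standardize = FALSE)
  p0 <- gpPredict(m0, X[3, , drop = FALSE])
  expect_lt(abs(p0$mean - y[3]), 1e-6)
})

test_that("predictions are invariant to consistent feature permutations", {
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3)
  y <- X[, 1] - 2 * X[, 3] + 0.05 * rnorm(20)
  hp <- gpHyperparams(1, c(0.7, 1.3, 2.1), 0.01)
  m <- gpFit(X, y, hp = hp, standardize = FALSE)
  perm <- c(3, 1, 2)
  hpP <- gpHyperparams(1, hp@lengthScales[perm], 0.01)
  mP <- gpFit(X[, perm], y, hp = hpP, standardize = FALSE)
  Xq <- matrix(rnorm(15), 5, 3)
  expect_equal(gpPredict(m, Xq)$mean, gpPredict(mP, Xq[, perm])$mean,
               tolerance = 1e-10)
})

test_that("GP model JSON serialization carries the hyperparameters", {
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  m <- gpFit(X, y, hp = gpHyperparams(1, c(1, 1), 0.1))
  path <- tempfile(fileext = ".json")
  writeGPModelJSON(m, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$hyperparams$signal_variance, 1)
  expect_equal(obj$n_train, 10)
  expect_match(obj$training_data_md5, "^[0-9a-f]{32}$")
})
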