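test_that("Cronbach's alpha matches its variance-decomposition arithmetic", {
  # orthogonalized columns: zero pairwise covariance means alpha = 0
  set.seed(71)
  X <- matrix(rnorm(60), 20, 3)
  # QR of the centered matrix: columns stay centered and become orthogonal
  X <- qr.Q(qr(scale(X, scale = FALSE)))
  expect_equal(cronbach_alpha(X)$alpha, 0, tolerance = 1e-10)
  # three copies of one variable: perfect consistency
  v <- rnorm(25)
  expect_equal(cronbach_alpha(cbind(v, v, v))$alpha, 1, tolerance = 1e-12)
  # small fixture against the hand-computed decomposition
  Y <- matrix(c(1, 2, 3, 4, 5,
                2, 2, 4, 5, 4,
                1, 3, 3, 5, 6,
                2, 1, 4, 4, 5), 5, 4)
  k <- 4
  want <- k / (k - 1) * (1 - sum(apply(Y, 2, var)) / var(rowSums(Y)))
  expect_equal(cronbach_alpha(Y)$alpha, want, tolerance = 1e-12)
  ci <- cronbach_alpha(Y)$ci
  expect_true(ci[1] < want && want < ci[2])
})

test_that("alpha on parallel items obeys the Spearman-Brown closed form", {
  for (k in c(3, 8, 19)) {
    for (rho in c(0.2, 0.35)) {
      R <- matrix(rho, k, k); diag(R) <- 1
      expect_equal(alpha_from_cov(R), k * rho / (1 + (k - 1) * rho),
                   tolerance = 1e-6)
    }
  }
})

test_that("correlation intervals behave at the boundaries and under sampling", {
  x <- rnorm(50)
  expect_equal(correlation_with_ci(x, x)$r, 1)
  expect_equal(correlation_with_ci(x, -x)$r, -1)
  expect_error(correlation_with_ci(x, rep(1, 50)), "zero variance")
  # Fisher-z oracle computed inline
  y <- x + rnorm(50)
  got <- correlation_with_ci(x, y)
  r <- cor(x, y)
  want <- tanh(atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(50 - 3))
  expect_equal(got$ci, want, tolerance = 1e-12)
  # seeded coverage check at the published design size
  set.seed(569)
  xs <- rnorm(569); ys <- 0.9 * xs + sqrt(1 - 0.81) * rnorm(569)
  ci <- correlation_with_ci(xs, ys)$ci
  expect_true(ci[1] <= 0.9 && 0.9 <= ci[2])
})

test_that("CFA is exact on an implied covariance and matches factanal elsewhere", {
  lam <- c(0.8, 0.7, 0.6, 0.5, 0.75, 0.65)
  Sig <- tcrossprod(lam) + diag(1 - lam^2)
  fit <- cfa_one_factor(Sig, n = 500)
  expect_equal(fit$chi2, 0, tolerance = 1e-6)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$cfi, 1)
  expect_lt(fit$srmr, 1e-6)
  expect_equal(abs(fit$loadings), lam, tolerance = 1e-4)

  # sampled data: the ML discrepancy minimum must match factanal's
  set.seed(73)
  X <- tcrossprod(rnorm(400), lam[1:5]) + matrix(rnorm(2000), 400, 5) %*%
    diag(sqrt(1 - lam[1:5]^2))
  got <- cfa_one_factor(X)
  fa <- factanal(X, factors = 1)
  expect_equal(got$F_ml, fa$criteria[["objective"]], tolerance = 1e-6)
})

test_that("the CFA minimum survives independent random-start optimization", {
  set.seed(79)
  dat <- quick_sample(n = 400, k = 5, seed = 79)
  X <- dat$responses
  fit <- cfa_one_factor(X)
  S <- cov(X); p <- 5
  fml <- function(par) {
    Sg <- tcrossprod(par[1:p]) + diag(exp(par[p + 1:p]), p)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S) -
      determinant(S)$modulus[1] - p
  }
  best <- Inf
  for (s in 1:10) {
    st <- c(runif(p, 0.2, 1.5) * sample(c(-1, 1), p, TRUE), log(runif(p, 0.2, 2)))
    o <- optim(st, fml, method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$F_ml, as.numeric(best), tolerance = 1e-6)
})

test_that("fit indices meet the adequacy cutoffs for a well-specified model", {
  set.seed(83)
  n <- 500; lam <- runif(6, 0.5, 0.8)
  X <- tcrossprod(rnorm(n), lam) +
    matrix(rnorm(6 * n), n, 6) %*% diag(sqrt(1 - lam^2))
  fit <- cfa_one_factor(X)
  expect_lte(fit$rmsea, 0.08)
  expect_lte(fit$srmr, 0.08)
  expect_gte(fit$cfi, 0.90)
  expect_true(fit$rmsea_ci90[1] <= fit$rmsea & fit$rmsea <= fit$rmsea_ci90[2])
})

test_that("information retention is a scale-invariant percentage", {
  expect_equal(information_retention(5, 5), 100.0)
  expect_equal(information_retention(3.3, 9.9), information_retention(33, 99))
  expect_error(information_retention(1, 0), "positive")
})

test_that("evaluating the full set against itself is the identity comparison", {
  dat <- quick_sample(n = 300, k = 5, seed = 89)
  model <- fit_gpcm(dat)
  ev <- evaluate_short_form(dat, 1:5, model)
  tr <- ev$training
  expect_equal(tr$r_summed$r, 1)
  expect_equal(tr$r_factor$r, 1)
  expect_equal(tr$alpha_subset$alpha, tr$alpha_full$alpha)
  expect_equal(tr$information$retention_full, 100.0)
})

test_that("alpha is stable across disjoint half-samples of one population", {
  dat <- quick_sample(n = 800, k = 6, seed = 97)
  x <- dat$responses
  a1 <- cronbach_alpha(x[1:400, ])
  a2 <- cronbach_alpha(x[401:800, ])
  expect_true(a1$ci[1] <= a2$ci[2] && a2$ci[1] <= a1$ci[2])
})
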