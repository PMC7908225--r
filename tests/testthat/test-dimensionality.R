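test_that("polychoric correlations recover latent correlations", {
  set.seed(3)
  n <- 40000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  cuts <- c(-Inf, -1, -0.3, 0.4, 1.1, Inf)
  x <- cut(z1, cuts, labels = FALSE)
  y <- cut(z2, cuts, labels = FALSE)
  R <- polychoric_matrix(cbind(x, y, x))
  expect_equal(R[1, 2], 0.5, tolerance = 0.02)
  # duplicated column: essentially perfect latent correlation
  expect_gte(R[1, 3], 0.999)
  # structure: exactly unit diagonal, symmetric to numerical precision
  expect_identical(unname(diag(R)), rep(1, 3))
  expect_lt(max(abs(R - t(R))), 1e-10)
  # independent items
  w <- cut(rnorm(n), cuts, labels = FALSE)
  expect_lt(abs(polychoric_matrix(cbind(x, w))[1, 2]), 0.02)
  # degenerate pair errors informatively
  expect_error(polychoric_matrix(cbind(x[1:50], rep(1L, 50))), "degenerate")
})

test_that("KMO behaves as the anti-image algebra dictates", {
  # uniformly strong one-factor structure: excellent adequacy
  lam <- rep(0.8, 10)
  R1 <- tcrossprod(lam) + diag(1 - lam^2)
  expect_gt(kmo_statistic(R1), 0.9)
  # 2 x 2: the partial equals the raw correlation, so KMO is exactly 1/2
  for (r in c(0.2, -0.5, 0.9)) {
    expect_equal(kmo_statistic(matrix(c(1, r, r, 1), 2)), 0.5, tolerance = 1e-12)
  }
  # near-diagonal matrix: partials track raws, KMO around or below 1/2
  set.seed(6)
  E <- matrix(rnorm(64, 0, 0.03), 8); E <- (E + t(E)) / 2; diag(E) <- 0
  expect_lte(kmo_statistic(diag(8) + E), 0.55)
})

test_that("Bartlett's sphericity statistic matches its closed form", {
  R_id <- diag(5)
  out <- bartlett_sphericity(R_id, 100)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(bartlett_sphericity(diag(21), 500)$df, 210)
  # direct determinant arithmetic on a fixture matrix
  R <- matrix(0.3, 4, 4); diag(R) <- 1
  got <- bartlett_sphericity(R, 80)
  want_stat <- -(80 - 1 - (2 * 4 + 5) / 6) * log(det(R))
  expect_equal(got$statistic, want_stat, tolerance = 1e-12)
  expect_equal(got$p_value, pchisq(want_stat, 6, lower.tail = FALSE))
})

test_that("minres factoring recovers noiseless one-factor structure", {
  lam <- c(0.7, 0.65, 0.8, 0.5, 0.6, 0.75)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  efa <- minres_efa(R, 1)
  expect_equal(as.vector(efa$loadings), lam, tolerance = 1e-4)
  expect_lt(efa$objective, 1e-8)
  expect_gte(sum(efa$loadings[, 1]), 0)   # sign convention
})

test_that("minres solution is locally optimal against random restarts", {
  set.seed(17)
  dat <- quick_sample(n = 400, k = 8, seed = 17)
  R <- polychoric_matrix(dat)
  efa <- minres_efa(R, 1)
  p <- ncol(R); off <- upper.tri(R)
  obj <- function(psi) {
    e <- eigen(R - diag(psi, p), symmetric = TRUE)
    L <- e$vectors[, 1, drop = FALSE] * sqrt(max(e$values[1], 0))
    2 * sum((R - tcrossprod(L))[off]^2)
  }
  for (r in 1:20) expect_lte(efa$objective, obj(runif(p, 0.05, 0.95)) + 1e-10)
})

test_that("a two-block structure fails the unidimensionality gate", {
  blk <- matrix(0.6, 5, 5); diag(blk) <- 1
  z5 <- matrix(0, 5, 5)
  R <- rbind(cbind(blk, z5), cbind(z5, blk))
  efa <- minres_efa(R, 2)
  chk <- unidimensionality_check(efa)
  expect_lt(chk$eigenvalue_ratio, 3)
  expect_false(chk$pass)
})

test_that("the unidimensionality decision applies the published rule", {
  fake <- structure(list(eigenvalues = c(5.1, 1.3),
                         variance_explained = c(0.241, 0.061),
                         loadings = matrix(rep(0.5, 10)),
                         flagged_items = integer(0)),
                    class = "efa_result")
  chk <- unidimensionality_check(fake)
  expect_true(chk$pass)
  expect_equal(chk$eigenvalue_ratio, 5.1 / 1.3)
  expect_length(chk$remove_items, 0)
  # identical input gives an identical decision (pure function)
  expect_identical(chk, unidimensionality_check(fake))

  fake$eigenvalues <- c(2, 1)
  expect_false(unidimensionality_check(fake)$pass)
})

test_that("a planted reverse-oriented item gets a negative loading and is flagged", {
  cfg <- synthetic_config(n_persons = 600, n_items = 8,
                          discrimination_range = c(0.6, 1.6),
                          reversed_items = 4,
                          covariate_correlations = numeric(0), seed = 23)
  dat <- simulate_responses(generate_true_model(cfg), cfg)
  efa <- efa_screen(dat)
  expect_identical(efa$flagged_items, 4L)
  expect_gt(efa$kmo, 0.6)
  expect_lt(efa$bartlett$p_value, 0.001)
})
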