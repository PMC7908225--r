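test_that("category probabilities follow the adjacent-category logistic form", {
  # zero discrimination gives a uniform distribution at any trait level
  p <- category_probabilities(gpcm_item(0, c(-1, 0, 0.5, 1, 2)), c(-2, 0, 3))
  expect_equal(p, matrix(1 / 6, 3, 6), tolerance = 1e-12)
  # a binary item at its step difficulty is an even coin for any slope
  for (a in c(0.3, 1, 2.5)) {
    expect_equal(as.vector(category_probabilities(gpcm_item(a, 0.4), 0.4)),
                 c(0.5, 0.5), tolerance = 1e-12)
  }
  # long-form brute-force summation agrees on randomized items
  set.seed(4)
  for (r in 1:20) {
    m <- sample(2:7, 1)
    it <- gpcm_item(runif(1, 0, 2), sort(rnorm(m - 1, 0, 1.2)))
    th <- rnorm(1, 0, 2)
    expect_equal(as.vector(category_probabilities(it, th)),
                 brute_gpcm_prob(it$a, it$b, th), tolerance = 1e-10)
    expect_equal(sum(category_probabilities(it, th)), 1, tolerance = 1e-12)
  }
  # the documented worked case
  expect_equal(as.vector(category_probabilities(gpcm_item(1.2, c(-1, 0, 1)), 0.3)),
               brute_gpcm_prob(1.2, c(-1, 0, 1), 0.3), tolerance = 1e-12)
})

test_that("marginal log-likelihood matches a high-resolution quadrature oracle", {
  # single person, single binary item with zero slope: exactly log(1/2)
  m0 <- gpcm_model(list(gpcm_item(0, 0)))
  d0 <- response_matrix(matrix(1L, 1, 1), m = 2)
  expect_equal(marginal_log_likelihood(m0, d0), log(0.5), tolerance = 1e-12)

  set.seed(11)
  items <- list(gpcm_item(1.1, c(-0.8, 0.4)), gpcm_item(0.6, c(-1.2, 0, 1)),
                gpcm_item(1.6, 0.3))
  model <- gpcm_model(items)
  x <- matrix(c(1L, 2L, 1L,
                3L, 4L, 2L,
                2L, 1L, 1L,
                3L, 3L, 2L,
                1L, NA, 2L), 5, 3, byrow = TRUE)
  got <- marginal_log_likelihood(model, response_matrix(x, m = 4))
  want <- mll_rect_oracle(model, x)
  expect_lt(got, 0)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("EM fitting is monotone in likelihood and invariant to duplication", {
  dat <- quick_sample(n = 180, k = 4, seed = 21, m = 4)
  fit <- fit_gpcm(dat)
  expect_true(fit$converged)
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  # duplicating every person rescales the likelihood but not the estimates
  dup <- response_matrix(rbind(dat$responses, dat$responses), m = dat$m)
  fit2 <- fit_gpcm(dup)
  # agreement up to the EM stopping tolerance
  expect_equal(vapply(fit2$items, `[[`, numeric(1), "a"),
               vapply(fit$items, `[[`, numeric(1), "a"), tolerance = 1e-3)
})

test_that("discrimination recovery error shrinks with sample size", {
  # nested subsamples of one simulated population per replicate, so only
  # the sample size varies within a comparison
  sizes <- c(200, 800, 3200)
  rmse <- matrix(NA_real_, 3, length(sizes))
  for (r in 1:3) {
    cfg <- synthetic_config(n_persons = max(sizes), n_items = 8,
                            n_categories = 4,
                            discrimination_range = c(0.4, 1.6),
                            covariate_correlations = numeric(0),
                            seed = 500 + r)
    mod <- generate_true_model(cfg)
    dat <- simulate_responses(mod, cfg)
    a_true <- vapply(mod$items, `[[`, numeric(1), "a")
    for (s in seq_along(sizes)) {
      sub <- response_matrix(dat$responses[seq_len(sizes[s]), ], m = dat$m)
      fit <- suppressWarnings(fit_gpcm(sub))
      a_est <- vapply(fit$items, `[[`, numeric(1), "a")
      rmse[r, s] <- sqrt(mean((a_est - a_true)^2))
    }
  }
  expect_true(all(diff(colMeans(rmse)) < 0))
})

test_that("EAP scores are prior-centered, monotone and symmetric", {
  # flat likelihood: every score is the prior mean
  m0 <- gpcm_model(list(gpcm_item(0, c(-1, 1)), gpcm_item(0, c(0, 0.5))))
  d0 <- response_matrix(matrix(c(1L, 3L, 2L, 1L), 2, 2), m = 3)
  expect_equal(eap_scores(m0, d0), c(0, 0), tolerance = 1e-10)

  # raising any single response never lowers the score (all slopes positive):
  # checked exhaustively over all 27 patterns of a 3-item, 3-category test
  model <- gpcm_model(list(gpcm_item(0.8, c(-0.5, 0.6)),
                           gpcm_item(1.3, c(-1, 0.2)),
                           gpcm_item(0.5, c(0, 1))))
  pats <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  sc <- eap_scores(model, response_matrix(pats, m = 3))
  for (i in seq_len(nrow(pats))) {
    for (j in 1:3) {
      if (pats[i, j] < 3) {
        up <- pats[i, ]; up[j] <- up[j] + 1L
        k <- which(apply(pats, 1, function(r) all(r == up)))
        expect_gte(sc[k], sc[i])
      }
    }
  }

  # symmetric binary item: opposite responses give opposite scores
  ms <- gpcm_model(list(gpcm_item(1.4, 0)))
  s <- eap_scores(ms, response_matrix(matrix(c(1L, 2L), 2, 1), m = 2))
  expect_equal(s[1], -s[2], tolerance = 1e-9)
})

test_that("item information equals a^2 times the conditional category variance", {
  th <- seq(-3, 3, by = 0.5)
  expect_equal(item_information(gpcm_item(0, c(-1, 0, 1)), th), rep(0, length(th)))
  expect_equal(item_information(gpcm_item(1, 0), 0), 0.25, tolerance = 1e-12)
  # spot-check the finite-difference Fisher oracle (full sweep in acceptance)
  set.seed(9)
  for (r in 1:5) {
    it <- gpcm_item(runif(1, 0.2, 2), sort(rnorm(sample(2:5, 1))))
    t0 <- rnorm(1)
    expect_equal(item_information(it, t0), fisher_info_fd(it, t0),
                 tolerance = 1e-4)
  }
})

test_that("integrated information matches an independent integrator", {
  it <- gpcm_item(1.2, c(-1, 0, 1))
  # Simpson's rule on a fine grid as the independent oracle
  gr <- seq(-3, 3, length.out = 2001)
  h <- gr[2] - gr[1]
  y <- item_information(it, gr)
  simpson <- h / 3 * (y[1] + y[2001] + 4 * sum(y[seq(2, 2000, 2)]) +
                        2 * sum(y[seq(3, 1999, 2)]))
  expect_equal(integrated_information(it, c(-3, 3)), simpson, tolerance = 1e-6)
  expect_equal(integrated_information(gpcm_item(0, c(-1, 1)), c(-3, 3)), 0)
  # narrow interval behaves like the midpoint value
  eps <- 1e-4
  expect_equal(integrated_information(it, c(-eps, eps)),
               2 * eps * item_information(it, 0), tolerance = 1e-6)
})

test_that("test information is additive over items and subsets", {
  set.seed(14)
  items <- lapply(1:6, function(j) gpcm_item(runif(1, 0.3, 1.8), sort(rnorm(3))))
  model <- gpcm_model(items)
  grid <- seq(-3, 3, length.out = 21)
  prof <- test_information(model, grid = grid)
  expect_equal(prof$total, colSums(prof$per_item), tolerance = 1e-14)
  expect_true(all(prof$per_item >= 0))
  empty <- test_information(model, subset = integer(0), grid = grid)
  expect_equal(empty$total, rep(0, length(grid)))
  s1 <- test_information(model, subset = c(1, 3), grid = grid)$total
  s2 <- test_information(model, subset = c(2, 5, 6), grid = grid)$total
  su <- test_information(model, subset = c(1, 2, 3, 5, 6), grid = grid)$total
  expect_equal(s1 + s2, su, tolerance = 1e-12)
})
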