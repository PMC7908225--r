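test_that("the generator is deterministic and respects its configuration", {
  cfg <- synthetic_config(n_persons = 50, n_items = 21,
                          discrimination_range = c(0.12, 1.7), seed = 7)
  m1 <- generate_true_model(cfg)
  m2 <- generate_true_model(cfg)
  expect_identical(m1, m2)
  a <- vapply(m1$items, `[[`, numeric(1), "a")
  expect_true(all(a >= 0.12 & a <= 1.7))
  # m - 1 strictly increasing step difficulties per item
  for (it in m1$items) {
    expect_length(it$b, cfg$n_categories - 1L)
    expect_true(all(diff(it$b) > 0))
  }
  cfg2 <- synthetic_config(n_categories = 2, n_items = 4, seed = 3)
  expect_true(all(lengths(lapply(generate_true_model(cfg2)$items, `[[`, "b")) == 1L))
  d1 <- simulate_responses(m1, cfg)
  d2 <- simulate_responses(m1, cfg)
  expect_identical(d1$responses, d2$responses)

  expect_error(synthetic_config(discrimination_range = c(1.5, 0.5)), "low < high")
  expect_error(synthetic_config(covariate_correlations = 1.2), "inside")
})

test_that("simulated marginals match quadrature-integrated model probabilities", {
  cfg <- synthetic_config(n_persons = 40000, n_items = 3,
                          discrimination_range = c(0.4, 1.4),
                          covariate_correlations = numeric(0), seed = 31)
  mod <- generate_true_model(cfg)
  dat <- simulate_responses(mod, cfg)
  q <- make_quadrature(201, c(-8, 8))
  for (j in 1:3) {
    p_model <- colSums(category_probabilities(mod$items[[j]], q$nodes) * q$weights)
    p_emp <- tabulate(dat$responses[, j], 6) / nrow(dat$responses)
    expect_lt(max(abs(p_model - p_emp)), 3 / sqrt(nrow(dat$responses)))
  }
})

test_that("with no DIF the two groups share a generating distribution", {
  cfg <- synthetic_config(n_persons = 100000, n_items = 2, focal_fraction = 0.5,
                          covariate_correlations = numeric(0), seed = 12)
  dat <- simulate_responses(generate_true_model(cfg), cfg)
  foc <- dat$group == "focal"
  for (j in 1:2) {
    f1 <- tabulate(dat$responses[foc, j], 6) / sum(foc)
    f0 <- tabulate(dat$responses[!foc, j], 6) / sum(!foc)
    expect_lt(max(abs(f1 - f0)), 0.015)
  }
})

test_that("a zero-discrimination item yields uniform category frequencies", {
  cfg <- synthetic_config(n_persons = 60000, n_items = 2,
                          discriminations = c(0, 1),
                          covariate_correlations = numeric(0), seed = 5)
  dat <- simulate_responses(generate_true_model(cfg), cfg)
  freq <- tabulate(dat$responses[, 1], 6) / nrow(dat$responses)
  expect_lt(max(abs(freq - 1 / 6)), 3 / sqrt(nrow(dat$responses)))
})

test_that("covariates hit their configured trait correlations", {
  cfg <- synthetic_config(n_persons = 100000, n_items = 2,
                          covariate_correlations = c(0.27, -0.11), seed = 8)
  dat <- simulate_responses(generate_true_model(cfg), cfg)
  expect_lt(abs(cor(dat$covariates[[1]], dat$theta) - 0.27), 0.01)
  expect_lt(abs(cor(dat$covariates[[2]], dat$theta) - (-0.11)), 0.01)
  # covariates live on a plausible summed-score range
  expect_true(all(dat$covariates[[1]] >= 12 & dat$covariates[[1]] <= 60))
})

test_that("DIF injection shifts only the targeted parameters", {
  cfg <- synthetic_config(n_items = 6, seed = 2)
  mod <- generate_true_model(cfg)
  expect_identical(inject_dif(mod, list()), mod)

  foc <- inject_dif(mod, list(list(item = 5, parameter = "b", shift = 0.5)))
  for (j in setdiff(1:6, 5)) expect_identical(foc$items[[j]], mod$items[[j]])
  expect_equal(foc$items[[5]]$b, mod$items[[5]]$b + 0.5)
  # harder item: expected score at theta = 0 strictly lower in the focal group
  esc <- function(it) sum(category_probabilities(it, 0) * (0:5))
  expect_lt(esc(foc$items[[5]]), esc(mod$items[[5]]))

  foc_a <- inject_dif(mod, list(list(item = 3, parameter = "a", shift = 0.4)))
  expect_equal(foc_a$items[[3]]$a, mod$items[[3]]$a + 0.4)
  for (j in setdiff(1:6, 3)) expect_identical(foc_a$items[[j]], mod$items[[j]])

  # a single-step shift breaking the ordering is rejected
  gap <- diff(mod$items[[2]]$b)[1]
  expect_error(inject_dif(mod, list(list(item = 2, parameter = "b1",
                                         shift = gap + 0.2))),
               "non-increasing")
})

test_that("reversed items are flipped in the emitted responses", {
  base <- synthetic_config(n_persons = 5000, n_items = 3,
                           discriminations = c(1.5, 1.5, 1.5),
                           covariate_correlations = numeric(0), seed = 9)
  rev <- synthetic_config(n_persons = 5000, n_items = 3,
                          discriminations = c(1.5, 1.5, 1.5),
                          reversed_items = 2,
                          covariate_correlations = numeric(0), seed = 9)
  d0 <- simulate_responses(generate_true_model(base), base)
  d1 <- simulate_responses(generate_true_model(rev), rev)
  expect_identical(d1$responses[, 2], 7L - d0$responses[, 2])
  expect_identical(d1$responses[, c(1, 3)], d0$responses[, c(1, 3)])
  # flipped items correlate negatively with the trait
  expect_lt(cor(d1$responses[, 2], d1$theta), 0)
})

test_that("simulation artifacts round-trip through CSV and the truth sidecar", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_persons = 30, n_items = 4, seed = 13)
  dat <- simulate_responses(generate_true_model(cfg), cfg)
  paths <- write_simulation(dat, dir)
  df <- read.csv(paths[["responses"]])
  expect_equal(nrow(df), 30)
  expect_equal(as.matrix(df[paste0("item", 1:4)]),
               dat$responses, ignore_attr = TRUE)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$theta, dat$theta, tolerance = 1e-9)
  expect_match(truth$note, "truth")
})
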