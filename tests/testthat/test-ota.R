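test_that("branch-and-bound equals exhaustive enumeration on random problems", {
  set.seed(53)
  for (r in 1:30) {
    k <- 12
    info <- matrix(rexp(k * 5, rate = 2), k, 5)
    L <- sample(3:6, 1)
    sol <- assemble_fixed_length(assembly_problem(info, length = L))
    expect_equal(sol$objective, enum_best_subset(rowSums(info), L),
                 tolerance = 1e-10)
    expect_length(sol$selected, L)
    # the top-L closed form must agree with the search
    expect_equal(sol$objective,
                 sum(sort(rowSums(info), decreasing = TRUE)[1:L]),
                 tolerance = 1e-10)
  }
})

test_that("assembly handles boundary lengths, ties and fixed items", {
  info <- matrix(c(4, 3, 2, 1, 0.5), 5, 1)
  # full length takes everything
  all5 <- assemble_fixed_length(assembly_problem(info, 0, length = 5))
  expect_identical(all5$selected, 1:5)
  expect_equal(all5$objective, sum(info))
  # length 1 is the argmax
  expect_identical(assemble_fixed_length(assembly_problem(info, 0, length = 1))$selected, 1L)
  # equal scores: lexicographically smallest index set
  tie <- assemble_fixed_length(assembly_problem(matrix(1, 6, 1), 0, length = 3))
  expect_identical(tie$selected, 1:3)
  # mandatory/forbidden are honored
  con <- assemble_fixed_length(assembly_problem(info, 0, length = 2,
                                                mandatory = 5, forbidden = 1))
  expect_true(5 %in% con$selected)
  expect_false(1 %in% con$selected)
  expect_identical(con$selected, c(2L, 5L))
  expect_error(assembly_problem(info, 0, length = 2, mandatory = 2, forbidden = 2),
               "mandatory and forbidden")
})

test_that("the anchor objective is monotone in length and reflection-invariant", {
  set.seed(59)
  items <- lapply(1:9, function(j) gpcm_item(runif(1, 0.3, 1.6), sort(rnorm(4))))
  anchors <- c(-3, -1, 0, 1, 3)
  info <- t(vapply(items, function(it) item_information(it, anchors), numeric(5)))
  objs <- vapply(2:8, function(L) {
    assemble_fixed_length(assembly_problem(info, anchors, L))$objective
  }, numeric(1))
  expect_true(all(diff(objs) > 0))
  # reflecting every item (b -> -b) mirrors information about 0; with a
  # symmetric anchor set the selected subset cannot change
  refl <- lapply(items, function(it) gpcm_item(it$a, sort(-it$b)))
  info_r <- t(vapply(refl, function(it) item_information(it, anchors), numeric(5)))
  for (L in c(3, 5, 7)) {
    expect_identical(
      assemble_fixed_length(assembly_problem(info, anchors, L))$selected,
      assemble_fixed_length(assembly_problem(info_r, anchors, L))$selected)
  }
})

test_that("constraint evaluation is exact for self-comparison and deterministic", {
  dat <- quick_sample(n = 350, k = 6, seed = 61)
  model <- dat$true_model
  full <- evaluate_constraints(1:6, dat, model)
  expect_equal(full$value, c(1, 1, 1))
  expect_true(all(full$pass))
  sub <- evaluate_constraints(c(1, 3, 5), dat, model)
  expect_identical(sub, evaluate_constraints(c(1, 3, 5), dat, model))
  expect_true(all(sub$value[2:3] <= 1))
})

test_that("minimal-length search returns the smallest feasible length", {
  # planted separation: 8 informative items among 11 near-flat ones
  a <- c(rep(1.5, 8), rep(0.06, 11))
  cfg <- synthetic_config(n_persons = 600, n_items = 19, discriminations = a,
                          covariate_correlations = numeric(0), seed = 67)
  dat <- simulate_responses(generate_true_model(cfg), cfg)
  model <- dat$true_model
  res <- select_minimal_length(dat, model)
  expect_true(res$feasible)
  expect_lte(res$length, 9)
  expect_gte(length(intersect(res$selected, 1:8)), 5)
  expect_true(all(diff(res$audit$objective) > 0))

  # vacuous constraints stop at the smallest candidate length
  easy <- select_minimal_length(dat, model,
                                thresholds = list(alpha_ratio = 1e-6,
                                                  r_summed = 1e-6,
                                                  r_factor = 1e-6))
  expect_equal(easy$length, 4)

  # impossible constraints produce a failure record, not an error
  hard <- select_minimal_length(dat, model, lengths = 4:6,
                                thresholds = list(alpha_ratio = 2,
                                                  r_summed = 0.9,
                                                  r_factor = 0.9))
  expect_false(hard$feasible)
  expect_equal(nrow(hard$audit), 3)
})
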