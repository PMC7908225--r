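# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# GPCM category probabilities by literal long-form summation
brute_gpcm_prob <- function(a, b, theta) {
  m <- length(b) + 1L
  w <- numeric(m)
  for (c in seq_len(m)) {
    s <- 0
    if (c > 1L) for (v in seq_len(c - 1L)) s <- s + a * (theta - b[v])
    w[c] <- exp(s)
  }
  w / sum(w)
}

# Fisher information as the negative expected second derivative of the
# log category probability, by central finite differences
fisher_info_fd <- function(item, theta, h = 1e-4) {
  p0 <- brute_gpcm_prob(item$a, item$b, theta)
  d2 <- vapply(seq_len(item$m), function(c) {
    lp <- function(t) log(brute_gpcm_prob(item$a, item$b, t)[c])
    (lp(theta + h) - 2 * lp(theta) + lp(theta - h)) / h^2
  }, numeric(1))
  -sum(p0 * d2)
}

# marginal log-likelihood by high-resolution rectangular quadrature
mll_rect_oracle <- function(model, x, n_nodes = 10001L, bounds = c(-8, 8)) {
  th <- seq(bounds[1], bounds[2], length.out = n_nodes)
  dth <- th[2] - th[1]
  total <- 0
  for (i in seq_len(nrow(x))) {
    f <- rep(1, n_nodes)
    for (j in seq_len(ncol(x))) {
      if (is.na(x[i, j])) next
      it <- model$items[[j]]
      f <- f * vapply(th, function(t) brute_gpcm_prob(it$a, it$b, t)[x[i, j]],
                      numeric(1))
    }
    total <- total + log(sum(f * dnorm(th)) * dth)
  }
  total
}

# best fixed-size subset objective by exhaustive enumeration
enum_best_subset <- function(scores, L) {
  combs <- utils::combn(length(scores), L)
  vals <- colSums(matrix(scores[combs], nrow = L))
  max(vals)
}

# quick simulated sample with sensible defaults for unit tests
quick_sample <- function(n = 400, k = 6, a_range = c(0.5, 1.5), seed = 1,
                         m = 6, ...) {
  cfg <- synthetic_config(n_persons = n, n_items = k, n_categories = m,
                          discrimination_range = a_range,
                          covariate_correlations = numeric(0),
                          seed = seed, ...)
  simulate_responses(generate_true_model(cfg), cfg)
}
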