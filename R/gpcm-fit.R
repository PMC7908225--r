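# Marginal maximum likelihood machinery for the GPCM. Persons are integrated
# out over a fixed normal-weight quadrature grid; the E-step posterior is a
# persons x nodes matrix and every per-item quantity is an expected-count
# table over (node, category).

# log category-probability table for one item: nodes x m
item_logprob_table <- function(a, b, nodes) {
  q <- length(nodes)
  z <- gpcm_cum(a, b, nodes)
  mx <- z[cbind(seq_len(q), max.col(z, "first"))]
  z <- z - mx
  z - log(.rowSums(exp(z), q, ncol(z)))
}

# category-probability table (nodes x m), same fast path
prob_table <- function(a, b, nodes) {
  q <- length(nodes)
  z <- gpcm_cum(a, b, nodes)
  z <- z - z[cbind(seq_len(q), max.col(z, "first"))]
  ez <- exp(z)
  ez / .rowSums(ez, q, ncol(ez))
}

# persons x nodes log-likelihood matrix; missing responses contribute 0.
# x: persons x items integer matrix already on each item's internal scale.
loglik_matrix <- function(items, x, nodes) {
  n <- nrow(x); q <- length(nodes)
  LL <- matrix(0, n, q)
  for (j in seq_along(items)) {
    it <- items[[j]]
    lp <- cbind(item_logprob_table(it$a, it$b, nodes), 0)  # extra col for NA
    xj <- x[, j]
    xj[is.na(xj)] <- it$m + 1L
    LL <- LL + t(lp[, xj, drop = FALSE])
  }
  LL
}

# map raw responses onto each item's observed-category scale
map_to_levels <- function(x, levels) {
  for (j in seq_len(ncol(x))) {
    if (!is.null(levels[[j]])) x[, j] <- match(x[, j], levels[[j]])
  }
  x
}

model_levels <- function(model, k) {
  if (!is.null(model$levels)) model$levels else rep(list(NULL), k)
}

#' Marginal log-likelihood of a GPCM
#'
#' `sum_i log int prod_j P(x_ij | theta) dPrior(theta)`, the integral taken
#' over the model's fixed quadrature scheme. Missing responses are skipped in
#' the within-person product (ignorable missingness); persons with no
#' observed responses are excluded with a warning.
#'
#' @param model A [gpcm_model()].
#' @param data A [response_matrix()] (or plain integer matrix).
#' @return Scalar log-likelihood (non-positive).
#' @export
marginal_log_likelihood <- function(model, data) {
  x <- if (inherits(data, "response_matrix")) data$responses else as.matrix(data)
  stopifnot(ncol(x) == length(model$items))
  allmiss <- rowSums(!is.na(x)) == 0L
  if (any(allmiss)) {
    warning(sum(allmiss), " person(s) with no observed responses excluded")
    x <- x[!allmiss, , drop = FALSE]
  }
  x <- map_to_levels(x, model_levels(model, ncol(x)))
  q <- model$quadrature
  LL <- loglik_matrix(model$items, x, q$nodes)
  LL <- sweep(LL, 2L, log(q$weights), `+`)
  mx <- apply(LL, 1L, max)
  sum(mx + log(rowSums(exp(LL - mx))))
}

# M-step maximization for one item: expected counts N (nodes x m) at the
# quadrature nodes. Optimized in the slope/intercept parameterization
# cum_c = a * (c-1) * theta - d_c (with d_c = a * B_{c-1}), in which the
# slope can cross zero freely — the (a, b) coordinates have a ridge at
# a = 0 that traps reverse-oriented items. Analytic gradient; BFGS started
# at the current values; the result is mapped back to (a, b).
m_step_item <- function(a, b, N, nodes) {
  m <- length(b) + 1L
  q <- length(nodes)
  nq <- .rowSums(N, q, m)
  sc <- 0:(m - 1L)
  TH <- outer(nodes, sc)                      # q x m, (c-1) * theta
  ptab <- function(par) {
    z <- TH * par[1] - rep(c(0, par[-1]), each = q)
    z <- z - z[cbind(seq_len(q), max.col(z, "first"))]
    ez <- exp(z)
    ez / .rowSums(ez, q, m)
  }
  negf <- function(par) {
    z <- TH * par[1] - rep(c(0, par[-1]), each = q)
    mx <- z[cbind(seq_len(q), max.col(z, "first"))]
    lse <- mx + log(.rowSums(exp(z - mx), q, m))
    -(sum(N * z) - sum(nq * lse))
  }
  neggr <- function(par) {
    P <- ptab(par)
    ga <- sum(N * TH) - sum(nq * .rowSums(P * TH, q, m))
    gd <- -(.colSums(N, q, m) - colSums(nq * P))[-1L]
    -c(ga, gd)
  }
  d <- (a * c(0, cumsum(b)))[-1L]
  fit <- stats::optim(c(a, d), negf, neggr, method = "BFGS",
                      control = list(maxit = 20L, reltol = 1e-12))
  a_new <- fit$par[1]
  if (abs(a_new) < 1e-6) a_new <- if (a_new < 0) -1e-6 else 1e-6
  b_new <- diff(c(0, fit$par[-1])) / a_new
  c(a_new, b_new)
}

#' Fit a GPCM by marginal maximum likelihood (EM)
#'
#' EM estimation with a fixed standard-normal prior for identification:
#' the E-step computes posterior weights on the quadrature nodes, the M-step
#' updates each item's discrimination and step difficulties by BFGS with
#' analytic gradients (started at the current values, so the marginal
#' likelihood never decreases). Convergence is declared when the largest
#' absolute parameter change falls below `tol`.
#'
#' @param data A [response_matrix()]; reverse-flagged items are recoded
#'   first via [apply_reverse_coding()].
#' @param n_quad,bounds Quadrature resolution (default 61 nodes on (-6, 6)).
#' @param tol Convergence tolerance on the maximum parameter change.
#' @param max_iter Maximum EM iterations; exceeding it flags
#'   `converged = FALSE` rather than raising an error.
#' @param collapse If `TRUE` (default), categories never observed for an
#'   item are collapsed out (with a warning) and the mapping is stored in
#'   the fitted model; if `FALSE` such items raise an error.
#' @param a_warn Discriminations with absolute value below this bound
#'   trigger a near-zero-slope warning.
#' @return A [gpcm_model()] with extra fields `logLik`, `ll_trace`,
#'   `converged`, `n_iter`, `levels`.
#' @export
fit_gpcm <- function(data, n_quad = 61L, bounds = c(-6, 6), tol = 1e-4,
                     max_iter = 500L, collapse = TRUE, a_warn = 0.02) {
  stopifnot(inherits(data, "response_matrix"))
  data <- apply_reverse_coding(data)
  x <- data$responses
  allmiss <- rowSums(!is.na(x)) == 0L
  if (any(allmiss)) {
    warning(sum(allmiss), " person(s) with no observed responses excluded from fitting")
    x <- x[!allmiss, , drop = FALSE]
  }
  k <- ncol(x)
  levels <- vector("list", k)
  for (j in seq_len(k)) {
    obs <- sort(unique(x[!is.na(x[, j]), j]))
    if (length(obs) < 2L) stop("item ", j, " has fewer than 2 observed categories")
    if (length(obs) < data$m) {
      if (!collapse) stop("item ", j, " has unobserved categories; set collapse = TRUE")
      warning("item ", j, ": collapsing to ", length(obs), " observed categories")
      levels[[j]] <- obs
      x[, j] <- match(x[, j], obs)
    }
  }
  quad <- make_quadrature(n_quad, bounds)
  nodes <- quad$nodes
  lw <- log(quad$weights)
  n <- nrow(x); q <- length(nodes)

  # starting values: unit slope, difficulties spread by observed category use
  items <- vector("list", k)
  for (j in seq_len(k)) {
    mj <- if (is.null(levels[[j]])) data$m else length(levels[[j]])
    ctr <- (mean(x[, j], na.rm = TRUE) - (mj + 1) / 2) * 0.5
    items[[j]] <- gpcm_item(1, seq(-1.5, 1.5, length.out = mj - 1L) - ctr)
  }

  # precompute category index lists per item for expected counts
  cat_idx <- lapply(seq_len(k), function(j) {
    mj <- items[[j]]$m
    lapply(seq_len(mj), function(c) which(!is.na(x[, j]) & x[, j] == c))
  })

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    LL <- loglik_matrix(items, x, nodes)
    LLw <- sweep(LL, 2L, lw, `+`)
    mx <- apply(LLw, 1L, max)
    lse <- mx + log(rowSums(exp(LLw - mx)))
    ll_trace <- c(ll_trace, sum(lse))
    r <- exp(LLw - lse)                       # n x q posterior weights
    delta <- 0
    for (j in seq_len(k)) {
      mj <- items[[j]]$m
      N <- matrix(0, q, mj)
      for (c in seq_len(mj)) {
        idx <- cat_idx[[j]][[c]]
        if (length(idx)) N[, c] <- colSums(r[idx, , drop = FALSE])
      }
      old <- c(items[[j]]$a, items[[j]]$b)
      new <- m_step_item(items[[j]]$a, items[[j]]$b, N, nodes)
      delta <- max(delta, max(abs(new - old)))
      items[[j]] <- gpcm_item(new[1], new[-1], name = data$item_names[j])
    }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  a_hat <- vapply(items, `[[`, numeric(1), "a")
  if (any(abs(a_hat) < a_warn)) {
    warning("near-zero discrimination for item(s): ",
            paste(which(abs(a_hat) < a_warn), collapse = ", "))
  }
  model <- gpcm_model(items, item_names = data$item_names, quadrature = quad)
  model$logLik <- ll_trace[length(ll_trace)]
  model$ll_trace <- ll_trace
  model$converged <- converged
  model$n_iter <- iter
  model$levels <- levels
  model
}

#' Expected a posteriori (EAP) trait scores
#'
#' Posterior mean of the latent trait for each person under the model's
#' normal prior, computed on the quadrature grid. Persons with no observed
#' responses receive `NA`.
#'
#' @param model A fitted [gpcm_model()].
#' @param data A [response_matrix()] (or plain matrix) on the same items.
#' @param subset Optional item indices: score using only these items (with
#'   the full model's parameters restricted to them).
#' @return Numeric vector of EAP scores, one per person.
#' @export
eap_scores <- function(model, data, subset = NULL) {
  x <- if (inherits(data, "response_matrix")) data$responses else as.matrix(data)
  items <- model$items
  levels <- model_levels(model, length(items))
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    items <- items[subset]
    levels <- levels[subset]
    x <- x[, subset, drop = FALSE]
  }
  stopifnot(ncol(x) == length(items))
  x <- map_to_levels(x, levels)
  q <- model$quadrature
  LL <- loglik_matrix(items, x, q$nodes)
  LL <- sweep(LL, 2L, log(q$weights), `+`)
  mx <- apply(LL, 1L, max)
  r <- exp(LL - (mx + log(rowSums(exp(LL - mx)))))
  out <- as.vector(r %*% q$nodes)
  out[rowSums(!is.na(x)) == 0L] <- NA_real_
  out
}
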