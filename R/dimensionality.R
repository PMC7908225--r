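# Essential-unidimensionality screening: two-step polychoric correlations,
# sampling adequacy (KMO), Bartlett's sphericity test, minimum-residual
# factoring, and the eigenvalue-ratio / variance-explained decision rule.

# Standard bivariate normal CDF P(X <= h, Y <= k) with correlation rho,
# via the single integral over the correlation parameter
#   Phi2(h,k,rho) = Phi(h)Phi(k) + (1/2pi) int_0^rho phi2(h,k;r) dr
# evaluated with Gauss-Legendre quadrature. Vectorized over (h, k) pairs.
binormal_cdf <- function(h, k, rho, gl_n = 32L) {
  stopifnot(length(h) == length(k), abs(rho) < 1)
  out <- stats::pnorm(h) * stats::pnorm(k)
  if (rho != 0) {
    gl <- gauss_legendre(gl_n, 0, rho)
    fin <- is.finite(h) & is.finite(k)
    if (any(fin)) {
      hf <- h[fin]; kf <- k[fin]
      acc <- numeric(sum(fin))
      for (i in seq_along(gl$nodes)) {
        r <- gl$nodes[i]
        acc <- acc + gl$weights[i] *
          exp(-(hf^2 - 2 * r * hf * kf + kf^2) / (2 * (1 - r^2))) /
          sqrt(1 - r^2)
      }
      out[fin] <- out[fin] + acc / (2 * pi)
    }
  }
  pmin(pmax(out, 0), 1)
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1L, ]^2
  list(nodes = (a + b) / 2 + (b - a) / 2 * x, weights = (b - a) / 2 * w)
}

# Polychoric correlation for one pair by the two-step method: thresholds
# from the marginal proportions, then 1-D ML over rho.
polychoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  lx <- sort(unique(x)); ly <- sort(unique(y))    # collapse to observed
  if (length(lx) < 2L || length(ly) < 2L) {
    stop("degenerate contingency table: an item has < 2 observed categories in the pair")
  }
  tab <- table(factor(x, levels = lx), factor(y, levels = ly))
  n <- sum(tab)
  tau_x <- c(-Inf, stats::qnorm(cumsum(rowSums(tab)) / n)[-length(lx)], Inf)
  tau_y <- c(-Inf, stats::qnorm(cumsum(colSums(tab)) / n)[-length(ly)], Inf)
  hi <- rep(tau_x[-1L], times = length(ly)); lo_h <- rep(tau_x[-length(tau_x)], times = length(ly))
  ki <- rep(tau_y[-1L], each = length(lx));  lo_k <- rep(tau_y[-length(tau_y)], each = length(lx))
  nll <- function(rho) {
    p <- binormal_cdf(hi, ki, rho) - binormal_cdf(lo_h, ki, rho) -
      binormal_cdf(hi, lo_k, rho) + binormal_cdf(lo_h, lo_k, rho)
    -sum(as.vector(tab) * log(pmax(p, 1e-12)))
  }
  stats::optimize(nll, c(-0.9999, 0.9999), tol = 1e-7)$minimum
}

#' Polychoric correlation matrix
#'
#' Pairwise two-step polychoric estimates: thresholds from the marginal
#' normal quantiles of each item, then one-dimensional maximum likelihood
#' over the latent correlation of the bivariate-normal cell probabilities.
#' Unobserved categories are collapsed out per pair; a pair in which an
#' item retains fewer than two observed categories raises an error naming
#' the degeneracy.
#'
#' @param data A [response_matrix()] or integer matrix of ordinal responses.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(data) {
  x <- if (inherits(data, "response_matrix")) data$responses else as.matrix(data)
  k <- ncol(x)
  R <- diag(1, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      R[i, j] <- R[j, i] <- tryCatch(
        polychoric_pair(x[, i], x[, j]),
        error = function(e) stop("polychoric failure for items ", i, " and ",
                                 j, ": ", conditionMessage(e), call. = FALSE))
    }
  }
  dimnames(R) <- list(colnames(x), colnames(x))
  R
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO: the ratio of summed squared off-diagonal correlations to
#' that sum plus the summed squared anti-image partial correlations.
#'
#' @param corr Invertible correlation matrix.
#' @return Scalar in `[0, 1]`.
#' @export
kmo_statistic <- function(corr) {
  S <- tryCatch(solve(corr),
                error = function(e) stop("correlation matrix is singular"))
  d <- 1 / sqrt(diag(S))
  Q <- -S * outer(d, d)           # anti-image partial correlations
  off <- upper.tri(corr)
  sum(corr[off]^2) / (sum(corr[off]^2) + sum(Q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' `chi^2 = -(n - 1 - (2p + 5)/6) * ln|R|` with `p(p-1)/2` degrees of
#' freedom, against the hypothesis that the correlation matrix is the
#' identity.
#'
#' @param corr Correlation matrix.
#' @param n Sample size (must exceed the number of items).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(corr, n) {
  p <- ncol(corr)
  stopifnot(n > p)
  detR <- det(corr)
  if (detR <= 0) stop("correlation matrix has non-positive determinant")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Minimum-residual (ULS) exploratory factor analysis
#'
#' Finds loadings minimizing the sum of squared off-diagonal residuals of
#' `R - Lambda Lambda'`. The uniquenesses are optimized by L-BFGS-B (started
#' from squared-multiple-correlation communalities) with the loadings given
#' by the leading eigenstructure of the reduced matrix. The first factor's
#' sign is fixed so its loading sum is nonnegative. Heywood cases
#' (communalities reaching 1) are clamped with a warning.
#'
#' @param corr Correlation matrix (typically polychoric).
#' @param n_factors Number of factors (below the Ledermann bound).
#' @param n_obs Optional sample size, stored for downstream tests.
#' @return An object of class `efa_result`: `loadings`, `uniquenesses`,
#'   `eigenvalues` (of `corr`), `variance_explained` (per factor, items
#'   denominator), `flagged_items` (negative first-factor loadings),
#'   `objective`, plus `kmo` and `bartlett` slots when built through
#'   [efa_screen()].
#' @export
minres_efa <- function(corr, n_factors = 1L, n_obs = NULL) {
  p <- ncol(corr)
  k <- as.integer(n_factors)
  ledermann <- ((2 * p + 1) - sqrt(8 * p + 1)) / 2
  stopifnot(k >= 1L, k <= ledermann)
  off <- upper.tri(corr)
  load_given_psi <- function(psi) {
    e <- eigen(corr - diag(psi, p), symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    L
  }
  obj <- function(psi) {
    L <- load_given_psi(psi)
    res <- corr - tcrossprod(L)
    2 * sum(res[off]^2)
  }
  smc <- 1 - 1 / diag(solve(corr))
  start <- pmin(pmax(1 - smc, 0.05), 1)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = rep(1e-3, p), upper = rep(1, p),
                      control = list(maxit = 500L, factr = 1e4))
  psi <- fit$par
  if (any(psi <= 1e-3 + 1e-8)) warning("Heywood case: communality clamped at 1")
  L <- load_given_psi(psi)
  for (f in seq_len(k)) if (sum(L[, f]) < 0) L[, f] <- -L[, f]
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  structure(list(polychoric = corr,
                 loadings = L,
                 uniquenesses = psi,
                 eigenvalues = ev,
                 variance_explained = colSums(L^2) / p,
                 flagged_items = which(L[, 1L] < 0),
                 objective = fit$value,
                 n_factors = k,
                 n_obs = n_obs),
            class = "efa_result")
}

#' Full unidimensionality screen of a response matrix
#'
#' Convenience wrapper: polychoric matrix, KMO, Bartlett's test and a
#' minres factoring, bundled into one `efa_result`.
#'
#' @param data A [response_matrix()].
#' @param n_factors Factors to extract (default 2 so both leading
#'   variance proportions are reported).
#' @return An `efa_result` with `kmo` and `bartlett` filled in.
#' @export
efa_screen <- function(data, n_factors = 2L) {
  stopifnot(inherits(data, "response_matrix"))
  data <- apply_reverse_coding(data)
  R <- polychoric_matrix(data)
  n <- sum(stats::complete.cases(data$responses))
  out <- minres_efa(R, n_factors = n_factors, n_obs = n)
  out$kmo <- kmo_statistic(R)
  out$bartlett <- bartlett_sphericity(R, n)
  out
}

#' Essential-unidimensionality decision
#'
#' Passes when the ratio of the first to the second eigenvalue of the
#' polychoric matrix exceeds `ratio_threshold` (default 3) and the first
#' factor explains at least `variance_threshold` (default 20%) of total
#' variance. Also returns the negative-first-factor-loading items, which
#' are removed before any IRT modeling.
#'
#' @param efa An `efa_result` from [minres_efa()] or [efa_screen()].
#' @param ratio_threshold Minimum first/second eigenvalue ratio.
#' @param variance_threshold Minimum first-factor variance proportion.
#' @return List with the component checks, the overall `pass`, and
#'   `remove_items`.
#' @export
unidimensionality_check <- function(efa, ratio_threshold = 3,
                                    variance_threshold = 0.20) {
  stopifnot(length(efa$eigenvalues) >= 2L)
  ratio <- efa$eigenvalues[1L] / efa$eigenvalues[2L]
  v1 <- efa$variance_explained[1L]
  list(eigenvalue_ratio = ratio,
       ratio_pass = ratio > ratio_threshold,
       variance_first = v1,
       variance_pass = v1 >= variance_threshold,
       pass = (ratio > ratio_threshold) && (v1 >= variance_threshold),
       remove_items = efa$flagged_items)
}
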