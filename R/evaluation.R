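# Short-form evaluation: internal consistency with Feldt intervals, score
# correlations with Fisher-z intervals, convergent validity, one-factor ML
# confirmatory factor analysis fit indices, and information retention.

#' Cronbach's alpha from a covariance matrix
#'
#' `alpha = k/(k-1) * (1 - sum(diag(C)) / sum(C))`. Useful for population
#' (model-implied) covariance matrices as well as sample ones.
#'
#' @param C Item covariance (or correlation) matrix.
#' @return Scalar alpha.
#' @export
alpha_from_cov <- function(C) {
  k <- ncol(C)
  stopifnot(k >= 2L)
  tot <- sum(C)
  if (tot <= 0) stop("total score has non-positive variance")
  k / (k - 1) * (1 - sum(diag(C)) / tot)
}

#' Cronbach's alpha with a Feldt confidence interval
#'
#' Alpha is computed on complete cases of the selected items; the interval
#' uses Feldt's F distribution with `n - 1` and `(n - 1)(k - 1)` degrees of
#' freedom.
#'
#' @param data A [response_matrix()] or numeric matrix.
#' @param subset Optional item indices.
#' @param conf Confidence level (default 0.95).
#' @return List with `alpha`, `ci` (length 2), `n`, `k`.
#' @export
cronbach_alpha <- function(data, subset = NULL, conf = 0.95) {
  x <- if (inherits(data, "response_matrix")) data$responses else as.matrix(data)
  if (!is.null(subset)) x <- x[, subset, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  stopifnot(k >= 2L)
  if (n < 3L) stop("too few complete cases for alpha")
  a <- alpha_from_cov(stats::cov(x))
  lo <- 1 - (1 - a) * stats::qf(1 - (1 - conf) / 2, n - 1, (n - 1) * (k - 1))
  hi <- 1 - (1 - a) * stats::qf((1 - conf) / 2, n - 1, (n - 1) * (k - 1))
  list(alpha = a, ci = c(lo, hi), n = n, k = k)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @param conf Confidence level.
#' @return List with `r`, `ci`, `n`.
#' @export
correlation_with_ci <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, ci = c(r, r), n = n))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- stats::qnorm(1 - (1 - conf) / 2)
  list(r = r, ci = tanh(c(z - crit * se, z + crit * se)), n = n)
}

# F_ML discrepancy and analytic gradient for the one-factor model
cfa_objective <- function(par, S) {
  p <- ncol(S)
  lambda <- par[seq_len(p)]
  psi <- exp(par[p + seq_len(p)])
  Sigma <- tcrossprod(lambda) + diag(psi, p)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, 2 * p)))
  Sinv <- chol2inv(ch)
  ldet <- 2 * sum(log(diag(ch)))
  val <- ldet + sum(Sinv * S) - determinant(S)$modulus[1] - p
  G <- Sinv - Sinv %*% S %*% Sinv
  glam <- 2 * as.vector(G %*% lambda)
  gpsi <- diag(G) * psi
  list(value = as.numeric(val), grad = c(glam, gpsi))
}

#' One-factor confirmatory factor analysis by maximum likelihood
#'
#' Fits a single-factor covariance structure `Sigma = lambda lambda' +
#' diag(psi)` to the Pearson covariance matrix of the (sub)scale items by
#' minimizing the ML discrepancy, and reports the usual fit indices:
#' `chi^2 = (n - 1) F_ML`, RMSEA with a 90% interval from the noncentral
#' chi-square inversion, SRMR over the standardized residuals (diagonal
#' included), and CFI against the independence baseline.
#'
#' @param data A [response_matrix()], a numeric data matrix, or a
#'   covariance matrix (in which case `n` must be given).
#' @param subset Optional item indices.
#' @param n Sample size when `data` is a covariance matrix.
#' @param n_starts Extra random starts used if the first optimization does
#'   not converge cleanly.
#' @return List of class `cfa_fit`: `chi2`, `df`, `p_value`, `rmsea`,
#'   `rmsea_ci90`, `srmr`, `cfi`, `loadings`, `uniquenesses`, `F_ml`,
#'   `converged`, `n`.
#' @export
cfa_one_factor <- function(data, subset = NULL, n = NULL, n_starts = 5L) {
  if (inherits(data, "response_matrix") || (is.matrix(data) && !isSymmetric(unname(as.matrix(data))))) {
    x <- if (inherits(data, "response_matrix")) data$responses else as.matrix(data)
    if (!is.null(subset)) x <- x[, subset, drop = FALSE]
    x <- x[stats::complete.cases(x), , drop = FALSE]
    n <- nrow(x)
    S <- stats::cov(x)
  } else {
    S <- as.matrix(data)
    if (!is.null(subset)) S <- S[subset, subset, drop = FALSE]
    if (is.null(n)) stop("'n' is required when passing a covariance matrix")
  }
  p <- ncol(S)
  stopifnot(p >= 4L, n > p)
  df <- p * (p + 1) / 2 - 2 * p
  e <- eigen(S, symmetric = TRUE)
  lam0 <- e$vectors[, 1L] * sqrt(max(e$values[1L], 1e-6) * 0.7)
  psi0 <- pmax(diag(S) - lam0^2, 0.05 * diag(S))
  run <- function(start) {
    stats::optim(start, fn = function(pp) cfa_objective(pp, S)$value,
                 gr = function(pp) cfa_objective(pp, S)$grad,
                 method = "BFGS",
                 control = list(maxit = 1000L, reltol = 1e-14))
  }
  fit <- run(c(lam0, log(psi0)))
  if (fit$convergence != 0) {
    set.seed(1L)
    for (s in seq_len(n_starts)) {
      cand <- run(c(lam0 * stats::runif(p, 0.5, 1.5),
                    log(psi0 * stats::runif(p, 0.5, 1.5))))
      if (cand$value < fit$value) fit <- cand
    }
  }
  lambda <- fit$par[seq_len(p)]
  if (sum(lambda) < 0) lambda <- -lambda
  psi <- exp(fit$par[p + seq_len(p)])
  F_ml <- max(fit$value, 0)
  chi2 <- (n - 1) * F_ml
  # baseline (independence) model
  R <- stats::cov2cor(S)
  chi2_b <- (n - 1) * (-determinant(R)$modulus[1])
  df_b <- p * (p - 1) / 2
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  ci <- rmsea_ci(chi2, df, n, level = 0.90)
  Sigma <- tcrossprod(lambda) + diag(psi, p)
  dscale <- sqrt(diag(S))
  res <- (S - Sigma) / outer(dscale, dscale)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 rmsea = rmsea, rmsea_ci90 = ci, srmr = srmr, cfi = cfi,
                 loadings = lambda, uniquenesses = psi, F_ml = F_ml,
                 converged = fit$convergence == 0, n = n),
            class = "cfa_fit")
}

# 90% RMSEA interval by inverting the noncentral chi-square
rmsea_ci <- function(chi2, df, n, level = 0.90) {
  a <- (1 - level) / 2
  upper_p <- function(ncp) stats::pchisq(chi2, df, ncp = ncp)
  lo <- 0
  if (upper_p(0) > 1 - a) {           # chi2 large enough for a positive bound
    lo <- stats::uniroot(function(l) upper_p(l) - (1 - a), c(0, chi2 + 100),
                         extendInt = "downX")$root
  }
  hi <- 0
  if (upper_p(0) > a) {
    hi <- stats::uniroot(function(l) upper_p(l) - a, c(0, chi2 + 200),
                         extendInt = "downX")$root
  }
  c(sqrt(max(lo, 0) / (df * (n - 1))), sqrt(max(hi, 0) / (df * (n - 1))))
}

#' Information retention percentage
#'
#' `100 * subset_total / full_total`, rounded to one decimal — the
#' convention used when reporting how much of the full scale's test
#' information a short form keeps.
#'
#' @param subset_total,full_total Integrated test information of the short
#'   form and the full scale over the same trait range; `full_total` must
#'   be positive.
#' @return Percentage (one decimal).
#' @export
information_retention <- function(subset_total, full_total) {
  if (any(full_total <= 0)) stop("full-scale information must be positive")
  round(100 * subset_total / full_total, 1)
}

#' Full evaluation of a candidate short form
#'
#' Produces the training-sample comparison of a subset against the full
#' (non-DIF) item set — Cronbach's alpha with CI, summed-score and
#' EAP-factor-score correlations with CI, convergent correlations with the
#' covariates, a one-factor CFA of the subset, and information retention
#' relative to a reference full-scale model over the entire trait range
#' (-10, 10) and over (-3, 3) — and, when a test sample is supplied, the
#' confirmation-sample evaluation (alpha, CFA, information retention with
#' models refitted on the test data). The subset's reported information
#' uses a GPCM refit on the subset items (final-report convention), while
#' the constraint scan in [select_minimal_length()] uses the full model's
#' restriction.
#'
#' @param train Training [response_matrix()] (non-DIF item set).
#' @param subset Item indices within `train`.
#' @param model [gpcm_model()] fitted to `train`.
#' @param test Optional test-sample [response_matrix()] on the same items.
#' @param reference_model Optional [gpcm_model()] for the information
#'   denominator (e.g. the original full scale including screened-out
#'   items); defaults to `model`.
#' @param reference_total Optional named numeric
#'   `c(full = ..., range33 = ...)` overriding the reference model's
#'   integrated information (used when the denominator comes from a
#'   different sample or a published calibration).
#' @param test_reference_model Optional [gpcm_model()] fitted to the test
#'   sample's full original scale, used as the test-sample information
#'   denominator; defaults to a refit of `test`'s items.
#' @return List of class `short_form_evaluation` with `training` and
#'   (optionally) `test` components.
#' @export
evaluate_short_form <- function(train, subset, model, test = NULL,
                                reference_model = NULL,
                                reference_total = NULL,
                                test_reference_model = NULL) {
  stopifnot(inherits(train, "response_matrix"))
  subset <- sort(as.integer(subset))
  if (is.null(reference_model)) reference_model <- model

  ref_full <- integrated_test_information(reference_model, range = c(-10, 10))
  ref_33 <- integrated_test_information(reference_model, range = c(-3, 3))
  if (!is.null(reference_total)) {
    ref_full <- reference_total[["full"]]
    ref_33 <- reference_total[["range33"]]
  }

  eval_sample <- function(data, fit_model, refit_sub) {
    alpha_full <- cronbach_alpha(data)
    alpha_sub <- cronbach_alpha(data, subset = subset)
    ss_full <- summed_scores(data)
    ss_sub <- summed_scores(data, subset)
    r_sum <- correlation_with_ci(ss_sub, ss_full)
    th_full <- eap_scores(fit_model, data)
    th_sub <- eap_scores(fit_model, data, subset = subset)
    r_fac <- correlation_with_ci(th_sub, th_full)
    conv <- NULL
    if (!is.null(data$covariates)) {
      conv <- lapply(data$covariates, function(v) correlation_with_ci(ss_sub, v))
    }
    cfa <- cfa_one_factor(data, subset = subset)
    sub_full <- integrated_test_information(refit_sub, range = c(-10, 10))
    sub_33 <- integrated_test_information(refit_sub, range = c(-3, 3))
    list(alpha_full = alpha_full, alpha_subset = alpha_sub,
         r_summed = r_sum, r_factor = r_fac, convergent = conv, cfa = cfa,
         information = list(
           subset_full = sub_full, subset_range33 = sub_33,
           retention_full = information_retention(sub_full, ref_full),
           retention_range33 = information_retention(sub_33, ref_33)))
  }

  sub_train <- subset_items(train, subset)
  refit_train <- fit_gpcm(sub_train)
  out <- list(subset = subset,
              reference_information = c(full = ref_full, range33 = ref_33),
              training = eval_sample(train, model, refit_train))

  if (!is.null(test)) {
    stopifnot(inherits(test, "response_matrix"))
    test_ref <- if (is.null(test_reference_model)) fit_gpcm(test) else test_reference_model
    sub_test <- subset_items(test, subset)
    refit_test <- fit_gpcm(sub_test)
    test_ref_full <- integrated_test_information(test_ref, range = c(-10, 10))
    test_ref_33 <- integrated_test_information(test_ref, range = c(-3, 3))
    ev <- list(alpha_subset = cronbach_alpha(test, subset = subset),
               cfa = cfa_one_factor(test, subset = subset),
               information = local({
                 sf <- integrated_test_information(refit_test, range = c(-10, 10))
                 s3 <- integrated_test_information(refit_test, range = c(-3, 3))
                 list(subset_full = sf, subset_range33 = s3,
                      retention_full = information_retention(sf, test_ref_full),
                      retention_range33 = information_retention(s3, test_ref_33))
               }))
    out$test <- ev
  }
  structure(out, class = "short_form_evaluation")
}
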