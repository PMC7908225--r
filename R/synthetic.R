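#' Configuration for the synthetic questionnaire generator
#'
#' Describes a simulated population of ordinal questionnaire responses with
#' known GPCM structure: per-item discriminations and ordered step
#' difficulties, a standard-normal latent trait, optional group DIF on
#' selected items, optional reverse-oriented items, and covariates with
#' specified latent-trait correlations. The defaults emulate a 21-item,
#' 6-category noise-sensitivity questionnaire administered to samples of a
#' few hundred adults, with discriminations spanning roughly 0.12-1.7.
#'
#' @param n_persons Sample size.
#' @param n_items Number of items.
#' @param n_categories Number of response categories (default 6).
#' @param discrimination_range `(low, high)` for uniform discrimination
#'   draws; both positive, `low < high`.
#' @param discriminations Optional explicit discrimination vector
#'   (overrides `discrimination_range`).
#' @param threshold_spread Standard deviation of the step-difficulty draws
#'   around each item's location.
#' @param dif_spec List of DIF plants, each
#'   `list(item =, parameter = "a"|"b"|"b<v>", shift =)`; shifts are applied
#'   additively to the focal group's parameters.
#' @param reversed_items Indices of items generated with reversed
#'   orientation (responses flipped `x -> m + 1 - x`), *not* declared in the
#'   output flags — these are the planted wrong-direction items a
#'   negative-loading screen should catch.
#' @param covariate_correlations Correlations (each in (-1, 1)) of the
#'   covariate scores with the latent trait; default +0.27 and -0.11,
#'   typical of neuroticism and extraversion scales.
#' @param focal_fraction Proportion of persons in the focal group
#'   (default 0.37, mirroring a ~63% female / 37% male sample with males
#'   as the focal group).
#' @param focal_theta_mean,focal_theta_sd Latent-trait distribution of the
#'   focal group (defaults: no impact, N(0, 1)).
#' @param seed Integer seed; all downstream draws derive from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_persons = 569L, n_items = 21L,
                             n_categories = 6L,
                             discrimination_range = c(0.12, 1.7),
                             discriminations = NULL,
                             threshold_spread = 0.8,
                             dif_spec = list(),
                             reversed_items = integer(0),
                             covariate_correlations = c(neuroticism = 0.27,
                                                        extraversion = -0.11),
                             focal_fraction = 0.37,
                             focal_theta_mean = 0, focal_theta_sd = 1,
                             seed = 1L) {
  stopifnot(n_persons >= 1L, n_items >= 1L, n_categories >= 2L)
  if (discrimination_range[1] <= 0 || discrimination_range[1] >= discrimination_range[2]) {
    stop("discrimination_range must satisfy 0 < low < high")
  }
  if (!is.null(discriminations)) stopifnot(length(discriminations) == n_items)
  stopifnot(threshold_spread > 0)
  if (length(covariate_correlations) &&
      any(abs(covariate_correlations) >= 1)) {
    stop("covariate correlations must lie strictly inside (-1, 1)")
  }
  stopifnot(all(reversed_items >= 1L), all(reversed_items <= n_items))
  for (d in dif_spec) {
    if (is.null(d$item) || d$item < 1L || d$item > n_items) {
      stop("dif_spec entries must reference valid item indices")
    }
    if (is.null(d$parameter) || is.null(d$shift)) {
      stop("dif_spec entries need 'parameter' and 'shift'")
    }
  }
  stopifnot(focal_fraction > 0, focal_fraction < 1, focal_theta_sd > 0)
  structure(list(n_persons = as.integer(n_persons),
                 n_items = as.integer(n_items),
                 n_categories = as.integer(n_categories),
                 discrimination_range = discrimination_range,
                 discriminations = discriminations,
                 threshold_spread = threshold_spread,
                 dif_spec = dif_spec,
                 reversed_items = as.integer(reversed_items),
                 covariate_correlations = covariate_correlations,
                 focal_fraction = focal_fraction,
                 focal_theta_mean = focal_theta_mean,
                 focal_theta_sd = focal_theta_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Draw the true generating GPCM
#'
#' Discriminations are uniform draws from `discrimination_range` (unless
#' given explicitly); each item's step difficulties are sorted normal draws
#' centered at a per-item location `~ N(0, 1)` with spread
#' `threshold_spread`, which guarantees strictly increasing, well-behaved
#' Likert-type thresholds centered near zero. Deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @return A [gpcm_model()] representing the simulation truth.
#' @export
generate_true_model <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- config$n_items; m <- config$n_categories
  a <- config$discriminations
  if (is.null(a)) {
    a <- stats::runif(k, config$discrimination_range[1],
                      config$discrimination_range[2])
  }
  items <- vector("list", k)
  for (j in seq_len(k)) {
    loc <- stats::rnorm(1)
    b <- sort(loc + config$threshold_spread * stats::rnorm(m - 1L))
    while (any(diff(b) <= 0)) b <- b + cumsum(c(0, diff(b) <= 0)) * 1e-8
    items[[j]] <- gpcm_item(a[j], b)
  }
  gpcm_model(items)
}

#' Plant DIF shifts into a focal-group model copy
#'
#' Returns a copy of `model` with the additive shifts from `dif_spec`
#' applied; the reference model is left unchanged. `parameter = "a"` shifts
#' the discrimination, `"b"` shifts every step difficulty (uniform DIF),
#' and `"b<v>"` (e.g. `"b2"`) shifts a single step. A shift that would make
#' an item's step difficulties non-increasing is rejected.
#'
#' @param model A [gpcm_model()].
#' @param dif_spec List of `list(item, parameter, shift)` entries.
#' @return The focal-group [gpcm_model()].
#' @export
inject_dif <- function(model, dif_spec) {
  focal <- model
  for (d in dif_spec) {
    j <- d$item
    stopifnot(j >= 1L, j <= length(focal$items))
    it <- focal$items[[j]]
    if (identical(d$parameter, "a")) {
      it$a <- it$a + d$shift
    } else if (identical(d$parameter, "b")) {
      it$b <- it$b + d$shift
    } else if (grepl("^b[0-9]+$", d$parameter)) {
      v <- as.integer(sub("^b", "", d$parameter))
      if (v < 1L || v > length(it$b)) stop("no step difficulty ", d$parameter,
                                           " in item ", j)
      it$b[v] <- it$b[v] + d$shift
      if (is.unsorted(it$b, strictly = TRUE)) {
        stop("DIF shift on item ", j, " produces non-increasing step difficulties")
      }
    } else {
      stop("unknown DIF parameter '", d$parameter, "'")
    }
    focal$items[[j]] <- gpcm_item(it$a, it$b, name = it$name)
  }
  focal
}

# sample one response per person for one item given theta (vectorized)
sample_item <- function(item, theta) {
  p <- category_probabilities(item, theta)
  cp <- t(apply(p, 1L, cumsum))
  u <- stats::runif(length(theta))
  as.integer(rowSums(u > cp) + 1L)
}

#' Simulate a response matrix from a generating model
#'
#' Draws latent traits (reference group standard normal, focal group
#' optionally shifted/scaled), samples each response from the GPCM category
#' probabilities — the focal group uses the DIF-shifted parameters from
#' `config$dif_spec` — flips the responses of planted reverse-oriented
#' items, and draws covariates jointly normal with the trait at the
#' configured correlations, rescaled and rounded to NEO-FFI-like score
#' ranges (12-item, 5-point scales: sums in 12..60). The true traits and
#' the generating models are retained in the result for recovery testing.
#'
#' @param model The reference-group [gpcm_model()] from
#'   [generate_true_model()].
#' @param config The matching [synthetic_config()].
#' @return A [response_matrix()] with `theta` (truth), `true_model`,
#'   `true_focal_model` and `config` attached.
#' @export
simulate_responses <- function(model, config) {
  stopifnot(inherits(model, "gpcm_model"), inherits(config, "synthetic_config"))
  stopifnot(length(model$items) == config$n_items)
  set.seed(config$seed + 1L)
  n <- config$n_persons; k <- config$n_items; m <- config$n_categories
  focal <- inject_dif(model, config$dif_spec)
  n_focal <- round(n * config$focal_fraction)
  group <- factor(rep(c("reference", "focal"), c(n - n_focal, n_focal)),
                  levels = c("reference", "focal"))
  theta <- stats::rnorm(n)
  is_foc <- group == "focal"
  theta[is_foc] <- config$focal_theta_mean + config$focal_theta_sd * theta[is_foc]
  x <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    x[!is_foc, j] <- sample_item(model$items[[j]], theta[!is_foc])
    x[is_foc, j] <- sample_item(focal$items[[j]], theta[is_foc])
  }
  if (length(config$reversed_items)) {
    x[, config$reversed_items] <- m + 1L - x[, config$reversed_items]
  }
  covariates <- NULL
  rho <- config$covariate_correlations
  if (length(rho)) {
    covariates <- as.data.frame(lapply(rho, function(r) {
      z <- r * theta + sqrt(1 - r^2) * stats::rnorm(n)
      pmin(pmax(round(36 + 8 * z), 12), 60)   # NEO-like 12..60 sum scores
    }))
    nms <- names(rho)
    if (is.null(nms) || any(nms == "")) nms <- paste0("covariate", seq_along(rho))
    names(covariates) <- nms
  }
  out <- response_matrix(x, m = m, group = group, covariates = covariates,
                         theta = theta)
  out$true_model <- model
  out$true_focal_model <- focal
  out$config <- config
  out
}

#' Write a simulated sample to disk
#'
#' Responses as CSV (one row per person: id, group, items, covariates) and
#' the simulation truth (per-item parameters, per-person traits) as a JSON
#' sidecar clearly labelled as truth.
#'
#' @param data A simulated [response_matrix()].
#' @param dir Output directory (created if missing).
#' @param stem File-name stem.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(data, dir, stem = "sample") {
  stopifnot(inherits(data, "response_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- data.frame(id = seq_len(nrow(data$responses)))
  if (!is.null(data$group)) df$group <- data$group
  df <- cbind(df, as.data.frame(data$responses))
  if (!is.null(data$covariates)) df <- cbind(df, data$covariates)
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  truth_path <- NULL
  if (!is.null(data$true_model)) {
    truth <- list(
      note = "simulation truth - generating parameters, not estimates",
      items = lapply(data$true_model$items, function(it) {
        list(a = it$a, b = it$b, m = it$m)
      }),
      theta = data$theta
    )
    truth_path <- file.path(dir, paste0(stem, "_truth.json"))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(responses = csv, truth = truth_path))
}
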