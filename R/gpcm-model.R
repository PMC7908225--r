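#' Generalized partial credit model item
#'
#' Constructs a single GPCM item from a discrimination and a vector of step
#' difficulties. Under the GPCM, the probability of responding in category
#' `c` (coded `1..m`) at trait level `theta` is proportional to
#' `exp(sum_{v<c} a * (theta - b_v))`, with the cumulative term for the first
#' category defined as zero. Each step difficulty `b_v` is the trait level at
#' which categories `v` and `v+1` are equally likely.
#'
#' @param a Discrimination (slope); any finite real, typically positive.
#' @param b Numeric vector of `m - 1` step difficulties.
#' @param name Optional item label.
#' @return An object of class `gpcm_item` with elements `a`, `b`, `m`, `name`.
#' @export
gpcm_item <- function(a, b, name = NULL) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  b <- as.numeric(b)
  if (length(b) < 1L || any(!is.finite(b))) {
    stop("'b' must hold at least one finite step difficulty (m >= 2)")
  }
  structure(list(a = as.numeric(a), b = b, m = length(b) + 1L, name = name),
            class = "gpcm_item")
}

#' Generalized partial credit measurement model
#'
#' Bundles a list of [gpcm_item()]s with a latent-trait prior and a fixed
#' quadrature scheme. The reference prior is standard normal, which
#' identifies the latent metric.
#'
#' @param items List of `gpcm_item` objects.
#' @param item_names Optional character vector of labels.
#' @param prior List with `mean` and `sd` of the normal latent-trait prior.
#' @param quadrature Quadrature scheme from [make_quadrature()].
#' @return An object of class `gpcm_model`.
#' @export
gpcm_model <- function(items, item_names = NULL,
                       prior = list(mean = 0, sd = 1),
                       quadrature = make_quadrature()) {
  stopifnot(is.list(items), length(items) >= 1L)
  for (it in items) {
    if (!inherits(it, "gpcm_item")) stop("all elements of 'items' must be gpcm_item objects")
  }
  if (is.null(item_names)) {
    item_names <- vapply(seq_along(items), function(j) {
      nm <- items[[j]]$name
      if (is.null(nm)) paste0("item", j) else nm
    }, character(1))
  }
  stopifnot(prior$sd > 0)
  structure(list(items = items, item_names = item_names,
                 prior = prior, quadrature = quadrature),
            class = "gpcm_model")
}

#' @export
print.gpcm_model <- function(x, ...) {
  cat("GPCM model:", length(x$items), "items\n")
  a <- vapply(x$items, `[[`, numeric(1), "a")
  cat("  discriminations:", paste(sprintf("%.3f", a), collapse = " "), "\n")
  invisible(x)
}

#' Normal-prior quadrature scheme
#'
#' Equally spaced nodes with normal-density weights, normalized to sum to
#' one. Used for all marginal likelihood integrals and EAP scoring.
#'
#' @param n Number of nodes.
#' @param bounds Interval covered by the nodes.
#' @param mean,sd Mean and standard deviation of the latent-trait prior.
#' @return List with `nodes` and `weights` (weights sum to 1).
#' @export
make_quadrature <- function(n = 61L, bounds = c(-6, 6), mean = 0, sd = 1) {
  stopifnot(n >= 3L, bounds[1] < bounds[2], sd > 0)
  nodes <- seq(bounds[1], bounds[2], length.out = n)
  w <- stats::dnorm(nodes, mean = mean, sd = sd)
  list(nodes = nodes, weights = w / sum(w))
}

# Cumulative numerator exponents for one item over a theta grid.
# Returns length(theta) x m matrix of a * ((c-1) * theta - B_{c-1}),
# where B_k is the partial sum of the first k step difficulties (B_0 = 0).
gpcm_cum <- function(a, b, theta) {
  m <- length(b) + 1L
  Bc <- c(0, cumsum(b))                       # length m
  outer(theta, 0:(m - 1L)) * a - rep(a * Bc, each = length(theta))
}

#' GPCM category probabilities
#'
#' @param item A [gpcm_item()].
#' @param theta Numeric vector of trait values.
#' @return A `length(theta) x m` matrix of category probabilities; each row
#'   sums to one. Overflow is guarded by subtracting the row maximum before
#'   exponentiation.
#' @export
category_probabilities <- function(item, theta) {
  stopifnot(inherits(item, "gpcm_item"), all(is.finite(theta)))
  z <- gpcm_cum(item$a, item$b, theta)
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' GPCM item information
#'
#' Fisher information about the latent trait contributed by one item:
#' `a^2 * Var(C | theta)` where `C` is the 0-based category score under the
#' model's category probabilities.
#'
#' @param item A [gpcm_item()].
#' @param theta Numeric vector of trait values.
#' @return Numeric vector of nonnegative information values.
#' @export
item_information <- function(item, theta) {
  p <- category_probabilities(item, theta)
  sc <- 0:(item$m - 1L)
  mu <- as.vector(p %*% sc)
  mu2 <- as.vector(p %*% sc^2)
  item$a^2 * (mu2 - mu^2)
}

#' Integrated item information over a trait interval
#'
#' Numerically integrates [item_information()] over `range` with adaptive
#' quadrature. The conventional "entire trait range" is `(-10, 10)`: beyond
#' that interval polytomous items of ordinary discrimination contribute
#' negligible information.
#'
#' @param item A [gpcm_item()].
#' @param range Integration interval `(lo, hi)`; default `c(-10, 10)`.
#' @return Scalar integrated information.
#' @export
integrated_information <- function(item, range = c(-10, 10)) {
  stopifnot(range[1] < range[2])
  stats::integrate(function(t) item_information(item, t),
                   range[1], range[2],
                   subdivisions = 500L, rel.tol = 1e-9)$value
}

#' Test information profile over a trait grid
#'
#' Per-item and total information for a subset of the model's items. Total
#' information is the sum of the item informations at every grid point.
#'
#' @param model A [gpcm_model()].
#' @param subset Integer indices of the items to include; defaults to all.
#' @param grid Trait grid.
#' @return A list of class `information_profile` with `theta`, `per_item`
#'   (`length(subset) x length(grid)` matrix) and `total`.
#' @export
test_information <- function(model, subset = seq_along(model$items),
                             grid = seq(-4, 4, length.out = 81L)) {
  subset <- as.integer(subset)
  stopifnot(all(subset >= 1L), all(subset <= length(model$items)))
  if (length(subset) == 0L) {
    per <- matrix(0, nrow = 0L, ncol = length(grid))
    return(structure(list(theta = grid, per_item = per,
                          total = rep(0, length(grid)), subset = subset),
                     class = "information_profile"))
  }
  per <- t(vapply(subset, function(j) item_information(model$items[[j]], grid),
                  numeric(length(grid))))
  structure(list(theta = grid, per_item = per, total = colSums(per),
                 subset = subset),
            class = "information_profile")
}

#' Integrated test information for an item subset
#'
#' @param model A [gpcm_model()].
#' @param subset Item indices; defaults to all items.
#' @param range Integration interval; `c(-10, 10)` covers the entire
#'   practically relevant trait range.
#' @return Scalar summed integrated information.
#' @export
integrated_test_information <- function(model, subset = seq_along(model$items),
                                        range = c(-10, 10)) {
  if (length(subset) == 0L) return(0)
  sum(vapply(subset, function(j) integrated_information(model$items[[j]], range),
             numeric(1)))
}
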