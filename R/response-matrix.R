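#' Ordinal response matrix with group labels and covariates
#'
#' The unit of every analysis stage: a persons-by-items matrix of integer
#' responses in `1..m` (missing allowed), an optional two-level group label
#' (for DIF analysis), optional per-person covariate scores (for convergent
#' validity), and per-item reverse-coding flags.
#'
#' @param responses Integer matrix, persons in rows, items in columns;
#'   observed entries must lie in `1..m`.
#' @param m Number of response categories; defaults to the largest observed
#'   category.
#' @param group Optional factor/vector with exactly two levels; the first
#'   level is taken as the reference group.
#' @param covariates Optional data frame (or named matrix) of per-person
#'   covariate scores.
#' @param item_names Optional item labels; default `item1..itemK`.
#' @param reverse_flags Logical vector marking reverse-worded items that must
#'   be recoded (`x -> m + 1 - x`) before scoring; see
#'   [apply_reverse_coding()].
#' @param theta Optional per-person true trait values (simulation truth).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, m = NULL, group = NULL,
                            covariates = NULL, item_names = NULL,
                            reverse_flags = NULL, theta = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (is.null(m)) m <- max(responses, na.rm = TRUE)
  m <- as.integer(m)
  obs <- responses[!is.na(responses)]
  if (m < 2L) stop("'m' must be at least 2")
  if (any(obs < 1L | obs > m)) stop("observed responses must lie in 1..m")
  n <- nrow(responses); k <- ncol(responses)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(k))
  stopifnot(length(item_names) == k)
  if (is.null(reverse_flags)) reverse_flags <- rep(FALSE, k)
  stopifnot(length(reverse_flags) == k, is.logical(reverse_flags))
  if (!is.null(group)) {
    group <- as.factor(group)
    if (nlevels(group) != 2L) stop("'group' must have exactly two levels")
    stopifnot(length(group) == n)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
  }
  if (!is.null(theta)) stopifnot(length(theta) == n)
  colnames(responses) <- item_names
  structure(list(responses = responses, m = m, group = group,
                 covariates = covariates, item_names = item_names,
                 reverse_flags = reverse_flags, theta = theta),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d persons x %d items, %d categories\n",
              nrow(x$responses), ncol(x$responses), x$m))
  if (!is.null(x$group)) {
    cat("  groups:", paste(levels(x$group), table(x$group), collapse = " / "), "\n")
  }
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Recode reverse-worded items
#'
#' Applies `x -> m + 1 - x` to every item whose `reverse_flags` entry is
#' `TRUE` and clears the flags, so that higher scores indicate a higher
#' trait level on every item. Recoding happens at ingest, before any model
#' fitting or scoring.
#'
#' @param data A [response_matrix()].
#' @return A `response_matrix` with recoded responses and all flags `FALSE`.
#' @export
apply_reverse_coding <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  flip <- which(data$reverse_flags)
  if (length(flip)) {
    data$responses[, flip] <- data$m + 1L - data$responses[, flip]
    data$reverse_flags[] <- FALSE
  }
  data
}

#' Restrict a response matrix to a subset of items
#'
#' @param data A [response_matrix()].
#' @param items Integer indices of items to keep.
#' @return A `response_matrix` holding only the selected columns.
#' @export
subset_items <- function(data, items) {
  stopifnot(inherits(data, "response_matrix"))
  items <- as.integer(items)
  stopifnot(all(items >= 1L), all(items <= ncol(data$responses)))
  response_matrix(data$responses[, items, drop = FALSE], m = data$m,
                  group = data$group, covariates = data$covariates,
                  item_names = data$item_names[items],
                  reverse_flags = data$reverse_flags[items],
                  theta = data$theta)
}

#' Summed scale scores
#'
#' Row sums of the (optionally subsetted) response matrix. Persons with any
#' missing response on the chosen items receive `NA`: summed scores are only
#' defined for complete cases.
#'
#' @param data A [response_matrix()].
#' @param subset Item indices; defaults to all items.
#' @return Numeric vector of summed scores (NA for incomplete persons).
#' @export
summed_scores <- function(data, subset = seq_len(ncol(data$responses))) {
  x <- data$responses[, subset, drop = FALSE]
  out <- rowSums(x)
  out
}
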