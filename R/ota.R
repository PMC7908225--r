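# Optimal test assembly: pick the item subset of a given length maximizing
# the test information summed over anchor trait levels, as an exact 0/1
# selection problem solved by branch and bound, then scan lengths upward for
# the smallest subset that retains the full scale's reliability and
# validity.

#' Assembly problem for a fixed-length short form
#'
#' @param info_matrix Items x anchor-points matrix of item information
#'   values (all nonnegative), typically [item_information()] evaluated at
#'   the anchor points.
#' @param anchor_points The trait levels at which information is targeted;
#'   default `c(-3, -1, 0, 1, 3)`.
#' @param length Target number of items.
#' @param mandatory,forbidden Optional index sets forced into / out of the
#'   selection.
#' @return An object of class `assembly_problem`.
#' @export
assembly_problem <- function(info_matrix, anchor_points = c(-3, -1, 0, 1, 3),
                             length, mandatory = integer(0),
                             forbidden = integer(0)) {
  info_matrix <- as.matrix(info_matrix)
  stopifnot(all(info_matrix >= 0), ncol(info_matrix) == base::length(anchor_points))
  length <- as.integer(length)
  stopifnot(length >= 1L, length <= nrow(info_matrix))
  mandatory <- sort(unique(as.integer(mandatory)))
  forbidden <- sort(unique(as.integer(forbidden)))
  if (base::length(intersect(mandatory, forbidden))) {
    stop("an item cannot be both mandatory and forbidden")
  }
  if (base::length(mandatory) > length ||
      nrow(info_matrix) - base::length(forbidden) < length) {
    stop("infeasible mandatory/forbidden combination for the requested length")
  }
  structure(list(info_matrix = info_matrix, anchor_points = anchor_points,
                 length = length, mandatory = mandatory, forbidden = forbidden),
            class = "assembly_problem")
}

# depth-first branch and bound for max sum(s[selected]) with |selected| = L.
# Items are explored in decreasing-score order; the bound at a node is the
# current sum plus the best remaining completion. Returns the optimum value.
bb_max_value <- function(s, L) {
  ord <- order(-s)
  sv <- s[ord]
  n <- length(sv)
  suffix_top <- function(i, need) {
    # best completion using items i..n (already sorted): top `need` of them
    if (need == 0L) return(0)
    sum(sv[i:(i + need - 1L)])
  }
  best <- -Inf
  rec <- function(i, chosen, acc) {
    need <- L - chosen
    if (need == 0L) { if (acc > best) best <<- acc; return(invisible()) }
    if (i > n || n - i + 1L < need) return(invisible())
    if (acc + suffix_top(i, need) <= best) return(invisible())  # prune
    rec(i + 1L, chosen + 1L, acc + sv[i])                       # take item i
    rec(i + 1L, chosen, acc)                                    # skip item i
  }
  rec(1L, 0L, 0)
  best
}

#' Assemble the information-optimal subset of a fixed length
#'
#' Exact maximization of the summed anchor-point information over all
#' subsets of the requested size, by branch and bound with a sorted-prefix
#' upper bound. Among equal-objective subsets the lexicographically
#' smallest index set is returned. For this pure cardinality-constrained
#' objective the optimum provably coincides with picking the top items by
#' anchor-summed information; the branch-and-bound search and that greedy
#' closed form act as built-in cross-checks of one another.
#'
#' @param problem An [assembly_problem()].
#' @return An object of class `assembly_solution`: `selected` (sorted
#'   indices), `objective`, `optimal` (exactness certificate), and
#'   `scores` (per-item anchor-summed information).
#' @export
assemble_fixed_length <- function(problem) {
  stopifnot(inherits(problem, "assembly_problem"))
  s <- rowSums(problem$info_matrix)
  n <- length(s)
  L <- problem$length
  fixed_in <- problem$mandatory
  open <- setdiff(setdiff(seq_len(n), fixed_in), problem$forbidden)
  need <- L - length(fixed_in)
  z_open <- if (need > 0L) bb_max_value(s[open], need) else 0
  z_star <- sum(s[fixed_in]) + z_open
  # lexicographically smallest optimal completion: walk indices in order and
  # keep an item iff an optimal completion through it exists (checked with
  # the exact top-remaining bound).
  tolr <- 1e-9 * max(1, abs(z_star))
  sel <- fixed_in
  acc <- sum(s[fixed_in])
  remaining <- open
  while (length(sel) < L) {
    nd <- L - length(sel)
    for (pos in seq_along(remaining)) {
      i <- remaining[pos]
      rest <- remaining[-seq_len(pos)]
      if (length(rest) >= nd - 1L) {
        top_rest <- if (nd - 1L > 0L) {
          sum(sort(s[rest], decreasing = TRUE)[seq_len(nd - 1L)])
        } else 0
        if (acc + s[i] + top_rest >= z_star - tolr) {
          sel <- c(sel, i)
          acc <- acc + s[i]
          remaining <- rest
          break
        }
      }
    }
  }
  sel <- sort(sel)
  structure(list(selected = sel, objective = sum(s[sel]), optimal = TRUE,
                 scores = s, problem = problem),
            class = "assembly_solution")
}

#' Evaluate the short-form retention constraints on training data
#'
#' The three retention rules: (1) the subset's Cronbach's alpha is at least
#' `alpha_ratio` (default 95%) of the full set's alpha; (2) the Pearson
#' correlation of subset and full summed scores is at least `r_summed`
#' (default 0.9); (3) the correlation of subset and full EAP factor scores
#' is at least `r_factor` (default 0.9). During the search the subset EAP
#' scores use the full model's parameters restricted to the subset (no
#' refit), which keeps the scan deterministic and fast.
#'
#' @param subset Item indices (within `data`'s items).
#' @param data The training [response_matrix()] (the non-DIF item set).
#' @param model The [gpcm_model()] fitted to `data`.
#' @param thresholds Named list with `alpha_ratio`, `r_summed`, `r_factor`.
#' @return Data frame with one row per constraint: `value`, `threshold`,
#'   `pass`.
#' @export
evaluate_constraints <- function(subset, data, model,
                                 thresholds = list(alpha_ratio = 0.95,
                                                   r_summed = 0.9,
                                                   r_factor = 0.9)) {
  stopifnot(inherits(data, "response_matrix"))
  full <- seq_len(ncol(data$responses))
  alpha_full <- cronbach_alpha(data)$alpha
  alpha_sub <- cronbach_alpha(data, subset = subset)$alpha
  ss_full <- summed_scores(data)
  ss_sub <- summed_scores(data, subset)
  ok <- !is.na(ss_full) & !is.na(ss_sub)
  if (stats::sd(ss_sub[ok]) == 0) stop("zero-variance summed score for the subset")
  r_sum <- if (identical(sort(as.integer(subset)), full)) 1 else
    stats::cor(ss_sub[ok], ss_full[ok])
  th_full <- eap_scores(model, data)
  th_sub <- eap_scores(model, data, subset = subset)
  okf <- !is.na(th_full) & !is.na(th_sub)
  r_fac <- if (identical(sort(as.integer(subset)), full)) 1 else
    stats::cor(th_sub[okf], th_full[okf])
  data.frame(
    constraint = c("alpha_ratio", "r_summed", "r_factor"),
    value = c(alpha_sub / alpha_full, r_sum, r_fac),
    threshold = c(thresholds$alpha_ratio, thresholds$r_summed, thresholds$r_factor),
    pass = c(alpha_sub / alpha_full >= thresholds$alpha_ratio,
             r_sum >= thresholds$r_summed,
             r_fac >= thresholds$r_factor))
}

#' Minimal-length optimal short form
#'
#' Scans candidate lengths in ascending order; for each length assembles
#' the information-optimal subset over the anchor points and evaluates the
#' three retention constraints on the training data; returns the first
#' (minimal) length whose optimal subset passes all constraints, with the
#' complete per-length audit trail. If no length passes, a failure record
#' (not an exception) is returned.
#'
#' @param data Training [response_matrix()] restricted to the non-DIF
#'   items.
#' @param model [gpcm_model()] fitted to `data`.
#' @param lengths Candidate lengths; default `4:(k - 1)`.
#' @param anchor_points Trait levels for the information objective.
#' @param thresholds Constraint thresholds (see [evaluate_constraints()]).
#' @return A list of class `ota_result`: `feasible`, `length`, `selected`,
#'   `solution`, and `audit` (one row per length with objective, constraint
#'   values and pass flags).
#' @export
select_minimal_length <- function(data, model,
                                  lengths = NULL,
                                  anchor_points = c(-3, -1, 0, 1, 3),
                                  thresholds = list(alpha_ratio = 0.95,
                                                    r_summed = 0.9,
                                                    r_factor = 0.9)) {
  k <- ncol(data$responses)
  if (is.null(lengths)) lengths <- 4:(k - 1L)
  lengths <- lengths[lengths >= 1L & lengths <= k]
  if (!length(lengths)) stop("no candidate length is compatible with the item count")
  info <- t(vapply(model$items, function(it) item_information(it, anchor_points),
                   numeric(length(anchor_points))))
  audit <- NULL
  chosen <- NULL
  for (L in sort(lengths)) {
    sol <- assemble_fixed_length(assembly_problem(info, anchor_points, L))
    cons <- evaluate_constraints(sol$selected, data, model, thresholds)
    row <- data.frame(length = L,
                      selected = paste(sol$selected, collapse = ","),
                      objective = sol$objective,
                      alpha_ratio = cons$value[1], r_summed = cons$value[2],
                      r_factor = cons$value[3], pass = all(cons$pass))
    audit <- rbind(audit, row)
    if (all(cons$pass) && is.null(chosen)) {
      chosen <- list(length = L, solution = sol, constraints = cons)
      break
    }
  }
  if (is.null(chosen)) {
    return(structure(list(feasible = FALSE, length = NA_integer_,
                          selected = integer(0), solution = NULL,
                          audit = audit),
                     class = "ota_result"))
  }
  structure(list(feasible = TRUE, length = chosen$length,
                 selected = chosen$solution$selected,
                 solution = chosen$solution,
                 constraints = chosen$constraints, audit = audit),
            class = "ota_result")
}

#' @export
print.ota_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("Optimal short form: %d items (%s)\n", x$length,
                paste(x$selected, collapse = ", ")))
  } else {
    cat("No candidate length satisfied all retention constraints\n")
  }
  invisible(x)
}
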