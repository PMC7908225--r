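# End-to-end short-form construction: reverse-code, screen
# unidimensionality, fit the GPCM, remove gender-DIF items, assemble the
# minimal-length optimal short form, and evaluate it on the training and
# test samples.

#' Pipeline configuration
#'
#' Bundles every tunable of the short-form workflow. All thresholds are
#' configuration, never hard-coded downstream.
#'
#' @param anchor_points Trait levels for the assembly objective.
#' @param alpha_ratio,r_summed,r_factor Retention thresholds (defaults
#'   0.95, 0.9, 0.9).
#' @param dif_alpha Per-item DIF significance level (default 0.05).
#' @param lengths Candidate short-form lengths; `NULL` means
#'   `4:(items - 1)` after removals.
#' @param run_efa_screen,run_dif Stage toggles.
#' @param ratio_threshold,variance_threshold Unidimensionality cutoffs.
#' @param n_anchors MaxA5 anchor count.
#' @param seed Seed recorded in the report (generation seeds live in the
#'   synthetic configs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(anchor_points = c(-3, -1, 0, 1, 3),
                            alpha_ratio = 0.95, r_summed = 0.9,
                            r_factor = 0.9, dif_alpha = 0.05,
                            lengths = NULL,
                            run_efa_screen = TRUE, run_dif = TRUE,
                            ratio_threshold = 3, variance_threshold = 0.20,
                            n_anchors = 5L, seed = 1L) {
  stopifnot(alpha_ratio > 0, alpha_ratio <= 1,
            r_summed > 0, r_summed <= 1, r_factor > 0, r_factor <= 1,
            dif_alpha > 0, dif_alpha < 1,
            all(is.finite(anchor_points)), !is.unsorted(anchor_points))
  structure(list(anchor_points = anchor_points,
                 thresholds = list(alpha_ratio = alpha_ratio,
                                   r_summed = r_summed, r_factor = r_factor),
                 dif_alpha = dif_alpha, lengths = lengths,
                 run_efa_screen = run_efa_screen, run_dif = run_dif,
                 ratio_threshold = ratio_threshold,
                 variance_threshold = variance_threshold,
                 n_anchors = as.integer(n_anchors), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full short-form construction workflow
#'
#' Stage order is fixed: reverse-code both samples; screen essential
#' unidimensionality on the training sample and drop negative-loading
#' items; fit the full-scale and screened GPCMs; run the iterative Wald DIF
#' procedure and drop flagged items; scan lengths for the minimal
#' information-optimal subset passing the retention constraints; evaluate
#' the chosen short form on the training and (if given) test samples. The
#' item set shrinks monotonically until assembly. Every stage's outputs are
#' collected in the returned report; with `out_dir` set, tabular artifacts
#' are also written as CSV/JSON.
#'
#' @param train Training [response_matrix()] (item selection sample).
#' @param test Optional test [response_matrix()] (confirmation sample);
#'   strongly recommended — a single-sample run warns.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @param verbose Print stage progress.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(train, test = NULL, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(train, "response_matrix"), inherits(config, "pipeline_config"))
  if (is.null(test)) {
    warning("no test sample supplied: short-form performance is evaluated ",
            "on the selection sample only and will be optimistic")
  }
  say <- function(...) if (verbose) message(...)
  report <- list(config = config, item_names = train$item_names,
                 stages = character(0))
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. reverse-code
  train <- stage("reverse_code", apply_reverse_coding(train))
  if (!is.null(test)) test <- apply_reverse_coding(test)
  report$stages <- c(report$stages, "reverse_code")
  k_all <- ncol(train$responses)
  keep <- seq_len(k_all)

  # 2. unidimensionality screen
  efa_removed <- integer(0)
  if (config$run_efa_screen) {
    efa <- stage("efa_screen", efa_screen(train))
    check <- unidimensionality_check(efa, config$ratio_threshold,
                                     config$variance_threshold)
    efa_removed <- check$remove_items
    report$efa <- efa
    report$unidimensionality <- check
    keep <- setdiff(keep, efa_removed)
    report$stages <- c(report$stages, "efa_screen")
  }
  report$efa_removed <- efa_removed
  screened <- subset_items(train, keep)

  # 3. GPCM fits: full original scale (information reference) and screened
  full_model <- stage("gpcm_full", fit_gpcm(train))
  screened_model <- if (length(efa_removed)) {
    stage("gpcm_screened", fit_gpcm(screened))
  } else full_model
  report$full_model <- full_model
  report$screened_model <- screened_model
  report$stages <- c(report$stages, "gpcm_fit")

  # 4. iterative Wald DIF
  dif_removed_orig <- integer(0)
  if (config$run_dif) {
    if (is.null(screened$group)) stop("DIF stage requested but no group labels present")
    dif <- stage("dif", iterative_wald(screened, baseline_model = screened_model,
                                       alpha = config$dif_alpha,
                                       n_anchors = config$n_anchors,
                                       verbose = verbose))
    report$dif <- dif
    dif_removed_orig <- keep[dif$removed]      # back to original indices
    keep <- setdiff(keep, dif_removed_orig)
    report$stages <- c(report$stages, "dif")
  }
  report$dif_removed <- dif_removed_orig
  report$kept_items <- keep

  nondif <- subset_items(train, keep)
  nondif_model <- if (length(c(efa_removed, dif_removed_orig))) {
    stage("gpcm_nondif", fit_gpcm(nondif))
  } else full_model

  # 5. optimal test assembly over the non-DIF set
  lengths <- config$lengths
  if (is.null(lengths)) lengths <- 4:(length(keep) - 1L)
  ota <- stage("ota", select_minimal_length(nondif, nondif_model,
                                            lengths = lengths,
                                            anchor_points = config$anchor_points,
                                            thresholds = config$thresholds))
  report$ota <- ota
  report$stages <- c(report$stages, "ota")

  # 6. evaluation (training + test)
  if (ota$feasible) {
    subset_orig <- keep[ota$selected]
    report$short_form <- subset_orig
    test_nondif <- NULL
    test_ref_model <- NULL
    if (!is.null(test)) {
      test_nondif <- subset_items(test, keep)
      test_ref_model <- stage("gpcm_test_full", fit_gpcm(test))
    }
    report$evaluation <- stage("evaluation",
      evaluate_short_form(nondif, ota$selected, nondif_model,
                          test = test_nondif,
                          reference_model = full_model,
                          test_reference_model = test_ref_model))
    report$stages <- c(report$stages, "evaluation")
  } else {
    report$short_form <- integer(0)
    report$infeasible <- TRUE
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Short-form construction report\n")
  cat("  screened out (negative loading):",
      if (length(x$efa_removed)) paste(x$efa_removed, collapse = ", ") else "none", "\n")
  cat("  removed for DIF:",
      if (length(x$dif_removed)) paste(x$dif_removed, collapse = ", ") else "none", "\n")
  if (length(x$short_form)) {
    cat("  short form (original item numbers):",
        paste(x$short_form, collapse = ", "), "\n")
    tr <- x$evaluation$training
    cat(sprintf("  training alpha %.3f, r(summed) %.3f, r(factor) %.3f\n",
                tr$alpha_subset$alpha, tr$r_summed$r, tr$r_factor$r))
    cat(sprintf("  information retention: %.1f%% (full range), %.1f%% (-3..3)\n",
                tr$information$retention_full, tr$information$retention_range33))
  } else {
    cat("  no feasible short form under the configured constraints\n")
  }
  invisible(x)
}

#' Write pipeline artifacts to disk
#'
#' Audit trail and DIF tables as CSV; the overall report (selected items,
#' constraint values, fit indices, retention) as JSON.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the directory.
#' @export
write_pipeline_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(report$ota)) {
    utils::write.csv(report$ota$audit, file.path(out_dir, "ota_audit.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$dif)) {
    utils::write.csv(report$dif$wald2, file.path(out_dir, "dif_wald2.csv"),
                     row.names = FALSE)
    utils::write.csv(report$dif$wald1, file.path(out_dir, "dif_wald1.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    efa_removed = report$efa_removed,
    dif_removed = report$dif_removed,
    anchors = if (!is.null(report$dif)) report$dif$anchors else NULL,
    short_form = report$short_form,
    seed = report$config$seed)
  if (length(report$short_form)) {
    tr <- report$evaluation$training
    summary$training <- list(
      alpha = tr$alpha_subset$alpha, alpha_ci = tr$alpha_subset$ci,
      r_summed = tr$r_summed$r, r_factor = tr$r_factor$r,
      cfa = tr$cfa[c("chi2", "df", "rmsea", "srmr", "cfi")],
      retention_full = tr$information$retention_full,
      retention_range33 = tr$information$retention_range33)
    if (!is.null(report$evaluation$test)) {
      te <- report$evaluation$test
      summary$test <- list(
        alpha = te$alpha_subset$alpha,
        cfa = te$cfa[c("chi2", "df", "rmsea", "srmr", "cfi")],
        retention_full = te$information$retention_full,
        retention_range33 = te$information$retention_range33)
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
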