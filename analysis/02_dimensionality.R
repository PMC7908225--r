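# Essential-unidimensionality screen of the training sample: polychoric
# correlations, KMO, Bartlett's test, minres factoring, and the
# eigenvalue-ratio / variance rule. Items with a negative first-factor
# loading are slated for removal.

source("analysis/00_config.R")

train <- make_samples()$train
efa <- efa_screen(train)
chk <- unidimensionality_check(efa)

message(sprintf("KMO = %.2f; Bartlett chi2(%d) = %.1f, p = %.3g",
                efa$kmo, efa$bartlett$df, efa$bartlett$statistic,
                efa$bartlett$p_value))
message(sprintf("eigenvalue ratio %.2f (first two: %.2f, %.2f); first factor %.1f%% of variance",
                chk$eigenvalue_ratio, efa$eigenvalues[1], efa$eigenvalues[2],
                100 * chk$variance_first))
message("essential unidimensionality: ", if (chk$pass) "PASS" else "FAIL")
message("negative-loading items to remove: ",
        if (length(chk$remove_items)) paste(chk$remove_items, collapse = ", ") else "none")

dir <- results_dir()
write.csv(round(efa$polychoric, 4), file.path(dir, "polychoric.csv"))
write.csv(data.frame(item = seq_len(nrow(efa$loadings)),
                     loading_f1 = round(efa$loadings[, 1], 4),
                     uniqueness = round(efa$uniquenesses, 4)),
          file.path(dir, "efa_loadings.csv"), row.names = FALSE)
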