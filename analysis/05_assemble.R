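# Optimal test assembly on the non-DIF item set: for each candidate length
# the information-optimal subset at the anchor points (-3, -1, 0, 1, 3),
# stopping at the minimal length that retains >= 95% of Cronbach's alpha
# and >= 0.9 summed-score and factor-score correlations.

source("analysis/00_config.R")

pipe <- run_pipeline(make_samples()$train,
                     config = pipeline_config(), verbose = TRUE) |>
  suppressWarnings()

message("per-length audit:")
print(pipe$ota$audit, digits = 4)
if (pipe$ota$feasible) {
  message("minimal feasible length: ", pipe$ota$length,
          "; selected items (original numbering): ",
          paste(pipe$short_form, collapse = ", "))
} else {
  message("no candidate length satisfied the constraints")
}

dir <- results_dir()
write.csv(pipe$ota$audit, file.path(dir, "ota_audit.csv"), row.names = FALSE)
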