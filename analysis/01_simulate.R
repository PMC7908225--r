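# Generate the two synthetic survey samples and write them (plus the
# simulation truth) under results/data/.

source("analysis/00_config.R")

samples <- make_samples()
dir <- results_dir("data")
write_simulation(samples$train, dir, stem = "train")
write_simulation(samples$test, dir, stem = "test")

message("training sample: ", nrow(samples$train$responses), " persons, ",
        ncol(samples$train$responses), " items (",
        sum(samples$train$group == "focal"), " focal)")
message("test sample: ", nrow(samples$test$responses), " persons")
message("covariate-trait correlations (train): ",
        paste(round(sapply(samples$train$covariates, cor, samples$train$theta), 3),
              collapse = ", "))
message("written to ", dir)
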