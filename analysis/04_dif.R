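# Gender DIF on the screened training items via the iterative Wald
# procedure: all-others-as-anchors screen, MaxA5 anchors, anchored Wald-1
# tests, removal at p < 0.05.

source("analysis/00_config.R")

train <- make_samples()$train
efa <- efa_screen(train)
keep <- setdiff(seq_len(ncol(train$responses)),
                unidimensionality_check(efa)$remove_items)
screened <- subset_items(train, keep)

dif <- iterative_wald(screened, verbose = TRUE)
print(dif)
message(sprintf("focal-group prior: mean %.2f, sd %.2f",
                dif$focal_prior["mean"], dif$focal_prior["sd"]))

dir <- results_dir()
w2 <- dif$wald2; w2$item <- keep[w2$item]
w1 <- dif$wald1; w1$item <- keep[w1$item]
write.csv(w2, file.path(dir, "dif_wald2.csv"), row.names = FALSE)
write.csv(w1, file.path(dir, "dif_wald1.csv"), row.names = FALSE)
message("Wald tables written to ", dir)
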