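# Shared study configuration for the analysis scripts. The synthetic study
# mirrors a two-sample questionnaire survey: a 12-item, 6-category
# instrument with an 8-item informative core (items 1-8), two weak filler
# items (9, 10), one item with planted gender DIF (11: uniform threshold
# shift of 1.0 in the focal group) and one undeclared reverse-oriented item
# (12). Training sample n = 569 (item selection), test sample n = 500
# (confirmation); 37% of respondents in the focal group; two covariates
# correlated +0.27 / -0.11 with the latent trait.

library(shortform)

STUDY_SEED <- 20210120L

study_config <- function(n, seed) {
  synthetic_config(
    n_persons = n, n_items = 12,
    discriminations = c(1.7, 1.2, 1.2, 1.1, 0.85, 0.8, 0.7, 0.6,
                        0.3, 0.25, 0.65, 0.4),
    dif_spec = list(list(item = 11, parameter = "b", shift = 1.0)),
    reversed_items = 12,
    covariate_correlations = c(neuroticism = 0.27, extraversion = -0.11),
    focal_fraction = 0.37, seed = seed)
}

make_samples <- function(seed = STUDY_SEED) {
  list(train = simulate_responses(generate_true_model(study_config(569, seed)),
                                  study_config(569, seed)),
       test = simulate_responses(generate_true_model(study_config(500, seed + 1L)),
                                 study_config(500, seed + 1L)))
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}
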