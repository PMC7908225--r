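#' Published calibration of the 21-item Chinese WNSS
#'
#' The published GPCM discrimination and integrated item-information values
#' for the 21 items of the traditional Chinese Weinstein Noise Sensitivity
#' Scale, shipped as a plain-text fixture. These printed estimates are the
#' only publicly available calibration of the instrument (the raw survey
#' data were never deposited) and are used for in-table arithmetic checks:
#' summing the per-item information, ranking discriminations for anchor
#' selection, and computing information-retention percentages.
#'
#' @return Data frame with columns `item`, `discrimination`, `information`,
#'   `in_short_form` (membership in the published 8-item short form) and
#'   `in_nss_sf` (membership in the pre-existing 5-item short form).
#' @export
published_wnss_items <- function() {
  utils::read.csv(system.file("extdata", "wnss_published_items.csv",
                              package = "shortform"),
                  stringsAsFactors = FALSE)
}

#' Published test-information totals for the WNSS and its short forms
#'
#' Integrated test information of the full 21-item scale, the 8-item
#' optimal short form, and the 5-item legacy short form, over the entire
#' trait range and over (-3, 3), as published for the training sample.
#'
#' @return Data frame with columns `scale`, `range` (`"full"` or
#'   `"range33"`), `information`.
#' @export
published_wnss_totals <- function() {
  utils::read.csv(system.file("extdata", "wnss_published_totals.csv",
                              package = "shortform"),
                  stringsAsFactors = FALSE)
}
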