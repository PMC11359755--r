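# Shared fixture builders. All data is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

simple_meta <- function(n, instrument = "inst", scan_mode = "static",
                        replicate = 1L, group = NULL) {
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    replicate = replicate,
    instrument = instrument,
    scan_mode = scan_mode,
    group = group %||% sprintf("g%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small reflectance set with smooth random spectra.
random_reflectance <- function(n = 4L, wl = seq(1454, 1554, by = 4), seed = 1) {
  set.seed(seed)
  vals <- t(vapply(seq_len(n), function(i) {
    0.3 + 0.4 * plogis(cumsum(rnorm(length(wl), 0, 0.2)))
  }, numeric(length(wl))))
  spectra_set(wl, vals, simple_meta(n), domain = "reflectance")
}

absorbance_set <- function(wl, values, ...) {
  n <- nrow(as.matrix(values))
  spectra_set(wl, values, simple_meta(n, ...), domain = "absorbance")
}

# Fast low-noise campaign config for pipeline-level tests.
small_campaign_config <- function(seed, n_samples = 150L, n_groups = 30L, ...) {
  synthetic_config(seed = seed, n_samples = n_samples, n_groups = n_groups,
                   replicates = 2L, ...)
}
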