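test_that("generated reference chemistry matches its distribution targets", {
  cfg <- synthetic_config(seed = 31, n_samples = 2000L, n_groups = 111L)
  refs <- generate_reference(cfg)
  st <- default_reference_stats()

  # CP distribution: mean and SD near targets (truncation shrinks the SD a
  # few percent), and the truncation bounds are hard
  cp <- refs$CP
  expect_equal(mean(cp), st$mean[st$constituent == "CP"], tolerance = 0.3 / 17.62)
  expect_lt(abs(sd(cp) - st$sd[st$constituent == "CP"]), 0.3)
  for (cc in FORAGE_CONSTITUENTS) {
    b <- st[st$constituent == cc, ]
    expect_true(all(refs[[cc]] >= b$min & refs[[cc]] <= b$max))
  }
  # every bunker used; within-bunker correlation positive (group intercepts)
  expect_equal(length(unique(refs$group)), 111L)
  gm <- tapply(refs$CP, refs$group, mean)
  expect_gt(var(gm), 0)

  # degenerate config: all SDs zero collapses every sample onto the mean
  st0 <- st; st0$sd <- 0
  cfg0 <- synthetic_config(seed = 1, n_samples = 10L, n_groups = 2L,
                           reference_stats = st0)
  refs0 <- generate_reference(cfg0)
  for (cc in FORAGE_CONSTITUENTS) {
    expect_equal(refs0[[cc]], rep(st$mean[st$constituent == cc], 10))
  }

  # infeasible truncation rejected
  st_bad <- st; st_bad$min[1] <- st_bad$max[1]
  expect_error(synthetic_config(reference_stats = st_bad), "min >= max")
})

test_that("spectra are built from the configured bands, water and noise model", {
  st <- default_reference_stats(); st$mean[] <- 0; st$sd[] <- 0
  st$min[] <- -1; st$max[] <- 1
  base_cfg <- function(...) {
    args <- list(seed = 5, n_samples = 4L, n_groups = 2L, replicates = 1L,
                 reference_stats = st, moisture_range = c(0, 0),
                 baseline_offset_range = c(0, 0), baseline_slope_range = c(0, 0),
                 scatter_sd = 0, noise_sd = 0, heterogeneity_sd = 0,
                 water_center_jitter_sd = 0)
    do.call(synthetic_config, utils::modifyList(args, list(...)))
  }
  # all concentrations 0, moisture 0, no noise/baseline -> A = 0, R = 1
  refs <- generate_reference(base_cfg())
  sp <- generate_spectra(refs, base_cfg(), "agrocares", "static")
  expect_equal(max(abs(sp$values - 1)), 0, tolerance = 1e-6)

  # moisture-only sample: global absorbance max at the grid point nearest 1904
  cfgw <- base_cfg(moisture_range = c(0.6, 0.6))
  refsw <- generate_reference(cfgw)
  spw <- generate_spectra(refsw, cfgw, "agrocares", "static")
  A <- -log10(spw$values)
  grid <- spw$wavelengths
  expect_equal(grid[apply(A, 1, which.max)],
               rep(grid[which.min(abs(grid - 1904))], 4))

  # a constituent without reference values is a config error
  bad_lib <- c(default_band_library(), list(XYZ = data.frame(
    center_nm = 2000, width_nm = 30, amplitude = 0.001)))
  cfg_bad <- synthetic_config(seed = 1, n_samples = 4L, n_groups = 2L,
                              band_library = bad_lib)
  refs_b <- generate_reference(cfg_bad)
  expect_error(generate_spectra(refs_b, cfg_bad, "agrocares", "static"),
               "without reference")
})

test_that("sub-spot averaging reduces replicate-to-replicate variance ~ 1/m", {
  # heterogeneity only: moving (5 sub-spots) variance ~ 1/5 of static (1)
  cfg <- synthetic_config(seed = 7, n_samples = 2L, n_groups = 2L,
                          replicates = 250L, heterogeneity_sd = 0.1,
                          scatter_sd = 0, noise_sd = 0,
                          baseline_offset_range = c(0.03, 0.03),
                          baseline_slope_range = c(0, 0),
                          water_center_jitter_sd = 0)
  refs <- generate_reference(cfg)
  v_at_band <- function(mode) {
    sp <- generate_spectra(refs, cfg, "agrocares", mode, seed = 99)
    A <- -log10(sp$values)
    j <- which.min(abs(sp$wavelengths - 1904))   # strongest water band
    mean(tapply(A[, j], sp$meta$sample_id, var))
  }
  ratio <- v_at_band("moving") / v_at_band("static")
  expect_equal(ratio, 1 / 5, tolerance = 0.35)
})

test_that("campaigns are reproducible and reflect the emulated study design", {
  cfg <- small_campaign_config(seed = 17)
  streams <- data.frame(instrument = c("agrocares", "neospectra"),
                        scan_mode = c("static", "turntable"),
                        stringsAsFactors = FALSE)
  c1 <- make_campaign(cfg, streams)
  c2 <- make_campaign(cfg, streams)
  expect_identical(c1$reference, c2$reference)
  expect_identical(c1$spectra, c2$spectra)

  expect_equal(nrow(c1$reference), 150L)
  expect_equal(length(unique(c1$reference$group)), 30L)
  for (s in c1$spectra) {
    expect_equal(n_spectra(s), 150L * 2L)     # replicates x samples
    expect_identical(s$domain, "reflectance")
  }
  # default design: 600 samples, 111 bunkers, 5 replicates
  dflt <- synthetic_config()
  expect_equal(dflt$n_samples, 600L)
  expect_equal(dflt$n_groups, 111L)
  expect_equal(dflt$replicates, 5L)
  expect_equal(unname(dflt$subspots), c(1L, 5L, 10L))

  # written-to-disk campaign round-trips through the I/O layer
  p1 <- tempfile(fileext = ".csv")
  write_spectra(c1$spectra[[1]], p1)
  back <- read_spectra(p1)
  expect_equal(back$values, c1$spectra[[1]]$values, tolerance = 1e-12)
  p2 <- tempfile(fileext = ".csv")
  write_reference(c1$reference, p2)
  refs_back <- read_reference(p2)
  expect_equal(refs_back$CP, c1$reference$CP, tolerance = 1e-12)
  expect_identical(refs_back$group, c1$reference$group)
})
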