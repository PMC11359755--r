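test_that("wide-CSV spectra parse, reject malformed input, and round-trip", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,replicate,instrument,scan_mode,group,1454,1458",
    "a,1,inst,static,g1,0.5,0.6",
    "b,1,inst,static,g1,0.4,0.3"
  ), path)
  s <- read_spectra(path)
  expect_equal(s$wavelengths, c(1454, 1458))
  expect_equal(n_spectra(s), 2L)
  expect_equal(s$values[1, ], c(0.5, 0.6))
  expect_identical(s$domain, "reflectance")

  # duplicate key rejected
  writeLines(c(
    "sample_id,replicate,instrument,scan_mode,group,1454,1458",
    "a,1,inst,static,g1,0.5,0.6",
    "a,1,inst,static,g1,0.4,0.3"
  ), path)
  expect_error(read_spectra(path), "duplicate")

  # missing metadata column and non-monotone headers
  writeLines(c("sample_id,replicate,instrument,group,1454,1458",
               "a,1,inst,g1,0.5,0.6"), path)
  expect_error(read_spectra(path), "missing metadata")
  writeLines(c("sample_id,replicate,instrument,scan_mode,group,1458,1454",
               "a,1,inst,static,g1,0.5,0.6"), path)
  expect_error(read_spectra(path), "increasing")

  # unparseable cells dropped with row report
  writeLines(c(
    "sample_id,replicate,instrument,scan_mode,group,1454,1458",
    "a,1,inst,static,g1,0.5,0.6",
    "b,1,inst,static,g1,oops,0.3"
  ), path)
  expect_warning(s2 <- read_spectra(path), "row")
  expect_equal(n_spectra(s2), 1L)

  # write/read round trip is identity on values (12 significant digits) and metadata
  for (seed in 1:3) {
    s3 <- random_reflectance(n = 5L, seed = seed)
    out <- tempfile(fileext = ".csv")
    write_spectra(s3, out)
    s4 <- read_spectra(out)
    expect_equal(s4$values, s3$values, tolerance = 1e-12)
    expect_equal(s4$wavelengths, s3$wavelengths)
    expect_equal(s4$meta, s3$meta)
    expect_true(file.exists(paste0(out, ".log")))
  }
})

test_that("spectra_set enforces its invariants", {
  meta <- simple_meta(2)
  expect_error(spectra_set(c(1458, 1454), matrix(0.5, 2, 2), meta), "increasing")
  expect_error(spectra_set(c(1454, 1458), matrix(1.5, 2, 2), meta), "reflectance")
  expect_error(spectra_set(c(1454, 1458), matrix(0.5, 2, 3), meta), "columns")
  expect_error(spectra_set(1454, matrix(0.5, 2, 1), meta), "length")
  meta2 <- meta; meta2$scan_mode <- "waved"
  expect_error(spectra_set(c(1454, 1458), matrix(0.5, 2, 2), meta2), "scan_mode")
})

test_that("absorbance transform is log10(1/R) and inverts exactly", {
  wl <- c(1454, 1458, 1462)
  s <- spectra_set(wl, rbind(c(1, 0.1, 0.25)), simple_meta(1))
  a <- to_absorbance(s)
  expect_identical(a$domain, "absorbance")
  expect_equal(a$values[1, ], c(0, 1, 0.6020599913), tolerance = 1e-10)

  # inverse round trip to 12 significant digits
  s2 <- random_reflectance(n = 3L, seed = 7)
  a2 <- to_absorbance(s2)
  back <- 10^(-a2$values)
  expect_equal(back, s2$values, tolerance = 1e-12)

  s3 <- spectra_set(wl, rbind(c(0.5, 0.5, 0.5)), simple_meta(1), "absorbance")
  expect_error(to_absorbance(s3), "reflectance")
})

test_that("linear resampling is exact on affine spectra and refuses extrapolation", {
  # midpoint of a straight segment
  s <- spectra_set(c(1450, 1458), rbind(c(1e-6, 1)), simple_meta(1), "absorbance")
  r <- resample_to_grid(s, 1450, 1458, 4)
  expect_equal(r$values[1, 2], 0.5, tolerance = 1e-6)

  # affine function reproduced exactly at all target nodes
  wl <- seq(1400, 1600, by = 7)
  a <- 0.2; b <- 1e-3
  s2 <- absorbance_set(wl, rbind(a + b * wl, 2 * a - b * wl))
  r2 <- resample_to_grid(s2, 1404, 1596, 4)
  expect_equal(r2$values[1, ], a + b * r2$wavelengths, tolerance = 1e-12)
  expect_equal(r2$values[2, ], 2 * a - b * r2$wavelengths, tolerance = 1e-12)

  # identity when grids match
  r3 <- resample_to_grid(s2, 1400, 1400 + 7 * (length(wl) - 1), 7)
  expect_equal(r3$values, s2$values)

  # linearity in the spectra
  set.seed(3)
  v1 <- runif(length(wl)); v2 <- runif(length(wl))
  mix <- absorbance_set(wl, rbind(v1, v2, 0.3 * v1 + 1.7 * v2))
  rm1 <- resample_to_grid(mix, 1410, 1590, 11)
  expect_equal(rm1$values[3, ], 0.3 * rm1$values[1, ] + 1.7 * rm1$values[2, ],
               tolerance = 1e-12)

  expect_error(resample_to_grid(s2, 1300, 1500, 4), "extrapolate")
})

test_that("replicate aggregation averages correctly and reduces variance by 1/m", {
  wl <- seq(1454, 1470, 4)
  meta <- data.frame(sample_id = "a", replicate = 1:2, instrument = "i",
                     scan_mode = "static", group = "g")
  s <- spectra_set(wl, rbind(rep(0, 5), rep(2, 5)), meta, "absorbance")
  m <- aggregate_replicates(s, "mean")
  expect_equal(n_spectra(m), 1L)
  expect_equal(m$values[1, ], rep(1, 5))
  expect_identical(aggregate_replicates(s, "keep_all"), s)

  # idempotence on identical replicates
  meta5 <- data.frame(sample_id = "a", replicate = 1:5, instrument = "i",
                      scan_mode = "static", group = "g")
  s5 <- spectra_set(wl, matrix(0.7, 5, 5), meta5, "absorbance")
  expect_equal(aggregate_replicates(s5, "mean")$values[1, ], rep(0.7, 5))

  # Monte-Carlo: variance of the mean of m independent replicates ~ sigma^2/m
  set.seed(42)
  m_rep <- 5L; n_draw <- 400L; sigma <- 0.1
  means <- replicate(n_draw, {
    vals <- matrix(rnorm(m_rep * 5, 1, sigma), m_rep, 5)
    mm <- spectra_set(wl, vals, meta5, "absorbance")
    aggregate_replicates(mm, "mean")$values[1, 1]
  })
  expect_equal(var(means), sigma^2 / m_rep, tolerance = 0.25)
})
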