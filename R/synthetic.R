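# Seeded generator of haylage-like reference chemistry and multi-instrument,
# multi-scan-mode NIR reflectance spectra.
#
# The generative model: each sample has a constituent vector (truncated
# multivariate normal with bunker-level random intercepts) and a moisture
# fraction. Absorbance is a sum of Gaussian bands -- per-constituent band
# profiles scaled by concentration, plus the water O-H band profile scaled by
# moisture (with a small per-sample band-centre jitter emulating
# hydrogen-bonding shifts) -- plus a per-replicate baseline and multiplicative
# scatter. Scan modes differ in the number of sub-spots whose heterogeneous
# compositions are averaged within one scan (static 1, moving 5, turntable
# 10); instruments differ in wavelength grid and line-shape width. White
# noise is added on the instrument grid and reflectance is emitted as
# R = 10^(-A).

#' Default per-constituent absorption band library
#'
#' Gaussian band parameters (centre nm, width nm, absorbance per %DM) for the
#' chemically expressed constituents: crude protein near the N-H combination
#' bands (2055, 2180 nm), fiber fractions near C-H/C-O bands (1730, 2100,
#' 2270-2330 nm), lignin sharing the fiber bands at low amplitude.
#' Digestibility measures (IVTD, NDFD) are deliberately absent: they are not
#' chemical species, so their NIR signal arises only indirectly through
#' correlation with the banded constituents.
#'
#' @return Named list of data frames with columns `center_nm`, `width_nm`,
#'   `amplitude`.
#' @export
default_band_library <- function() {
  list(
    CP = data.frame(center_nm = c(2055, 2180),
                    width_nm = c(40, 45),
                    amplitude = c(0.0060, 0.0050)),
    aNDF = data.frame(center_nm = c(1730, 2100, 2310),
                      width_nm = c(35, 50, 40),
                      amplitude = c(0.0040, 0.0045, 0.0035)),
    ADF = data.frame(center_nm = c(1736, 2270, 2330),
                     width_nm = c(30, 35, 35),
                     amplitude = c(0.0030, 0.0035, 0.0030)),
    ADL = data.frame(center_nm = c(1680, 2100, 2270),
                     width_nm = c(40, 50, 35),
                     amplitude = c(0.0010, 0.0008, 0.0012))
  )
}

#' Default inter-constituent correlation matrix
#'
#' Plausible correlations for mixed alfalfa-grass haylage: fiber fractions
#' strongly positively correlated with each other, protein negatively
#' correlated with fiber, digestibility negatively correlated with fiber and
#' lignin and positively with protein.
#'
#' @return Symmetric positive-definite 6x6 matrix in [FORAGE_CONSTITUENTS]
#'   order.
#' @export
default_reference_correlation <- function() {
  cn <- FORAGE_CONSTITUENTS
  R <- diag(6)
  dimnames(R) <- list(cn, cn)
  set_cor <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_cor("IVTD", "aNDF", -0.70); set_cor("IVTD", "NDFD", 0.70)
  set_cor("IVTD", "ADF", -0.75);  set_cor("IVTD", "ADL", -0.70)
  set_cor("IVTD", "CP", 0.45)
  set_cor("aNDF", "NDFD", -0.30); set_cor("aNDF", "ADF", 0.85)
  set_cor("aNDF", "ADL", 0.55);   set_cor("aNDF", "CP", -0.65)
  set_cor("NDFD", "ADF", -0.40);  set_cor("NDFD", "ADL", -0.55)
  set_cor("NDFD", "CP", 0.30)
  set_cor("ADF", "ADL", 0.65);    set_cor("ADF", "CP", -0.55)
  set_cor("ADL", "CP", -0.30)
  R
}

#' Default instrument definitions
#'
#' Two fixed-grid instruments reporting 1454-2446 nm at a 4 nm step with a
#' delta line-shape, and one wide-range instrument reporting 1350-2550 nm on
#' a variable grid (step 2.5-8.8 nm) with a 16 nm FWHM Gaussian line-shape.
#'
#' @return Named list; each element has `grid` (wavelengths, nm) and
#'   `fwhm_nm`.
#' @export
default_instruments <- function() {
  list(
    agrocares = list(grid = seq(1454, 2446, by = 4), fwhm_nm = 0),
    trinamix = list(grid = seq(1454, 2446, by = 4), fwhm_nm = 0),
    neospectra = list(grid = variable_step_grid(1350, 2550, 2.5, 8.8), fwhm_nm = 16)
  )
}

# Variable-step grid: densest mid-range, coarsest at the extremes
# (deterministic; step varies quadratically between min_step and max_step).
variable_step_grid <- function(from, to, min_step, max_step) {
  mid <- (from + to) / 2
  half <- (to - from) / 2
  lam <- from
  out <- numeric(0)
  while (lam < to) {
    out <- c(out, lam)
    step <- min_step + (max_step - min_step) * ((lam - mid) / half)^2
    lam <- lam + step
  }
  c(out, to)
}

#' Configuration of the synthetic campaign generator
#'
#' Defaults emulate the sampling design the pipeline targets: 600 samples
#' from 111 farm bunkers, five replicate scans per sample, three instruments
#' and three scan modes.
#'
#' @param n_samples Number of samples (default 600).
#' @param n_groups Number of groups/bunkers (default 111).
#' @param replicates Replicate scans per sample per stream (default 5).
#' @param reference_stats Distribution targets (mean, sd, min, max per
#'   constituent); default [default_reference_stats()].
#' @param reference_correlation Inter-constituent correlation matrix.
#' @param group_sd_fraction Fraction of each constituent's SD attributed to
#'   bunker-level random intercepts (default 0.3).
#' @param band_library Per-constituent Gaussian band parameters.
#' @param water_bands Water band table ([water_band_table()]).
#' @param water_intensity_ratios Relative band amplitudes,
#'   very_small : large : very_large (default 1:10:25).
#' @param water_band_widths_nm Gaussian widths of the water bands (same order
#'   as `water_bands`).
#' @param water_amplitude Absorbance of the very-large band per unit moisture
#'   fraction (default 1.2).
#' @param water_center_jitter_sd Per-sample SD (nm) of the water band-centre
#'   shift emulating hydrogen-bonding matrix effects (default 2).
#' @param moisture_range Uniform range of the fresh-basis moisture fraction
#'   (default 0.45-0.70, typical of haylage).
#' @param baseline_offset_range,baseline_slope_range Per-replicate additive
#'   baseline (absorbance units; slope per nm).
#' @param scatter_sd SD of the per-sub-spot multiplicative scatter factor.
#' @param noise_sd SD of the white noise added on the instrument grid
#'   (absorbance units).
#' @param heterogeneity_sd Relative SD tau of sub-spot composition
#'   perturbations (default 0.08).
#' @param subspots Sub-spots averaged per scan, by mode.
#' @param instruments Instrument definitions ([default_instruments()]).
#' @param seed Master seed; mandatory for reproducible campaigns.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 600L, n_groups = 111L, replicates = 5L,
                             reference_stats = default_reference_stats(),
                             reference_correlation = default_reference_correlation(),
                             group_sd_fraction = 0.3,
                             band_library = default_band_library(),
                             water_bands = water_band_table(),
                             water_intensity_ratios = c(very_small = 1, large = 10,
                                                        very_large = 25),
                             water_band_widths_nm = c(45, 30, 55, 30, 30),
                             water_amplitude = 1.2,
                             water_center_jitter_sd = 2,
                             moisture_range = c(0.45, 0.70),
                             baseline_offset_range = c(0.01, 0.06),
                             baseline_slope_range = c(-2e-5, 2e-5),
                             scatter_sd = 0.02,
                             noise_sd = 0.002,
                             heterogeneity_sd = 0.08,
                             subspots = c(static = 1L, moving = 5L, turntable = 10L),
                             instruments = default_instruments(),
                             seed = 1L) {
  if (n_samples < 2L || n_groups < 2L || replicates < 1L) {
    stopf("need n_samples >= 2, n_groups >= 2, replicates >= 1")
  }
  if (n_groups > n_samples) stopf("more groups than samples")
  R <- as.matrix(reference_correlation)
  if (!isTRUE(all.equal(R, t(R))) || min(eigen(R, symmetric = TRUE,
                                               only.values = TRUE)$values) < -1e-10) {
    stopf("reference_correlation must be symmetric positive semi-definite")
  }
  if (any(reference_stats$min >= reference_stats$max)) {
    stopf("infeasible truncation: min >= max")
  }
  for (b in band_library) {
    if (any(b$width_nm <= 0)) stopf("band widths must be > 0")
    if (any(b$center_nm < 1300 | b$center_nm > 2600)) {
      stopf("band centres must lie within 1300-2600 nm")
    }
  }
  stopifnot(scatter_sd >= 0, noise_sd >= 0, heterogeneity_sd >= 0,
            group_sd_fraction >= 0, group_sd_fraction < 1)
  structure(list(
    n_samples = as.integer(n_samples), n_groups = as.integer(n_groups),
    replicates = as.integer(replicates),
    reference_stats = reference_stats, reference_correlation = R,
    group_sd_fraction = group_sd_fraction,
    band_library = band_library, water_bands = water_bands,
    water_intensity_ratios = water_intensity_ratios,
    water_band_widths_nm = water_band_widths_nm,
    water_amplitude = water_amplitude,
    water_center_jitter_sd = water_center_jitter_sd,
    moisture_range = moisture_range,
    baseline_offset_range = baseline_offset_range,
    baseline_slope_range = baseline_slope_range,
    scatter_sd = scatter_sd, noise_sd = noise_sd,
    heterogeneity_sd = heterogeneity_sd,
    subspots = subspots, instruments = instruments,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic reference-chemistry table
#'
#' Constituent vectors are drawn from a Gaussian copula with truncated-normal
#' marginals: a latent standard multivariate normal with the configured
#' correlation matrix -- decomposed into a bunker-level random intercept
#' (variance `group_sd_fraction^2`) plus a within-bunker part -- is mapped
#' coordinate-wise through a truncated-normal quantile function whose latent
#' parameters are moment-matched so the truncated distribution reproduces the
#' configured mean and SD while respecting min/max as hard bounds (no
#' rejection bias propagating through the correlations). A per-sample moisture fraction (uniform in
#' `moisture_range`) is attached as attribute `"moisture"`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A `reference_table` with `n_samples` rows and attribute
#'   `moisture`.
#' @export
generate_reference <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  st <- cfg$reference_stats
  K <- nrow(st)
  # Cholesky of the latent correlation (ridge for semi-definite inputs)
  L <- tryCatch(chol(cfg$reference_correlation),
                error = function(e) chol(cfg$reference_correlation + diag(1e-8, K)))
  f <- cfg$group_sd_fraction
  with_seed(seed, {
    n <- cfg$n_samples; G <- cfg$n_groups
    # every bunker gets at least one sample; the rest are assigned at random
    grp <- c(seq_len(G), sample.int(G, n - G, replace = TRUE))
    grp <- sample(grp)
    Zg <- matrix(rnorm(G * K), G, K) %*% L
    Zw <- matrix(rnorm(n * K), n, K) %*% L
    Z <- f * Zg[grp, , drop = FALSE] + sqrt(1 - f^2) * Zw
    vals <- matrix(NA_real_, n, K)
    for (k in seq_len(K)) {
      if (st$sd[k] == 0) {
        vals[, k] <- st$mean[k]
      } else {
        # latent marginal moment-matched so the truncated distribution
        # reproduces the target mean and SD
        lat <- truncnorm_match(st$mean[k], st$sd[k], st$min[k], st$max[k])
        pa <- pnorm((st$min[k] - lat$mu) / lat$sd)
        pb <- pnorm((st$max[k] - lat$mu) / lat$sd)
        u <- pa + pnorm(Z[, k]) * (pb - pa)
        vals[, k] <- pmin(pmax(qnorm(u) * lat$sd + lat$mu,
                               st$min[k]), st$max[k])
      }
    }
    colnames(vals) <- st$constituent
    refs <- reference_table(data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      group = sprintf("bunker%03d", grp),
      vals, check.names = FALSE, stringsAsFactors = FALSE
    ), bounds = st[c("constituent", "min", "max")])
    attr(refs, "moisture") <- setNames(
      runif(n, cfg$moisture_range[1L], cfg$moisture_range[2L]),
      refs$sample_id
    )
    refs
  })
}

# Mean and SD of a normal distribution truncated to [lo, hi].
truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  c(m, sqrt(max(v, 0)))
}

# Latent (mu, sd) whose truncation to [lo, hi] has the target mean and SD.
truncnorm_match <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  res <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-13, maxit = 5000))
  list(mu = res$par[1], sd = exp(res$par[2]))
}

# Gaussian band basis of the chemically expressed constituents on a
# wavelength grid: one row per constituent, amplitude per %DM.
constituent_basis <- function(band_library, lambda) {
  t(vapply(band_library, function(b) {
    prof <- numeric(length(lambda))
    for (j in seq_len(nrow(b))) {
      prof <- prof + b$amplitude[j] *
        exp(-(lambda - b$center_nm[j])^2 / (2 * b$width_nm[j]^2))
    }
    prof
  }, numeric(length(lambda))))
}

# Water band profile per sample (rows), with per-sample centre shift.
water_profiles <- function(cfg, lambda, center_shift) {
  amps <- cfg$water_amplitude *
    cfg$water_intensity_ratios[cfg$water_bands$relative_intensity] /
    max(cfg$water_intensity_ratios)
  W <- matrix(0, length(center_shift), length(lambda))
  for (b in seq_len(nrow(cfg$water_bands))) {
    ctr <- cfg$water_bands$center_nm[b] + center_shift
    sdv <- cfg$water_band_widths_nm[b]
    D <- outer(ctr, lambda, function(c, l) l - c)
    W <- W + amps[b] * exp(-D^2 / (2 * sdv^2))
  }
  W
}

#' Generate synthetic reflectance spectra for one instrument and scan mode
#'
#' @param refs A `reference_table` from [generate_reference()] (with its
#'   `moisture` attribute).
#' @param cfg A [synthetic_config()].
#' @param instrument Name of an instrument in `cfg$instruments`.
#' @param scan_mode One of `names(cfg$subspots)`.
#' @param seed Seed for this stream; defaults to `cfg$seed`.
#' @param replicates Override for `cfg$replicates`.
#' @return A `spectra_set` in the reflectance domain on the instrument grid,
#'   with `cfg$replicates` rows per sample.
#' @export
generate_spectra <- function(refs, cfg, instrument, scan_mode,
                             seed = cfg$seed, replicates = cfg$replicates) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(refs, "reference_table"))
  inst <- cfg$instruments[[instrument]]
  if (is.null(inst)) stopf("instrument '%s' not defined in the config", instrument)
  if (!scan_mode %in% names(cfg$subspots)) stopf("unknown scan_mode '%s'", scan_mode)
  banded <- names(cfg$band_library)
  missing_bands <- setdiff(banded, names(refs))
  if (length(missing_bands)) {
    stopf("constituent(s) without reference values: %s",
          paste(missing_bands, collapse = ", "))
  }
  n <- nrow(refs)
  moisture <- attr(refs, "moisture")
  if (is.null(moisture)) moisture <- setNames(rep(0, n), refs$sample_id)
  moisture <- unname(moisture[refs$sample_id])
  n_sub <- as.integer(cfg$subspots[[scan_mode]])
  lam_fine <- seq(1300, 2600, by = 2)
  basis <- constituent_basis(cfg$band_library, lam_fine)
  C <- as.matrix(as.data.frame(refs)[banded])

  with_seed(seed, {
    shift <- if (cfg$water_center_jitter_sd > 0) {
      rnorm(n, 0, cfg$water_center_jitter_sd)
    } else {
      rep(0, n)
    }
    Wprof <- water_profiles(cfg, lam_fine, shift)
    rows <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      A_acc <- matrix(0, n, length(lam_fine))
      for (s in seq_len(n_sub)) {
        pert <- if (cfg$heterogeneity_sd > 0) {
          matrix(1 + rnorm(n * ncol(C), 0, cfg$heterogeneity_sd), n)
        } else {
          matrix(1, n, ncol(C))
        }
        m_pert <- moisture * (if (cfg$heterogeneity_sd > 0) {
          1 + rnorm(n, 0, cfg$heterogeneity_sd)
        } else 1)
        A_sub <- (C * pert) %*% basis + m_pert * Wprof
        scatter <- if (cfg$scatter_sd > 0) 1 + rnorm(n, 0, cfg$scatter_sd) else rep(1, n)
        offs <- runif(n, cfg$baseline_offset_range[1L], cfg$baseline_offset_range[2L])
        slope <- runif(n, cfg$baseline_slope_range[1L], cfg$baseline_slope_range[2L])
        A_sub <- A_sub * scatter + offs + outer(slope, lam_fine - lam_fine[1L])
        A_acc <- A_acc + A_sub
      }
      A_rep <- A_acc / n_sub
      if (inst$fwhm_nm > 0) A_rep <- convolve_lineshape(A_rep, lam_fine, inst$fwhm_nm)
      A_grid <- t(apply(A_rep, 1L, function(a) approx(lam_fine, a, xout = inst$grid)$y))
      if (cfg$noise_sd > 0) {
        A_grid <- A_grid + matrix(rnorm(length(A_grid), 0, cfg$noise_sd), nrow(A_grid))
      }
      rows[[r]] <- pmax(A_grid, 1e-8)
    }
    vals <- 10^(-do.call(rbind, rows))
    meta <- data.frame(
      sample_id = rep(refs$sample_id, times = replicates),
      replicate = rep(seq_len(replicates), each = n),
      instrument = instrument, scan_mode = scan_mode,
      group = rep(refs$group, times = replicates),
      stringsAsFactors = FALSE
    )
    spectra_set(inst$grid, vals, meta, "reflectance",
                provenance = sprintf("synthetic: %s/%s seed=%s", instrument,
                                     scan_mode, format(seed)))
  })
}

# Gaussian instrument line-shape: row-wise convolution with a truncated,
# renormalized kernel (FWHM in nm).
convolve_lineshape <- function(A, lambda, fwhm_nm) {
  sdv <- fwhm_nm / (2 * sqrt(2 * log(2)))
  D <- outer(lambda, lambda, `-`)
  K <- exp(-D^2 / (2 * sdv^2))
  K[abs(D) > 4 * sdv] <- 0
  K <- K / rowSums(K)
  A %*% t(K)
}

#' Generate a full multi-stream synthetic campaign
#'
#' One reference table plus reflectance spectra for each configured
#' (instrument, scan mode) stream over the same samples. Per-stream seeds are
#' derived deterministically from the master seed, so two runs with the same
#' config are identical.
#'
#' @param cfg A [synthetic_config()].
#' @param streams Data frame with columns `instrument`, `scan_mode`; the
#'   default reproduces the emulated study design (fixed-grid instruments in
#'   static/moving modes, the wide-range instrument in all three).
#' @return List with `reference` (a `reference_table`), `spectra` (named list
#'   of `spectra_set`, names `instrument.scan_mode`) and `config`.
#' @export
make_campaign <- function(cfg = synthetic_config(),
                          streams = data.frame(
                            instrument = c("agrocares", "agrocares", "neospectra",
                                           "neospectra", "neospectra", "trinamix"),
                            scan_mode = c("static", "moving", "static", "moving",
                                          "turntable", "static"),
                            stringsAsFactors = FALSE
                          )) {
  stopifnot(inherits(cfg, "synthetic_config"))
  refs <- generate_reference(cfg, seed = derive_seed(cfg$seed, 0L))
  spectra <- vector("list", nrow(streams))
  names(spectra) <- paste(streams$instrument, streams$scan_mode, sep = ".")
  for (i in seq_len(nrow(streams))) {
    spectra[[i]] <- generate_spectra(refs, cfg, streams$instrument[i],
                                     streams$scan_mode[i],
                                     seed = derive_seed(cfg$seed, i))
  }
  list(reference = refs, spectra = spectra, config = cfg)
}
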