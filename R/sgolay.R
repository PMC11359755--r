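# Savitzky-Golay local-polynomial derivative filtering.
#
# Implemented as general weighted least squares on an arbitrary evaluation
# index within the window, which (a) supports even window lengths -- the
# window of four points used throughout this pipeline -- and (b) supplies the
# boundary rule: edge points are differentiated by refitting the polynomial
# to the nearest full window instead of padding, so no reflection artefacts
# appear at the range limits.

#' Savitzky-Golay filter parameters
#'
#' @param window Number of points in the fitting window (>= 2). Even windows
#'   are supported; the evaluation point is then the later of the two central
#'   points (`floor(window/2)`, 0-based). Set `odd_window = TRUE` to map an
#'   even `window` to `window + 1`, the convention of implementations that
#'   require odd windows.
#' @param polyorder Degree of the local polynomial, `< window`.
#' @param deriv Derivative order, `<= polyorder`. Output is scaled per nm
#'   (divided by `step^deriv`) so derivative spectra are comparable across
#'   instruments with different native steps.
#' @param odd_window If `TRUE`, an even `window` is replaced by `window + 1`.
#' @return An object of class `sg_params`.
#' @export
sg_params <- function(window = 4L, polyorder = 3L, deriv = 1L, odd_window = FALSE) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (odd_window && window %% 2L == 0L) window <- window + 1L
  if (window < 2L) stopf("window must be >= 2")
  if (polyorder < 0L || polyorder >= window) stopf("need 0 <= polyorder < window")
  if (deriv < 0L || deriv > polyorder) stopf("need 0 <= deriv <= polyorder")
  structure(list(window = window, polyorder = polyorder, deriv = deriv),
            class = "sg_params")
}

# Least-squares SG weights for a window of `window` points with unit spacing,
# evaluating the deriv-th derivative of the fitted degree-`polyorder`
# polynomial at (1-based) position `eval_index` inside the window.
sg_weights_at <- function(window, polyorder, deriv, eval_index) {
  offsets <- seq_len(window) - eval_index
  G <- outer(offsets, 0:polyorder, `^`)
  # row (deriv+1) of the pseudo-inverse gives the polynomial coefficient
  # beta_deriv; the derivative at offset 0 is deriv! * beta_deriv.
  pinv <- solve(crossprod(G), t(G))
  factorial(deriv) * pinv[deriv + 1L, ]
}

#' Savitzky-Golay convolution weights
#'
#' Returns the weights `w` such that `sum(w * f)` over a window of
#' equally-spaced samples equals the `deriv`-th derivative (per nm) of the
#' least-squares polynomial fit, evaluated at the central index
#' `floor(window/2)` (0-based). For `window = 4, polyorder = 3` the fit
#' interpolates the four points exactly.
#'
#' @param p An [sg_params()] object.
#' @param step_nm Grid spacing in nm (> 0).
#' @return Numeric weight vector of length `p$window`.
#' @export
sg_coefficients <- function(p, step_nm = 1) {
  stopifnot(inherits(p, "sg_params"))
  if (step_nm <= 0) stopf("step_nm must be > 0")
  centre <- p$window %/% 2L + 1L
  sg_weights_at(p$window, p$polyorder, p$deriv, centre) / step_nm^p$deriv
}

#' Apply a Savitzky-Golay derivative filter to spectra
#'
#' Interior points are computed by convolution with [sg_coefficients()];
#' points too close to either end are computed by refitting the polynomial to
#' the nearest full window and differentiating it at the actual wavelength
#' (no padding). Output length equals input length.
#'
#' @param x A `spectra_set` in the absorbance domain on a uniform grid
#'   (resample first if the native grid is irregular).
#' @param p An [sg_params()] object.
#' @return A `spectra_set` in the derivative domain (per-nm units) when
#'   `deriv > 0`, absorbance when `deriv = 0` (smoothing only).
#' @export
apply_sg <- function(x, p) {
  stopifnot(inherits(x, "spectra_set"), inherits(p, "sg_params"))
  if (x$domain != "absorbance") {
    stopf("apply_sg() expects absorbance input, got %s", x$domain)
  }
  steps <- diff(x$wavelengths)
  if (max(steps) - min(steps) > GRID_TOL_NM) {
    stopf("non-uniform wavelength grid; call resample_to_grid() first")
  }
  M <- sg_filter_matrix(length(x$wavelengths), p, steps[1L])
  x$values <- x$values %*% t(M)
  if (p$deriv > 0L) x$domain <- "derivative"
  add_provenance(x, sprintf("apply_sg: window=%d polyorder=%d deriv=%d",
                            p$window, p$polyorder, p$deriv))
}

# Dense p_out x p_in filter matrix combining interior convolution with
# refit-at-edges rows.
sg_filter_matrix <- function(np, p, step) {
  w <- p$window
  if (np < w) stopf("spectrum has %d points, shorter than the window (%d)", np, w)
  centre <- w %/% 2L + 1L
  M <- matrix(0, np, np)
  scale <- step^p$deriv
  interior <- seq.int(centre, np - (w - centre))
  wc <- sg_weights_at(w, p$polyorder, p$deriv, centre) / scale
  for (i in interior) M[i, (i - centre + 1L):(i - centre + w)] <- wc
  for (i in seq_len(np)[-interior]) {
    if (i < centre) {            # left edge: fit to points 1..w
      wi <- sg_weights_at(w, p$polyorder, p$deriv, i) / scale
      M[i, 1:w] <- wi
    } else {                     # right edge: fit to the last w points
      wi <- sg_weights_at(w, p$polyorder, p$deriv, i - (np - w)) / scale
      M[i, (np - w + 1L):np] <- wi
    }
  }
  M
}
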