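#' Standard normal variate transform
#'
#' Row-wise z-scoring: each spectrum is centred to mean 0 and scaled to unit
#' sample standard deviation. Removes per-sample additive and multiplicative
#' offsets without a reference spectrum.
#'
#' @param x A [spectra_set] or numeric matrix (rows = spectra).
#' @return Object of the same type with transformed rows.
#' @export
#' @examples
#' snv(matrix(1:6, 2, byrow = TRUE))
snv <- function(x) {
  m <- .as_refl(x)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad)) {
    ids <- if (inherits(x, "spectra_set")) x$sample_ids[bad] else as.character(bad)
    stop("SNV undefined for constant spectra: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  .rewrap(x, (m - mu) / sdv)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on a reference spectrum `r` by ordinary
#' least squares, `x ~ a + b r`, and corrected to `(x - a)/b`. Affine
#' (additive + multiplicative) scatter relative to the reference is removed
#' exactly. The reference defaults to the mean spectrum of `x`; to avoid
#' test-set leakage, compute the reference on the training partition with
#' [msc_reference] and pass it here for both partitions.
#'
#' @param x A [spectra_set] or numeric matrix (rows = spectra).
#' @param reference Optional reference spectrum (length `D`). Default: the
#'   column-wise mean of `x`.
#' @param b_tol Samples whose fitted slope `|b|` falls below this tolerance
#'   are an error (the correction would divide by ~0).
#' @return Object of the same type, with the reference attached as
#'   attribute `"reference"`.
#' @export
msc <- function(x, reference = NULL, b_tol = 1e-12) {
  m <- .as_refl(x)
  if (is.null(reference)) reference <- colMeans(m)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(m)) {
    stop("reference length must equal the number of bands", call. = FALSE)
  }
  vr <- stats::var(reference)
  if (!is.finite(vr) || vr == 0) {
    stop("MSC reference has zero variance", call. = FALSE)
  }
  rc <- reference - mean(reference)
  # per-row OLS: b = cov(r, x)/var(r), a = mean(x) - b*mean(r)
  b <- as.numeric(m %*% rc) / sum(rc^2)
  a <- rowMeans(m) - b * mean(reference)
  bad <- which(abs(b) < b_tol | !is.finite(b))
  if (length(bad)) {
    ids <- if (inherits(x, "spectra_set")) x$sample_ids[bad] else as.character(bad)
    stop("MSC slope ~0 for sample(s): ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  out <- .rewrap(x, (m - a) / b)
  attr(out, "reference") <- reference
  out
}

#' @rdname msc
#' @export
msc_reference <- function(x) colMeans(.as_refl(x))

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing along the wavelength axis.
#' Interior points use the standard central convolution coefficients; the
#' first and last half-windows are handled by fitting the polynomial to the
#' terminal window and evaluating it there (no shrinkage of the spectrum).
#' The filter is linear and reproduces polynomials up to degree `polyorder`
#' exactly.
#'
#' @param x A [spectra_set] or numeric matrix (rows = spectra).
#' @param window Odd integer window length (default 11).
#' @param polyorder Polynomial degree, `< window` (default 3).
#' @return Object of the same type with smoothed rows.
#' @export
sg_smooth <- function(x, window = 11L, polyorder = 3L) {
  m <- .as_refl(x)
  S <- sg_matrix(ncol(m), window, polyorder)
  .rewrap(x, m %*% t(S))
}

#' Savitzky-Golay filter coefficients
#'
#' Central smoothing coefficients for an odd `window` and degree
#' `polyorder`: the row of the least-squares projection matrix that
#' evaluates the local fit at the window centre. `sg_matrix` builds the full
#' `D x D` linear operator applied by [sg_smooth], including the
#' fit-and-evaluate edge treatment.
#'
#' @param window Odd integer window length.
#' @param polyorder Polynomial degree, must be `< window`.
#' @return `sg_coefficients`: numeric vector of length `window`.
#' @export
#' @examples
#' sg_coefficients(5, 2) # (-3, 12, 17, 12, -3)/35
sg_coefficients <- function(window, polyorder) {
  .sg_check(window, polyorder)
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:polyorder, `^`)
  P <- A %*% solve(crossprod(A), t(A))
  P[h + 1L, ]
}

#' @rdname sg_coefficients
#' @param d Spectrum length (number of bands); must be `>= window`.
#' @export
sg_matrix <- function(d, window, polyorder) {
  .sg_check(window, polyorder)
  if (window > d) stop("window exceeds the number of bands", call. = FALSE)
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:polyorder, `^`)
  P <- A %*% solve(crossprod(A), t(A))  # window x window projection
  S <- matrix(0, d, d)
  for (i in seq_len(d)) {
    if (i <= h) {                       # leading edge: fit first window
      S[i, 1:window] <- P[i, ]
    } else if (i > d - h) {             # trailing edge: fit last window
      S[i, (d - window + 1L):d] <- P[window - (d - i), ]
    } else {
      S[i, (i - h):(i + h)] <- P[h + 1L, ]
    }
  }
  S
}

.sg_check <- function(window, polyorder) {
  if (window %% 2L != 1L || window < 3L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (polyorder < 0L || polyorder >= window) {
    stop("polyorder must satisfy 0 <= polyorder < window", call. = FALSE)
  }
  invisible(TRUE)
}

#' Wavelength regions covering the axis
#'
#' Splits the span of a wavelength axis into `n` contiguous equal-width
#' intervals, the default region layout for [region_proportions].
#'
#' @param wavelengths Strictly increasing numeric vector (nm).
#' @param n Number of regions (default 6).
#' @return Data frame with columns `low`, `high` (nm).
#' @export
default_regions <- function(wavelengths, n = 6L) {
  br <- seq(min(wavelengths), max(wavelengths), length.out = n + 1L)
  data.frame(low = br[-length(br)], high = br[-1])
}

#' Distribution of selected bands over wavelength regions
#'
#' For a selected band subset, the fraction of selected bands whose
#' wavelength falls into each region. Regions are half-open `[low, high)`
#' except the last, which includes its upper edge; together they must cover
#' the axis without overlap.
#'
#' @param selected Integer indices (1-based) of selected bands.
#' @param wavelengths Strictly increasing wavelength axis (nm).
#' @param regions Data frame with columns `low`, `high`; default
#'   [default_regions]`(wavelengths)`.
#' @return An object of class `region_table`: data frame with `low`, `high`,
#'   `n_selected`, `proportion` (proportions sum to 1).
#' @export
region_proportions <- function(selected, wavelengths, regions = NULL) {
  selected <- as.integer(selected)
  if (length(selected) == 0L) {
    stop("empty selection: region proportions undefined", call. = FALSE)
  }
  if (any(selected < 1L | selected > length(wavelengths))) {
    stop("selected indices out of range", call. = FALSE)
  }
  if (is.null(regions)) regions <- default_regions(wavelengths)
  regions <- regions[order(regions$low), , drop = FALSE]
  if (any(regions$high[-nrow(regions)] > regions$low[-1] + 1e-9)) {
    stop("regions overlap", call. = FALSE)
  }
  if (min(wavelengths) < regions$low[1] - 1e-9 ||
      max(wavelengths) > regions$high[nrow(regions)] + 1e-9) {
    stop("regions do not cover the wavelength axis", call. = FALSE)
  }
  wl <- wavelengths[selected]
  counts <- integer(nrow(regions))
  for (k in seq_len(nrow(regions))) {
    inside <- wl >= regions$low[k] &
      (wl < regions$high[k] | (k == nrow(regions) & wl <= regions$high[k]))
    counts[k] <- sum(inside)
  }
  out <- data.frame(low = regions$low, high = regions$high,
                    n_selected = counts,
                    proportion = counts / length(selected))
  class(out) <- c("region_table", "data.frame")
  out
}
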