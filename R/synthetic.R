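#' Synthetic seed-spectra specification
#'
#' Describes the generative model for [generate_seed_spectra]: per-class
#' smooth reflectance templates with planted discriminative bands,
#' per-sample affine scatter (what MSC/SNV correct) and band-wise Gaussian
#' noise (what Savitzky-Golay smooths).
#'
#' @param n_per_class Samples per class (default 100).
#' @param classes Class labels (default `control`, `water_bath`,
#'   `microwave` — an untreated group and two artificial-aging analogues).
#' @param d Number of bands (default 360; scale down for speed).
#' @param wl_range Wavelength range in nm (default `c(395.24, 1008.20)`).
#' @param n_informative Number of planted discriminative bands (default 8).
#' @param effect_size Reflectance offset magnitude at informative bands
#'   (default 0.05). Aged classes are shifted by `+/- effect_size` relative
#'   to the first (control) class, with alternating sign across bands.
#' @param scatter Apply per-sample affine scatter: multiplicative
#'   `b ~ U(0.8, 1.2)` and additive `a ~ U(-0.05, 0.05)` (default `TRUE`).
#' @param noise_sd Band-wise Gaussian noise standard deviation
#'   (default 0.01).
#' @param seed RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 100L,
                           classes = c("control", "water_bath", "microwave"),
                           d = 360L,
                           wl_range = c(395.24, 1008.20),
                           n_informative = 8L,
                           effect_size = 0.05,
                           scatter = TRUE,
                           noise_sd = 0.01,
                           seed = 1L) {
  d <- as.integer(d)
  n_informative <- as.integer(n_informative)
  if (d < 4L) stop("d must be >= 4", call. = FALSE)
  if (n_informative < 1L || n_informative > d) {
    stop("n_informative must lie in [1, d]", call. = FALSE)
  }
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class), classes = classes,
                 d = d, wl_range = as.numeric(wl_range),
                 n_informative = n_informative, effect_size = effect_size,
                 scatter = isTRUE(scatter), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# smooth seed-like reflectance template: low in the visible, rising over
# 500-700 nm, high and flat in the NIR with a small water-related dip ~750 nm
.base_curve <- function(wl) {
  0.12 +
    0.35 / (1 + exp(-(wl - 600) / 45)) +
    0.05 * exp(-((wl - 930) / 90)^2) -
    0.04 * exp(-((wl - 760) / 18)^2)
}

#' Generate labeled synthetic seed spectra with planted bands
#'
#' Reflectance model per sample `i` of class `c`:
#' `b_i * (base(wl) + effect_c) + a_i + N(0, noise_sd^2)` per band, where
#' `effect_c` is nonzero only at the planted informative bands. Classes are
#' balanced; everything is deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec].
#' @return List with `spectra` (a [spectra_set]) and `truth` (class
#'   `synthetic_truth`): informative band indices, the class-by-band effect
#'   matrix, class mean curves, a recoverability flag and the generating
#'   spec.
#' @export
generate_seed_spectra <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_local_seed(spec$seed, function() {
    d <- spec$d
    wl <- seq(spec$wl_range[1], spec$wl_range[2], length.out = d)
    base <- .base_curve(wl)
    n_cls <- length(spec$classes)
    info <- sort(sample.int(d, spec$n_informative))

    # class 1 = reference; the others get +/- effect_size with alternating
    # sign across bands so no single global offset separates the classes
    effects <- matrix(0, n_cls, d)
    for (c in seq_len(n_cls)[-1]) {
      sgn <- rep_len(c(1, -1), spec$n_informative) * (-1)^c
      effects[c, info] <- sgn * spec$effect_size
    }

    recoverable <- spec$effect_size >= 2 * spec$noise_sd
    if (!recoverable) {
      warning("planted effect size below 2 * noise_sd: ",
              "bands may not be recoverable", call. = FALSE)
    }

    n <- spec$n_per_class * n_cls
    labels <- factor(rep(spec$classes, each = spec$n_per_class),
                     levels = spec$classes)
    R <- matrix(0, n, d)
    for (i in seq_len(n)) {
      cls <- as.integer(labels[i])
      b <- if (spec$scatter) stats::runif(1, 0.8, 1.2) else 1
      a <- if (spec$scatter) stats::runif(1, -0.05, 0.05) else 0
      R[i, ] <- b * (base + effects[cls, ]) + a +
        stats::rnorm(d, 0, spec$noise_sd)
    }
    truth <- structure(
      list(informative_bands = info,
           effects = effects,
           class_means = t(vapply(seq_len(n_cls),
                                  function(c) base + effects[c, ],
                                  numeric(d))),
           recoverable = recoverable,
           spec = spec),
      class = "synthetic_truth")
    list(spectra = spectra_set(wl, R, labels), truth = truth)
  })
}

#' Generate a tabular feature-selection benchmark
#'
#' Generic labeled matrix with known ground truth: `n_informative` columns
#' drawn from class-shifted Gaussians (class `c` mean `(c - 1) * class_sep`
#' with alternating sign across columns), `n_redundant` columns that are
#' noisy linear copies of informative ones, and pure-noise columns for the
#' remainder.
#'
#' @param n Number of samples.
#' @param d Number of columns.
#' @param n_informative Number of class-informative columns.
#' @param n_redundant Number of noisy copies of informative columns.
#' @param n_classes Number of balanced classes (default 2).
#' @param class_sep Gaussian mean shift between adjacent classes
#'   (default 2).
#' @param seed RNG seed.
#' @return List with `X` (matrix), `y` (factor) and `truth` (informative
#'   and redundant column indices plus the parameters).
#' @export
generate_fs_benchmark <- function(n = 200L, d = 10L, n_informative = 3L,
                                  n_redundant = 0L, n_classes = 2L,
                                  class_sep = 2, seed = 1L) {
  n_informative <- as.integer(n_informative)
  n_redundant <- as.integer(n_redundant)
  d <- as.integer(d)
  if (n_informative < 1L || n_informative + n_redundant > d) {
    stop("need 1 <= n_informative and n_informative + n_redundant <= d",
         call. = FALSE)
  }
  .with_local_seed(as.integer(seed), function() {
    y <- factor(rep_len(paste0("c", seq_len(n_classes)), n))
    yi <- as.integer(y)
    X <- matrix(stats::rnorm(n * d), n, d)
    info <- seq_len(n_informative)
    for (j in info) {
      sgn <- (-1)^j
      X[, j] <- X[, j] + sgn * (yi - 1) * class_sep
    }
    red <- if (n_redundant > 0L) n_informative + seq_len(n_redundant)
           else integer(0)
    for (j in red) {
      src <- info[1L + (j - n_informative - 1L) %% n_informative]
      X[, j] <- X[, src] + stats::rnorm(n, 0, 0.3)
    }
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = y,
         truth = list(informative = info, redundant = red,
                      class_sep = class_sep, n_classes = n_classes,
                      seed = as.integer(seed)))
  })
}

#' Exhaustive subset-fitness oracle
#'
#' Enumerates all `2^d - 1` nonempty column subsets and evaluates the same
#' wrapper fitness the optimizers use (built via [make_knn_fitness] from
#' `cfg`, so the internal split is identical for the same `cfg$seed`).
#' Intended as an independent verification oracle for small `d`.
#'
#' @param X Numeric `n x d` matrix, `d <= d_max`.
#' @param y Labels.
#' @param cfg A [fitness_config].
#' @param d_max Refusal threshold (default 12).
#' @return List with `best_mask` (logical), `best_fitness`, `best_error`,
#'   and `landscape`: a data frame with one row per subset (`mask` as a
#'   bitstring, `n_selected`, `error`, `fitness`).
#' @export
exhaustive_oracle <- function(X, y, cfg = fitness_config(), d_max = 12L) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (d > d_max) {
    stop("refusing exhaustive enumeration for d = ", d, " > d_max = ", d_max,
         call. = FALSE)
  }
  fn <- make_knn_fitness(X, y, cfg)
  n_masks <- 2L^d - 1L
  fitness <- numeric(n_masks)
  error <- numeric(n_masks)
  n_sel <- integer(n_masks)
  bits <- character(n_masks)
  for (m in seq_len(n_masks)) {
    mask <- as.logical(bitwAnd(m, 2L^(seq_len(d) - 1L)) > 0L)
    f <- fn(mask)
    fitness[m] <- f
    error[m] <- attr(f, "error")
    n_sel[m] <- sum(mask)
    bits[m] <- paste(as.integer(mask), collapse = "")
  }
  best <- which.min(fitness)
  best_mask <- as.logical(bitwAnd(best, 2L^(seq_len(d) - 1L)) > 0L)
  list(best_mask = best_mask,
       best_fitness = fitness[best],
       best_error = error[best],
       landscape = data.frame(mask = bits, n_selected = n_sel,
                              error = error, fitness = fitness))
}

#' Re-weight an enumerated fitness landscape
#'
#' Given the landscape from [exhaustive_oracle] (whose per-subset `error`
#' does not depend on `alpha`), returns the optimal subset under a new
#' error weight. Ties are broken toward fewer features, then by order of
#' enumeration, making the size of the optimum well defined.
#'
#' @param landscape Data frame from [exhaustive_oracle].
#' @param alpha Error weight in `[0, 1]`.
#' @param n_total Total number of features.
#' @return List with `best_index`, `best_fitness`, `best_size`.
#' @export
oracle_reweight <- function(landscape, alpha, n_total) {
  f <- subset_fitness(landscape$error, landscape$n_selected, n_total, alpha)
  o <- order(f, landscape$n_selected)
  list(best_index = o[1L], best_fitness = f[o[1L]],
       best_size = landscape$n_selected[o[1L]])
}
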