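#' Labeled spectra set
#'
#' Container for a labeled reflectance table: a strictly increasing
#' wavelength axis (nm), an `n x D` reflectance matrix, one class label per
#' sample and optional sample identifiers.
#'
#' @param wavelengths Numeric vector of band centres in nm, length `D`.
#'   Reordered (together with the reflectance columns) to be strictly
#'   increasing; duplicated wavelengths are an error.
#' @param reflectance Numeric `n x D` matrix of reflectance values.
#' @param labels Vector (coerced to factor) of class labels, length `n`.
#' @param sample_ids Optional character vector of sample identifiers,
#'   length `n`; defaults to `"s1" ... "sn"`.
#'
#' @return An object of class `spectra_set` with elements `wavelengths`,
#'   `reflectance`, `labels`, `sample_ids`.
#' @export
#' @examples
#' s <- spectra_set(c(400, 500, 600), matrix(runif(6), 2), c("a", "b"))
#' n_bands(s)
spectra_set <- function(wavelengths, reflectance, labels, sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (length(wavelengths) != ncol(reflectance)) {
    stop("length(wavelengths) must equal ncol(reflectance)", call. = FALSE)
  }
  if (anyDuplicated(wavelengths)) {
    stop("duplicate wavelengths: ",
         paste(unique(wavelengths[duplicated(wavelengths)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(reflectance) != length(labels)) {
    stop("nrow(reflectance) must equal length(labels)", call. = FALSE)
  }
  if (anyNA(wavelengths)) stop("wavelengths contain NA", call. = FALSE)
  if (anyNA(reflectance)) {
    bad <- which(is.na(reflectance), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-numeric reflectance at row %d, band %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]
  reflectance <- reflectance[, ord, drop = FALSE]
  colnames(reflectance) <- format(wavelengths, trim = TRUE)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(reflectance)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance)) {
    stop("length(sample_ids) must equal the number of samples", call. = FALSE)
  }
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance,
         labels = factor(labels), sample_ids = sample_ids),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d bands (%.2f-%.2f nm), %d classes\n",
              n_samples(x), n_bands(x), min(x$wavelengths), max(x$wavelengths),
              nlevels(x$labels)))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @rdname spectra_set
#' @param x A `spectra_set`.
#' @export
n_bands <- function(x) length(x$wavelengths)

#' @rdname spectra_set
#' @export
n_samples <- function(x) nrow(x$reflectance)

#' Read a labeled spectra table from delimited text
#'
#' The file must have a header row whose entries are wavelengths in nm,
#' except for the label column and (optionally) an id column. Columns are
#' reordered so the wavelength axis is strictly increasing.
#'
#' @param path Path to a delimited text file.
#' @param label_column Name of the label column (default `"label"`).
#' @param id_column Optional name of a sample-id column. When `NULL` a
#'   column literally named `"id"` (as written by [write_spectra]) is used
#'   if present.
#' @param sep Field separator (default comma).
#' @return A [spectra_set].
#' @export
read_spectra <- function(path, label_column = "label", id_column = NULL,
                         sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path, call. = FALSE)
  }
  labels <- df[[label_column]]
  ids <- NULL
  drop <- label_column
  if (is.null(id_column) && "id" %in% names(df)) id_column <- "id"
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop("id column '", id_column, "' not found in ", path, call. = FALSE)
    }
    ids <- df[[id_column]]
    drop <- c(drop, id_column)
  }
  band_cols <- setdiff(names(df), drop)
  wl <- suppressWarnings(as.numeric(band_cols))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header(s): ",
         paste(band_cols[is.na(wl)], collapse = ", "), call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow(df), length(band_cols))
  for (j in seq_along(band_cols)) {
    v <- suppressWarnings(as.numeric(df[[band_cols[j]]]))
    bad <- which(is.na(v) | df[[band_cols[j]]] == "")
    if (length(bad)) {
      stop(sprintf("non-numeric or missing reflectance at row %d, column '%s'",
                   bad[1], band_cols[j]), call. = FALSE)
    }
    mat[, j] <- v
  }
  spectra_set(wl, mat, labels, ids)
}

#' Write a spectra set as delimited text
#'
#' Inverse of [read_spectra]: one header row of wavelengths plus a `label`
#' and an `id` column.
#'
#' @param x A [spectra_set].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "spectra_set"))
  df <- as.data.frame(x$reflectance, check.names = FALSE)
  names(df) <- format(x$wavelengths, trim = TRUE)
  df$label <- as.character(x$labels)
  df$id <- x$sample_ids
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: extract the reflectance matrix from spectra_set or matrix input.
.as_refl <- function(x) {
  if (inherits(x, "spectra_set")) x$reflectance else as.matrix(x)
}

# Internal: put a transformed matrix back into the same container shape.
.rewrap <- function(x, mat) {
  if (inherits(x, "spectra_set")) {
    out <- x
    out$reflectance <- mat
    colnames(out$reflectance) <- colnames(x$reflectance)
    out
  } else {
    mat
  }
}
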