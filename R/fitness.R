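#' Wrapper fitness configuration
#'
#' Settings for the KNN wrapper objective: the error/size trade-off weight
#' `alpha` (size weight is `1 - alpha`), the number of neighbours, and the
#' internal evaluation scheme used to estimate the classification error of a
#' candidate subset.
#'
#' @param alpha Weight on the classifier error, in `[0, 1]` (default 0.99 —
#'   the dominant convention in wrapper feature selection; the size term
#'   gets `1 - alpha`).
#' @param knn_k Number of neighbours (default 3).
#' @param scheme `"holdout"` (default) or `"kfold"`.
#' @param holdout_fraction Test fraction for the holdout scheme
#'   (default 0.3, stratified).
#' @param folds Number of folds for the k-fold scheme (default 5,
#'   stratified).
#' @param seed Seed fixing the internal split; one split is reused across
#'   all fitness calls of a run so subsets are compared on identical data.
#' @return A list of class `fitness_config`.
#' @export
fitness_config <- function(alpha = 0.99, knn_k = 3L,
                           scheme = c("holdout", "kfold"),
                           holdout_fraction = 0.3, folds = 5L, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L) stop("knn_k must be >= 1", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(alpha = alpha, knn_k = knn_k, scheme = match.arg(scheme),
                 holdout_fraction = holdout_fraction,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "fitness_config")
}

#' K-nearest-neighbour prediction
#'
#' Euclidean KNN with a deterministic tie-break: when the vote among the `k`
#' nearest neighbours is tied, the label of the single nearest neighbour is
#' used.
#'
#' @param X_train,y_train Training matrix and labels (factor).
#' @param X_test Matrix of query rows.
#' @param k Number of neighbours.
#' @return Factor of predicted labels (levels of `y_train`).
#' @export
knn_predict <- function(X_train, y_train, X_test, k = 3L) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  y_train <- factor(y_train)
  if (k > nrow(X_train)) stop("k exceeds the number of training rows",
                              call. = FALSE)
  d2 <- outer(rowSums(X_test^2), rep(1, nrow(X_train))) +
    outer(rep(1, nrow(X_test)), rowSums(X_train^2)) -
    2 * tcrossprod(X_test, X_train)
  yi <- as.integer(y_train)
  nlev <- nlevels(y_train)
  pred <- integer(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- tabulate(yi[nn], nbins = nlev)
    top <- which(votes == max(votes))
    pred[i] <- if (length(top) == 1L) top else yi[nn[1L]]
  }
  factor(levels(y_train)[pred], levels = levels(y_train))
}

# run fn with a private, seeded RNG stream; the caller's stream is untouched
.with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# stratified split: returns logical vector, TRUE = held-out/test row
.stratified_holdout <- function(y, fraction, seed) {
  .with_local_seed(seed, function() {
    test <- logical(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      n_test <- max(1L, round(fraction * length(idx)))
      if (n_test >= length(idx)) n_test <- length(idx) - 1L
      test[sample(idx, n_test)] <- TRUE
    }
    test
  })
}

# stratified fold assignment 1..k
.stratified_folds <- function(y, k, seed) {
  .with_local_seed(seed, function() {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' KNN error rate of a feature subset
#'
#' Misclassification rate of a KNN classifier restricted to the masked
#' columns, under the evaluation scheme in `cfg`. Features are z-scored with
#' training-partition statistics before distances are computed. The split is
#' fully determined by `cfg$seed`, so repeated calls are deterministic.
#'
#' @param X Numeric `n x D` matrix.
#' @param y Labels (coerced to factor).
#' @param mask Logical (or 0/1) vector of length `D` with at least one
#'   selected column.
#' @param cfg A [fitness_config].
#' @return Error rate in `[0, 1]`.
#' @export
knn_error <- function(X, y, mask, cfg = fitness_config()) {
  X <- as.matrix(X)
  y <- factor(y)
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty feature mask", call. = FALSE)
  if (nlevels(y) == 1L) return(0)
  fn <- make_knn_fitness(X, y, cfg)
  as.numeric(attr(fn(mask), "error"))
}

#' Combined error/size fitness
#'
#' The wrapper objective `alpha * error + (1 - alpha) * n_selected/n_total`
#' (lower is better). With `alpha = 1` it reduces to pure error
#' minimization.
#'
#' @param error Classifier error rate in `[0, 1]`.
#' @param n_selected Number of selected features (>= 1).
#' @param n_total Total number of features.
#' @param alpha Error weight in `[0, 1]`.
#' @return Fitness value in `[0, 1]`.
#' @export
subset_fitness <- function(error, n_selected, n_total, alpha = 0.99) {
  if (any(n_selected < 1)) stop("n_selected must be >= 1", call. = FALSE)
  if (any(error < 0 | error > 1)) stop("error must lie in [0, 1]",
                                       call. = FALSE)
  alpha * error + (1 - alpha) * n_selected / n_total
}

#' Build a KNN wrapper fitness function
#'
#' Precomputes the internal split and the z-scored design matrices once and
#' returns a closure `f(mask)` suitable for [run_optimizer], [binary_pso]
#' and [binary_sca]: it returns the combined fitness with the KNN error
#' attached as attribute `"error"`.
#'
#' @param X Numeric `n x D` matrix.
#' @param y Labels.
#' @param cfg A [fitness_config].
#' @return Function(mask) -> fitness (numeric scalar with attribute
#'   `"error"`).
#' @export
make_knn_fitness <- function(X, y, cfg = fitness_config()) {
  X <- as.matrix(X)
  y <- factor(y)
  n_total <- ncol(X)
  single_class <- nlevels(y) == 1L

  scale_pair <- function(tr, te) {
    mu <- colMeans(tr)
    sdv <- apply(tr, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    list(tr = sweep(sweep(tr, 2, mu), 2, sdv, "/"),
         te = sweep(sweep(te, 2, mu), 2, sdv, "/"))
  }

  if (cfg$scheme == "holdout") {
    test <- .stratified_holdout(y, cfg$holdout_fraction, cfg$seed)
    n_train_cls <- table(y[!test])
    small <- names(n_train_cls)[n_train_cls < cfg$knn_k]
    if (length(small) && !single_class) {
      stop("class(es) too small for k = ", cfg$knn_k,
           " under the holdout split: ", paste(small, collapse = ", "),
           call. = FALSE)
    }
    sp <- scale_pair(X[!test, , drop = FALSE], X[test, , drop = FALSE])
    splits <- list(list(Xtr = sp$tr, ytr = y[!test],
                        Xte = sp$te, yte = y[test]))
  } else {
    fold <- .stratified_folds(y, cfg$folds, cfg$seed)
    splits <- lapply(seq_len(cfg$folds), function(k) {
      tr <- fold != k
      n_train_cls <- table(y[tr])
      small <- names(n_train_cls)[n_train_cls < cfg$knn_k]
      if (length(small) && !single_class) {
        stop("class(es) too small for k = ", cfg$knn_k, " under fold ", k,
             ": ", paste(small, collapse = ", "), call. = FALSE)
      }
      sp <- scale_pair(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
      list(Xtr = sp$tr, ytr = y[tr], Xte = sp$te, yte = y[!tr])
    })
  }

  # cache: fitness is deterministic given the mask, so repeated masks
  # (frequent once the search concentrates) are looked up, not recomputed
  cache <- new.env(hash = TRUE, parent = emptyenv())

  function(mask) {
    mask <- as.logical(mask)
    if (length(mask) != n_total) stop("mask length mismatch", call. = FALSE)
    if (!any(mask)) stop("empty feature mask", call. = FALSE)
    key <- rawToChar(as.raw(mask + 48L))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    err <- if (single_class) 0 else {
      mean(vapply(splits, function(sp) {
        pred <- knn_predict(sp$Xtr[, mask, drop = FALSE], sp$ytr,
                            sp$Xte[, mask, drop = FALSE], cfg$knn_k)
        mean(pred != sp$yte)
      }, numeric(1)))
    }
    out <- subset_fitness(err, sum(mask), n_total, cfg$alpha)
    attr(out, "error") <- err
    cache[[key]] <- out
    out
  }
}
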