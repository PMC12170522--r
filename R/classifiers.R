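#' Evaluation protocol
#'
#' Train/test split and hyperparameter grids for the final-model evaluation
#' harness. Defaults follow the reference protocol: stratified 8:2 split,
#' ELM hidden-layer grid 30..100 step 10 with a sigmoid activation, random
#' forest with 300 trees and a depth grid 1..20 step 1, RBF-SVM with the
#' classic logarithmic (C, gamma) grid, all tuned by stratified 5-fold
#' cross-validated accuracy on the training partition.
#'
#' @param test_fraction Held-out test fraction (default 0.2).
#' @param elm_hidden_grid Hidden-unit counts for the ELM grid search.
#' @param rf_n_trees Number of trees in the random forest (default 300).
#' @param rf_depth_grid Maximum-depth grid for the forest.
#' @param svm_c_grid,svm_gamma_grid RBF-SVM cost and kernel-width grids.
#' @param cv_folds Cross-validation folds for the grid searches (default 5).
#' @param sg_window,sg_polyorder Savitzky-Golay settings used when the
#'   `"sg"` preprocessor is requested.
#' @return A list of class `eval_protocol`.
#' @export
eval_protocol <- function(test_fraction = 0.2,
                          elm_hidden_grid = seq(30L, 100L, 10L),
                          rf_n_trees = 300L,
                          rf_depth_grid = 1:20,
                          svm_c_grid = 2^seq(-5, 15, 2),
                          svm_gamma_grid = 2^seq(-15, 3, 2),
                          cv_folds = 5L,
                          sg_window = 11L,
                          sg_polyorder = 3L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(test_fraction = test_fraction,
                 elm_hidden_grid = as.integer(elm_hidden_grid),
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_depth_grid = as.integer(rf_depth_grid),
                 svm_c_grid = svm_c_grid, svm_gamma_grid = svm_gamma_grid,
                 cv_folds = as.integer(cv_folds),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "eval_protocol")
}

## ---- extreme learning machine -------------------------------------------

#' Extreme learning machine
#'
#' Single-hidden-layer network with random fixed input weights and biases
#' drawn from U(-1, 1), sigmoid activation, and output weights obtained by
#' the Moore-Penrose pseudoinverse of the hidden-layer output matrix
#' against the one-hot label matrix. Prediction takes the arg-max output.
#'
#' @param X Numeric `n x d` matrix (n >= 2).
#' @param y Labels (coerced to factor).
#' @param n_hidden Number of hidden units (>= 1).
#' @param seed Seed for the random input weights.
#' @return An object of class `elm_model`.
#' @export
elm_train <- function(X, y, n_hidden = 50L, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nrow(X) < 2L) stop("ELM needs at least 2 samples", call. = FALSE)
  if (n_hidden < 1L) stop("n_hidden must be >= 1", call. = FALSE)
  d <- ncol(X)
  wb <- .with_local_seed(as.integer(seed), function() {
    list(W = matrix(stats::runif(d * n_hidden, -1, 1), d, n_hidden),
         b = stats::runif(n_hidden, -1, 1))
  })
  H <- transfer_sigmoid(X %*% wb$W + matrix(wb$b, nrow(X), n_hidden,
                                            byrow = TRUE))
  Y <- stats::model.matrix(~ y - 1)
  beta <- MASS::ginv(H) %*% Y
  structure(list(W = wb$W, b = wb$b, beta = beta, classes = levels(y),
                 n_hidden = as.integer(n_hidden), seed = as.integer(seed)),
            class = "elm_model")
}

#' @export
predict.elm_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  H <- transfer_sigmoid(X %*% object$W +
                          matrix(object$b, nrow(X), object$n_hidden,
                                 byrow = TRUE))
  scores <- H %*% object$beta
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

## ---- random forest (bagged CART) ----------------------------------------

# Gini-based CART split search on a node. Returns NULL if no valid split.
.best_split <- function(X, yi, idx, feats, nlev) {
  n <- length(idx)
  best <- NULL
  best_imp <- Inf
  for (f in feats) {
    x <- X[idx, f]
    o <- order(x)
    xs <- x[o]
    ys <- yi[idx][o]
    if (xs[1] == xs[n]) next
    cum <- apply(outer(ys, seq_len(nlev), `==`), 2, cumsum)  # n x nlev
    tot <- cum[n, ]
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L]
    if (!any(valid)) next
    nl <- i
    nr <- n - i
    gl <- 1 - rowSums((cum[i, , drop = FALSE] / nl)^2)
    gr <- 1 - rowSums((sweep(-cum[i, , drop = FALSE], 2, tot, `+`) / nr)^2)
    imp <- (nl * gl + nr * gr) / n
    imp[!valid] <- Inf
    j <- which.min(imp)
    if (imp[j] < best_imp) {
      best_imp <- imp[j]
      best <- list(feature = f, threshold = (xs[j] + xs[j + 1L]) / 2,
                   impurity = imp[j])
    }
  }
  best
}

# fit one CART tree; nodes held in a growing list
.tree_fit <- function(X, yi, idx, max_depth, mtry, nlev) {
  nodes <- list()
  grow <- function(idx, depth) {
    counts <- tabulate(yi[idx], nbins = nlev)
    pred <- which.max(counts)
    leaf <- list(leaf = TRUE, pred = pred)
    if (depth >= max_depth || length(idx) < 2L || max(counts) == length(idx)) {
      nodes[[length(nodes) + 1L]] <<- leaf
      return(length(nodes))
    }
    feats <- sample.int(ncol(X), mtry)
    sp <- .best_split(X, yi, idx, feats, nlev)
    if (is.null(sp)) {
      nodes[[length(nodes) + 1L]] <<- leaf
      return(length(nodes))
    }
    go_left <- X[idx, sp$feature] <= sp$threshold
    me <- length(nodes) + 1L
    nodes[[me]] <<- list(leaf = FALSE, feature = sp$feature,
                         threshold = sp$threshold, left = NA, right = NA,
                         pred = pred)
    nodes[[me]]$left <<- grow(idx[go_left], depth + 1L)
    nodes[[me]]$right <<- grow(idx[!go_left], depth + 1L)
    me
  }
  root <- grow(idx, 0L)
  list(nodes = nodes, root = root)
}

.tree_predict <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  walk <- function(node_id, rows) {
    nd <- tree$nodes[[node_id]]
    if (nd$leaf) {
      out[rows] <<- nd$pred
      return(invisible())
    }
    go_left <- X[rows, nd$feature] <= nd$threshold
    if (any(go_left)) walk(nd$left, rows[go_left])
    if (any(!go_left)) walk(nd$right, rows[!go_left])
  }
  walk(tree$root, seq_len(n))
  out
}

#' Random forest classifier
#'
#' Bagging ensemble of Gini-grown CART trees: each tree is fit on a
#' bootstrap sample with `mtry` features considered per split, and the
#' forest predicts by majority vote (ties broken toward the first class
#' level). A self-contained implementation — no external tree package is
#' required.
#'
#' @param X Numeric `n x d` matrix.
#' @param y Labels (coerced to factor).
#' @param n_trees Number of trees (default 300).
#' @param max_depth Maximum tree depth (default 10).
#' @param mtry Features tried per split (default `floor(sqrt(d))`).
#' @param seed RNG seed.
#' @return An object of class `rf_model`.
#' @export
rf_train <- function(X, y, n_trees = 300L, max_depth = 10L, mtry = NULL,
                     seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  mtry <- min(as.integer(mtry), ncol(X))
  yi <- as.integer(y)
  nlev <- nlevels(y)
  trees <- .with_local_seed(as.integer(seed), function() {
    lapply(seq_len(n_trees), function(t) {
      boot <- sample.int(nrow(X), replace = TRUE)
      tr <- .tree_fit(X[boot, , drop = FALSE], yi[boot],
                      seq_along(boot), max_depth, mtry, nlev)
      tr
    })
  })
  structure(list(trees = trees, classes = levels(y), mtry = mtry,
                 max_depth = as.integer(max_depth),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  nlev <- length(object$classes)
  votes <- matrix(0L, nrow(X), nlev)
  for (tree in object$trees) {
    p <- .tree_predict(tree, X)
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1L
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

## ---- RBF support vector machine (QP dual) --------------------------------

.rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# soft-margin binary C-SVM dual solved with quadprog
.svm_binary <- function(K, yc, cost) {
  n <- length(yc)
  ridge <- 1e-8
  sol <- NULL
  for (attempt in 1:4) {
    Dmat <- (yc %o% yc) * K + diag(ridge, n)
    sol <- tryCatch(
      quadprog::solve.QP(Dmat, rep(1, n),
                         cbind(yc, diag(n), -diag(n)),
                         c(0, rep(0, n), rep(-cost, n)), meq = 1)$solution,
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stop("SVM QP failed to solve", call. = FALSE)
  alpha <- pmin(pmax(sol, 0), cost)
  f_no_b <- as.numeric(K %*% (alpha * yc))
  free <- alpha > 1e-6 & alpha < cost - 1e-6
  b <- if (any(free)) mean(yc[free] - f_no_b[free]) else {
    sv <- alpha > 1e-6
    if (any(sv)) mean(yc[sv] - f_no_b[sv]) else 0
  }
  list(coef = alpha * yc, b = b)
}

#' RBF support vector machine
#'
#' Soft-margin C-SVM with a radial basis kernel, trained by solving the
#' dual quadratic program directly (one-vs-rest for more than two classes;
#' prediction by maximum decision value). Features are z-scored with
#' training statistics before the kernel is computed.
#'
#' @param X Numeric `n x d` matrix.
#' @param y Labels (coerced to factor).
#' @param cost Penalty parameter C (default 1).
#' @param gamma RBF kernel width (default `1/d`).
#' @return An object of class `svm_model`.
#' @export
svm_train <- function(X, y, cost = 1, gamma = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("SVM needs at least 2 classes", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  K <- .rbf_kernel(Xs, Xs, gamma)
  machines <- lapply(levels(y), function(lv) {
    yc <- ifelse(y == lv, 1, -1)
    .svm_binary(K, yc, cost)
  })
  structure(list(machines = machines, classes = levels(y), X_sv = Xs,
                 mu = mu, sd = sdv, gamma = gamma, cost = cost),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
  K <- .rbf_kernel(Xs, object$X_sv, object$gamma)
  scores <- vapply(object$machines,
                   function(m) as.numeric(K %*% m$coef + m$b),
                   numeric(nrow(Xs)))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1L)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

## ---- metrics & grid search ----------------------------------------------

#' Classification metrics
#'
#' Accuracy plus macro-averaged precision, recall and F1. Per-class ratios
#' with a zero denominator are defined as 0 (not `NaN`), so a class the
#' predictor never emits contributes precision 0.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return List with `accuracy`, `precision`, `recall`, `f1` (macro), and
#'   `per_class` data frame.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  lev <- union(levels(factor(y_true)), levels(factor(y_pred)))
  y_true <- factor(y_true, levels = lev)
  y_pred <- factor(y_pred, levels = lev)
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  tp <- fp <- fn <- numeric(length(lev))
  for (k in seq_along(lev)) {
    tp[k] <- sum(y_pred == lev[k] & y_true == lev[k])
    fp[k] <- sum(y_pred == lev[k] & y_true != lev[k])
    fn[k] <- sum(y_pred != lev[k] & y_true == lev[k])
  }
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  list(accuracy = mean(y_true == y_pred),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       per_class = data.frame(class = lev, precision = prec,
                              recall = rec, f1 = f1))
}

# train one classifier of the given kind with explicit hyperparameters
.fit_classifier <- function(kind, X, y, pars, protocol, seed) {
  switch(kind,
    elm = elm_train(X, y, n_hidden = pars$n_hidden, seed = seed),
    rf = rf_train(X, y, n_trees = protocol$rf_n_trees,
                  max_depth = pars$max_depth, seed = seed),
    svm = svm_train(X, y, cost = pars$cost, gamma = pars$gamma),
    stop("unknown classifier kind: ", kind, call. = FALSE)
  )
}

#' Grid search over classifier hyperparameters
#'
#' Selects the grid point maximizing stratified `cv_folds`-fold
#' cross-validated accuracy on the supplied (training) data, then refits on
#' all of it. Grids come from the [eval_protocol]: hidden units for the
#' ELM, maximum depth for the random forest, and the (C, gamma) grid for
#' the RBF-SVM. Ties are broken toward the first grid point.
#'
#' @param kind One of `"elm"`, `"rf"`, `"svm"`.
#' @param X,y Training data.
#' @param protocol An [eval_protocol].
#' @param seed Seed for fold assignment and classifier randomness.
#' @return List with `model`, `best_params`, `cv_accuracy`.
#' @export
grid_search_classifier <- function(kind = c("elm", "rf", "svm"), X, y,
                                   protocol = eval_protocol(), seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- factor(y)
  if (any(table(y) < protocol$cv_folds)) {
    stop("each class needs at least cv_folds samples for the grid search",
         call. = FALSE)
  }
  grid <- switch(kind,
    elm = lapply(protocol$elm_hidden_grid, function(h) list(n_hidden = h)),
    rf = lapply(protocol$rf_depth_grid, function(m) list(max_depth = m)),
    svm = {
      g <- expand.grid(cost = protocol$svm_c_grid,
                       gamma = protocol$svm_gamma_grid)
      lapply(seq_len(nrow(g)),
             function(i) list(cost = g$cost[i], gamma = g$gamma[i]))
    })
  fold <- .stratified_folds(y, protocol$cv_folds, seed)
  cv_acc <- vapply(grid, function(pars) {
    mean(vapply(seq_len(protocol$cv_folds), function(k) {
      tr <- fold != k
      fit <- .fit_classifier(kind, X[tr, , drop = FALSE], y[tr], pars,
                             protocol, seed)
      mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cv_acc)
  model <- .fit_classifier(kind, X, y, grid[[best]], protocol, seed)
  list(model = model, best_params = grid[[best]], cv_accuracy = cv_acc[best])
}

## ---- experiment grid ------------------------------------------------------

#' Selector specification for the experiment grid
#'
#' @param algorithm One of `"eiao"`, `"iao"`, `"pso"`, `"sca"`.
#' @param ... Arguments passed to [optimizer_config] (everything but `dim`,
#'   which is filled in from the data).
#' @return A list of class `selector_spec`.
#' @export
selector_spec <- function(algorithm = c("eiao", "iao", "pso", "sca"), ...) {
  structure(list(algorithm = match.arg(algorithm), args = list(...)),
            class = "selector_spec")
}

# fit a preprocessor on the training partition; returns transform function
.fit_preprocessor <- function(name, X_train, protocol) {
  switch(name,
    raw = identity,
    snv = function(X) snv(X),
    sg = function(X) sg_smooth(X, protocol$sg_window, protocol$sg_polyorder),
    msc = {
      ref <- msc_reference(X_train)
      function(X) {
        out <- msc(X, ref)
        attr(out, "reference") <- NULL
        out
      }
    },
    stop("unknown preprocessor: ", name, call. = FALSE)
  )
}

#' Run the preprocess x selector x classifier experiment grid
#'
#' Splits the spectra into stratified train/test partitions, fits each
#' preprocessor on the training partition only (the MSC reference is the
#' training mean spectrum, reused on the test partition), runs each
#' selector on the preprocessed training data, applies the selected mask to
#' both partitions, grid-searches each classifier on the training data and
#' reports train/test accuracy and macro precision/recall/F1 on the test
#' partition. The test partition never influences preprocessing statistics,
#' selection or hyperparameter choice.
#'
#' @param spectra A [spectra_set].
#' @param protocol An [eval_protocol].
#' @param preprocessors Character vector from `"raw"`, `"msc"`, `"snv"`,
#'   `"sg"`.
#' @param selectors Named list: `NULL` entries mean "use all bands"; other
#'   entries are [selector_spec] objects.
#' @param classifiers Character vector from `"elm"`, `"rf"`, `"svm"`.
#' @param fitness_cfg A [fitness_config] for the wrapper fitness inside the
#'   selectors.
#' @param seed Master seed (split, folds, classifier randomness).
#' @return A `results_table`: data frame with one row per combination and
#'   columns `preprocess`, `selector`, `classifier`, `n_selected`,
#'   `train_accuracy`, `test_accuracy`, `precision`, `recall`, `f1`.
#'   Selector traces and masks are attached as attributes `"traces"` and
#'   `"masks"`.
#' @export
run_experiment_grid <- function(spectra,
                                protocol = eval_protocol(),
                                preprocessors = c("raw", "msc", "snv", "sg"),
                                selectors = list(none = NULL),
                                classifiers = c("elm", "rf", "svm"),
                                fitness_cfg = fitness_config(),
                                seed = 1L) {
  stopifnot(inherits(spectra, "spectra_set"))
  test <- .stratified_holdout(spectra$labels, protocol$test_fraction, seed)
  X_all <- spectra$reflectance
  y_tr <- spectra$labels[!test]
  y_te <- spectra$labels[test]
  if (is.null(names(selectors))) names(selectors) <- paste0("sel", seq_along(selectors))

  rows <- list()
  traces <- list()
  masks <- list()
  for (pname in preprocessors) {
    tf <- .fit_preprocessor(pname, X_all[!test, , drop = FALSE], protocol)
    X_tr <- tf(X_all[!test, , drop = FALSE])
    X_te <- tf(X_all[test, , drop = FALSE])
    for (sname in names(selectors)) {
      sel <- selectors[[sname]]
      combo <- paste(pname, sname, sep = "-")
      if (is.null(sel)) {
        mask <- rep(TRUE, ncol(X_tr))
      } else {
        stopifnot(inherits(sel, "selector_spec"))
        fit_fn <- make_knn_fitness(X_tr, y_tr, fitness_cfg)
        cfg <- do.call(optimizer_config, c(list(dim = ncol(X_tr)), sel$args))
        res <- tryCatch(
          run_selector(sel$algorithm, fit_fn, cfg),
          error = function(e) stop("selector '", combo, "' failed: ",
                                   conditionMessage(e), call. = FALSE))
        mask <- res$best_mask
        traces[[combo]] <- res$trace
      }
      masks[[combo]] <- mask
      for (cname in classifiers) {
        gs <- tryCatch(
          grid_search_classifier(cname, X_tr[, mask, drop = FALSE], y_tr,
                                 protocol, seed),
          error = function(e) stop("classifier '", cname, "' on '", combo,
                                   "' failed: ", conditionMessage(e),
                                   call. = FALSE))
        pr_tr <- predict(gs$model, X_tr[, mask, drop = FALSE])
        pr_te <- predict(gs$model, X_te[, mask, drop = FALSE])
        met <- compute_metrics(y_te, pr_te)
        rows[[length(rows) + 1L]] <- data.frame(
          preprocess = pname, selector = sname, classifier = cname,
          n_selected = sum(mask),
          train_accuracy = mean(pr_tr == y_tr),
          test_accuracy = met$accuracy,
          precision = met$precision, recall = met$recall, f1 = met$f1)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "traces") <- traces
  attr(out, "masks") <- masks
  class(out) <- c("results_table", "data.frame")
  out
}
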