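#' Optimizer configuration
#'
#' Configuration for the information-acquisition optimizers ([run_optimizer])
#' and, via its shared fields, the binary PSO/SCA baselines. The enhancement
#' flags turn the EIAO additions on or off; with every flag `FALSE` the run
#' is the plain IAO (uniform random initialization, single-difference
#' collection stage, plain filtering stage, no Levy flight, no crossover).
#'
#' @param dim Problem dimension `D` (number of candidate features/bands).
#' @param n_pop Population size `N` (default 20).
#' @param max_iter Iteration budget (default 50).
#' @param lb,ub Scalar or length-`D` continuous search bounds. The default
#'   `[-4, 4]` lets the sigmoid transfer span roughly (0.018, 0.982) so both
#'   bit values stay reachable under a 0.5 threshold.
#' @param mu Logistic-map rate for chaotic initialization (default 4, the
#'   fully chaotic regime).
#' @param elite_fraction Fraction of the population treated as elites in
#'   opposition-based learning (default 0.10).
#' @param levy_exponent Stability exponent of the Levy step in (1, 2]
#'   (default 1.5).
#' @param levy_scale Levy step scale as a fraction of the per-dimension box
#'   width (default 0.01).
#' @param laplace_p,laplace_q Location and scale of the Laplace crossover
#'   distribution (defaults 0 and 0.5; `laplace_q > 0`).
#' @param laplace_variant `"two_uniform"` (a genuine Laplace distribution,
#'   default) or `"as_printed"` (single-uniform variant; see
#'   [laplace_sample]).
#' @param threshold_mode Binarization threshold: `"fixed_half"` (C = 0.5,
#'   default) or `"uniform_random"` (C ~ U(0,1) per dimension per call).
#' @param dual_difference Use two difference terms in the collection stage.
#' @param sine_cosine_stage2 Use the sine/cosine form of the filtering stage.
#' @param levy_stage3 Add a Levy step in the organization stage.
#' @param laplace_crossover Apply one Laplace crossover (global best x random
#'   agent) per iteration.
#' @param elite_opposition Chaotic initialization plus elite opposition-based
#'   learning (off = uniform random initialization, as in plain IAO).
#' @param seed Integer RNG seed; identical configs and seeds give
#'   bit-identical results.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(dim,
                             n_pop = 20L,
                             max_iter = 50L,
                             lb = -4,
                             ub = 4,
                             mu = 4,
                             elite_fraction = 0.10,
                             levy_exponent = 1.5,
                             levy_scale = 0.01,
                             laplace_p = 0,
                             laplace_q = 0.5,
                             laplace_variant = c("two_uniform", "as_printed"),
                             threshold_mode = c("fixed_half", "uniform_random"),
                             dual_difference = TRUE,
                             sine_cosine_stage2 = TRUE,
                             levy_stage3 = TRUE,
                             laplace_crossover = TRUE,
                             elite_opposition = TRUE,
                             seed = 1L) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 2L) stop("dim must be an integer >= 2", call. = FALSE)
  n_pop <- as.integer(n_pop)
  max_iter <- as.integer(max_iter)
  if (n_pop < 2L) stop("n_pop must be >= 2", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  lb <- rep_len(as.numeric(lb), dim)
  ub <- rep_len(as.numeric(ub), dim)
  if (any(lb >= ub)) stop("lb must be < ub elementwise", call. = FALSE)
  if (elite_fraction <= 0 || elite_fraction >= 1) {
    stop("elite_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (mu <= 0 || mu > 4) stop("mu must lie in (0, 4]", call. = FALSE)
  if (levy_exponent <= 1 || levy_exponent > 2) {
    stop("levy_exponent must lie in (1, 2]", call. = FALSE)
  }
  if (laplace_q <= 0) stop("laplace_q must be > 0", call. = FALSE)
  cfg <- list(
    dim = dim, n_pop = n_pop, max_iter = max_iter, lb = lb, ub = ub,
    mu = mu, elite_fraction = elite_fraction,
    levy_exponent = levy_exponent, levy_scale = levy_scale,
    laplace_p = laplace_p, laplace_q = laplace_q,
    laplace_variant = match.arg(laplace_variant),
    threshold_mode = match.arg(threshold_mode),
    dual_difference = isTRUE(dual_difference),
    sine_cosine_stage2 = isTRUE(sine_cosine_stage2),
    levy_stage3 = isTRUE(levy_stage3),
    laplace_crossover = isTRUE(laplace_crossover),
    elite_opposition = isTRUE(elite_opposition),
    seed = as.integer(seed)
  )
  class(cfg) <- "optimizer_config"
  cfg
}

#' @rdname optimizer_config
#' @param ... Passed to [optimizer_config]; the enhancement flags are forced
#'   off so the run is the plain IAO.
#' @export
iao_config <- function(dim, ...) {
  optimizer_config(dim, ...,
                   dual_difference = FALSE, sine_cosine_stage2 = FALSE,
                   levy_stage3 = FALSE, laplace_crossover = FALSE,
                   elite_opposition = FALSE)
}

clamp <- function(x, lb, ub) pmin(pmax(x, lb), ub)

# sign-preserving real power / cube root (negative bases stay real)
signed_pow <- function(x, p) sign(x) * abs(x)^p
signed_cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Logistic map sequence
#'
#' Iterates the chaotic logistic recurrence `theta <- mu * theta * (1 - theta)`.
#'
#' @param theta0 Starting value in (0, 1), away from the degenerate points
#'   \{0, 0.25, 0.5, 0.75, 1\} of the mu = 4 map.
#' @param mu Map rate in (0, 4].
#' @param n Number of iterates to return (the returned vector starts at
#'   `theta1`, i.e. `theta0` is not included).
#' @param tol Rejection tolerance around degenerate points.
#' @return Numeric vector of length `n`, all values in `[0, 1]`.
#' @export
logistic_sequence <- function(theta0, mu = 4, n = 1L, tol = 1e-6) {
  if (mu <= 0 || mu > 4) stop("mu must lie in (0, 4]", call. = FALSE)
  degen <- c(0, 0.25, 0.5, 0.75, 1)
  if (any(abs(theta0 - degen) < tol)) {
    stop("theta0 is (near) a degenerate point of the logistic map",
         call. = FALSE)
  }
  out <- numeric(n)
  th <- theta0
  for (k in seq_len(n)) {
    th <- mu * th * (1 - th)
    out[k] <- th
  }
  out
}

# draw a logistic seed away from degenerate points
.draw_theta0 <- function(tol = 1e-6) {
  repeat {
    th <- stats::runif(1)
    if (all(abs(th - c(0, 0.25, 0.5, 0.75, 1)) >= tol)) return(th)
  }
}

#' Chaotic population initialization
#'
#' One logistic-map trajectory per agent, affinely mapped onto the search
#' box: `x_j = (ub_j - lb_j) * theta_j + lb_j`.
#'
#' @param config An [optimizer_config].
#' @return `n_pop x dim` numeric matrix of positions, all within bounds.
#' @export
chaotic_init <- function(config) {
  X <- matrix(0, config$n_pop, config$dim)
  for (i in seq_len(config$n_pop)) {
    th <- logistic_sequence(.draw_theta0(), config$mu, config$dim)
    X[i, ] <- (config$ub - config$lb) * th + config$lb
  }
  X
}

#' Sigmoid transfer function
#'
#' S-shaped transfer `1 / (1 + exp(-x))` mapping a continuous position
#' coordinate to a bit-selection probability.
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
transfer_sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binarize a continuous position
#'
#' Bit `j` is set iff `transfer_sigmoid(x_j) >= C_j`, with `C_j = 0.5`
#' (`"fixed_half"`) or `C_j ~ U(0,1)` drawn per dimension
#' (`"uniform_random"`). An all-zero result is repaired by setting one
#' uniformly random bit (a fitness on the empty subset is undefined).
#'
#' @param x Numeric position vector.
#' @param mode Threshold mode.
#' @return Logical vector with at least one `TRUE`.
#' @export
binarize <- function(x, mode = c("fixed_half", "uniform_random")) {
  mode <- match.arg(mode)
  thr <- if (mode == "fixed_half") 0.5 else stats::runif(length(x))
  bits <- transfer_sigmoid(x) >= thr
  if (!any(bits)) bits[sample.int(length(x), 1L)] <- TRUE
  bits
}

#' Per-update stochastic factors
#'
#' The scalar factors driving the filtering and organization stages. Each is
#' recomputed per agent per iteration from fresh uniform draws.
#'
#' `subjective_influence` returns `Xi = 2 * mod(3.648 * nu * (1 - beta_r) *
#' acos(gamma_r) * 1e4, 1)`, a chaotic multiplier in `[0, 2)`.
#' `quality_factor` returns `Phi = cos(2 * delta_r + 1) * (1 - iter/max_iter)`.
#' `reliability_factor` returns `Gamma = sin(pi/4 * iter/max_iter) + Phi +
#' log10(iter/max_iter)/8`. `subjective_error` returns
#' `Delta = signed_pow(cos(pi/2 * |Gamma|), Xi)` and `control_factor`
#' returns `Lambda = 2 * (|Gamma| - 2)`.
#'
#' @param nu,beta_r,gamma_r,delta_r Uniform(0,1) draws; by default drawn
#'   from the current RNG stream.
#' @param iter,max_iter Current (>= 1) and maximum iteration.
#' @param phi Information quality factor `Phi`.
#' @param gamma Reliability factor `Gamma`.
#' @param xi Subjective influence factor `Xi`.
#' @return A scalar.
#' @name iteration_factors
NULL

#' @rdname iteration_factors
#' @export
subjective_influence <- function(nu = stats::runif(1),
                                 beta_r = stats::runif(1),
                                 gamma_r = stats::runif(1)) {
  2 * ((3.648 * nu * (1 - beta_r) * acos(gamma_r) * 1e4) %% 1)
}

#' @rdname iteration_factors
#' @export
quality_factor <- function(iter, max_iter, delta_r = stats::runif(1)) {
  cos(2 * delta_r + 1) * (1 - iter / max_iter)
}

#' @rdname iteration_factors
#' @export
reliability_factor <- function(iter, max_iter, phi) {
  if (iter < 1) stop("iter must be >= 1 (log10 of 0 undefined)", call. = FALSE)
  sin((pi / 4) * iter / max_iter) + phi + log10(iter / max_iter) / 8
}

#' @rdname iteration_factors
#' @export
subjective_error <- function(gamma, xi) signed_pow(cos(pi / 2 * abs(gamma)), xi)

#' @rdname iteration_factors
#' @export
control_factor <- function(gamma) 2 * (abs(gamma) - 2)

#' Stage 1: information collection
#'
#' Differential move using one (plain) or two (`dual_difference`) randomly
#' chosen donor pairs: `x' = x + theta*(x_r1 - x_r2) [+ theta*(x_r3 - x_r4)]`,
#' clipped to bounds.
#'
#' @param i Index of the agent being updated.
#' @param X Population position matrix (`n_pop x dim`).
#' @param theta Scalar uniform(0,1) step factor.
#' @param dual_difference Add the second difference pair.
#' @param lb,ub Bounds.
#' @return Candidate position vector.
#' @export
stage1_collect <- function(i, X, theta, dual_difference, lb, ub) {
  n <- nrow(X)
  need <- if (dual_difference) 4L else 2L
  if (n - 1L < need) {
    stop("population too small for ", need, " distinct donors", call. = FALSE)
  }
  donors <- sample(setdiff(seq_len(n), i), need)
  cand <- X[i, ] + theta * (X[donors[1L], ] - X[donors[2L], ])
  if (dual_difference) {
    cand <- cand + theta * (X[donors[3L], ] - X[donors[4L], ])
  }
  clamp(cand, lb, ub)
}

#' Stage 2: information filtering
#'
#' Move relative to a random reference agent. With `sine_cosine = TRUE` the
#' step is modulated by `sin(r5)`/`cos(r5)`:
#' `x' = x -/+ Delta * sin|cos(r5) * step * (x_rand - x)`; without it the
#' plain form drops the trigonometric factor. The branch (minus vs plus) is
#' taken when `branch < 0.5`.
#'
#' @param x Current position.
#' @param x_rand Reference position (uniformly drawn agent).
#' @param delta Subjective error `Delta` (see [subjective_error]).
#' @param r5 Uniform(0, 2*pi) phase draw.
#' @param branch,step Uniform(0,1) draws: branch selector and step size.
#' @param sine_cosine Use the sine/cosine form.
#' @param lb,ub Bounds.
#' @return Candidate position vector.
#' @export
stage2_filter <- function(x, x_rand, delta, r5, branch, step, sine_cosine,
                          lb, ub) {
  diffv <- x_rand - x
  cand <- if (sine_cosine) {
    if (branch < 0.5) x - delta * sin(r5) * step * diffv
    else              x + delta * cos(r5) * step * diffv
  } else {
    if (branch < 0.5) x - delta * step * diffv
    else              x + delta * step * diffv
  }
  clamp(cand, lb, ub)
}

#' Levy flight step
#'
#' Heavy-tailed step vector via the Mantegna algorithm:
#' `step_j = u_j / |v_j|^(1/exponent)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and the standard Mantegna `sigma_u`. The result is scaled
#' by `scale * (ub - lb)` per dimension.
#'
#' @param d Dimension.
#' @param exponent Stability exponent in (1, 2].
#' @param scale Step scale as a fraction of the box width.
#' @param lb,ub Bounds (define the box width).
#' @return Numeric vector of length `d`.
#' @export
levy_step <- function(d, exponent = 1.5, scale = 0.01, lb = -4, ub = 4) {
  sigma_u <- (gamma(1 + exponent) * sin(pi * exponent / 2) /
                (gamma((1 + exponent) / 2) * exponent *
                   2^((exponent - 1) / 2)))^(1 / exponent)
  u <- stats::rnorm(d, 0, sigma_u)
  v <- stats::rnorm(d)
  scale * (ub - lb) * u / abs(v)^(1 / exponent)
}

#' Stage 3: information organization
#'
#' Local move around the global best position. With `m = mean(x_best)`:
#' if `phi >= 0.5`, `x' = x_best * cos(pi/2 * Lambda^(1/3)) -
#' eps * (m - x_best)`; otherwise `x' = x_best * cos(pi/2 * Lambda^(1/3)) -
#' 0.8 * (zeta * kap * m - (2*omg - 1) * x_best)`. `Lambda^(1/3)` is the
#' real signed cube root. An optional Levy vector is added.
#'
#' @param x_best Global best position.
#' @param gamma,phi Reliability and quality factors.
#' @param eps,zeta,kap,omg Uniform(0,1) draws.
#' @param levy Optional Levy step vector (or `NULL`).
#' @param lb,ub Bounds.
#' @return Candidate position vector.
#' @export
stage3_organize <- function(x_best, gamma, phi, eps, zeta, kap, omg,
                            levy = NULL, lb, ub) {
  lam <- control_factor(gamma)
  cfac <- cos(pi / 2 * signed_cbrt(lam))
  m <- mean(x_best)
  cand <- if (phi >= 0.5) {
    x_best * cfac - eps * (m - x_best)
  } else {
    x_best * cfac - 0.8 * (zeta * kap * m - (2 * omg - 1) * x_best)
  }
  if (!is.null(levy)) cand <- cand + levy
  clamp(cand, lb, ub)
}

#' Laplace-distributed samples
#'
#' `"two_uniform"` (default) draws a genuine Laplace(p, q) variate from two
#' independent uniforms: magnitude `-q*log(u)` with a fair sign. The
#' `"as_printed"` variant uses a single uniform for both branch and
#' magnitude (`l = p - q*log(u)` if `u <= 1/2`, else `p + q*log(u)`); its
#' support has a gap of width `2*q*log(2)` centred at `p` and it is kept
#' only for fidelity to the single-draw recipe.
#'
#' @param n Number of samples.
#' @param p Location parameter.
#' @param q Scale parameter, `> 0`.
#' @param variant `"two_uniform"` or `"as_printed"`.
#' @return Numeric vector of length `n`.
#' @export
laplace_sample <- function(n, p = 0, q = 1,
                           variant = c("two_uniform", "as_printed")) {
  if (q <= 0) stop("q must be > 0", call. = FALSE)
  variant <- match.arg(variant)
  u <- stats::runif(n)
  if (variant == "as_printed") {
    ifelse(u <= 0.5, p - q * log(u), p + q * log(u))
  } else {
    r <- stats::runif(n)
    ifelse(r <= 0.5, p - q * log(u), p + q * log(u))
  }
}

#' Laplace crossover
#'
#' Offspring are placed symmetrically around the parents at Laplace-
#' distributed multiples of the per-dimension parent gap:
#' `y1_j = x1_j + l_j * |x1_j - x2_j|`, `y2_j = x2_j + l_j * |x1_j - x2_j|`.
#'
#' @param x1,x2 Parent position vectors (equal length).
#' @param p,q Laplace location and scale (`q > 0`).
#' @param variant Passed to [laplace_sample].
#' @param lb,ub Optional bounds for clipping.
#' @return List with elements `y1`, `y2`.
#' @export
laplace_crossover <- function(x1, x2, p = 0, q = 0.5,
                              variant = c("two_uniform", "as_printed"),
                              lb = NULL, ub = NULL) {
  if (length(x1) != length(x2)) {
    stop("parent vectors must have equal length", call. = FALSE)
  }
  l <- laplace_sample(length(x1), p, q, match.arg(variant))
  gap <- abs(x1 - x2)
  y1 <- x1 + l * gap
  y2 <- x2 + l * gap
  if (!is.null(lb)) {
    y1 <- clamp(y1, lb, ub)
    y2 <- clamp(y2, lb, ub)
  }
  list(y1 = y1, y2 = y2)
}

#' Elite opposition-based learning
#'
#' For the best `ceiling(elite_fraction * N)` agents, evaluates the opposite
#' point `r * (da + db) - x` inside the elites' dynamic per-dimension bounds
#' `[da, db]` (`r ~ U(0,1)` per agent) and keeps whichever of original and
#' opposite has the better (lower) fitness.
#'
#' @param X Position matrix.
#' @param fit Fitness vector (lower is better).
#' @param masks Logical mask matrix matching `X`.
#' @param eval_fn Function(position) -> list(mask, fitness, error).
#' @param elite_fraction Fraction in (0, 1).
#' @param lb,ub Bounds.
#' @return List with updated `X`, `fit`, `masks`, `err`.
#' @keywords internal
elite_opposition_step <- function(X, fit, masks, err, eval_fn,
                                  elite_fraction, lb, ub) {
  n_elite <- ceiling(elite_fraction * nrow(X))
  elite <- order(fit)[seq_len(n_elite)]
  da <- apply(X[elite, , drop = FALSE], 2, min)
  db <- apply(X[elite, , drop = FALSE], 2, max)
  for (i in elite) {
    r <- stats::runif(1)
    opp <- clamp(r * (da + db) - X[i, ], lb, ub)
    ev <- eval_fn(opp)
    if (ev$fitness < fit[i]) {
      X[i, ] <- opp
      fit[i] <- ev$fitness
      masks[i, ] <- ev$mask
      err[i] <- ev$error
    }
  }
  list(X = X, fit = fit, masks = masks, err = err)
}

# evaluate a continuous position: binarize, call the user fitness
.make_eval <- function(fitness_fn, mode) {
  function(x) {
    mask <- binarize(x, mode)
    f <- fitness_fn(mask)
    e <- attr(f, "error")
    list(mask = mask, fitness = as.numeric(f),
         error = if (is.null(e)) NA_real_ else as.numeric(e))
  }
}

#' Run an information-acquisition optimizer
#'
#' Minimizes `fitness_fn` over bit vectors of length `config$dim` using the
#' EIAO scheme (or plain IAO when all enhancement flags are off). Each
#' iteration, every agent passes through the collection, filtering and
#' organization stages with greedy per-stage acceptance: a candidate is
#' kept only if its binarized fitness is at least as good as the agent's
#' (collection/filtering stages, allowing drift across the plateaus of the
#' piecewise-constant binarized landscape) or strictly better (the
#' organization stage and the crossover, whose candidates derive from the
#' global best and would otherwise collapse population diversity).
#' Optionally one Laplace crossover between the global best and a random
#' agent closes the iteration. All randomness comes from `config$seed`.
#'
#' @param fitness_fn Function(logical mask) -> numeric fitness (lower is
#'   better). May attach an `"error"` attribute (e.g. a classifier error
#'   rate), which is propagated into the result.
#' @param config An [optimizer_config].
#' @return A `selection_result`: list with `best_mask` (logical),
#'   `best_fitness`, `best_error`, `best_accuracy` (`1 - best_error`),
#'   `n_selected`, `trace` (data frame `iteration`, `best_fitness`;
#'   non-increasing), `algorithm`, `seed`, `config`.
#' @export
run_optimizer <- function(fitness_fn, config) {
  stopifnot(inherits(config, "optimizer_config"))
  set.seed(config$seed)
  d <- config$dim
  n <- config$n_pop
  lb <- config$lb
  ub <- config$ub
  eval_fn <- .make_eval(fitness_fn, config$threshold_mode)

  X <- if (config$elite_opposition) {
    chaotic_init(config)
  } else {
    matrix(stats::runif(n * d), n, d) *
      matrix(ub - lb, n, d, byrow = TRUE) +
      matrix(lb, n, d, byrow = TRUE)
  }
  masks <- matrix(FALSE, n, d)
  fit <- numeric(n)
  err <- numeric(n)
  for (i in seq_len(n)) {
    ev <- .eval_with_context(eval_fn, X[i, ], 0L, i)
    masks[i, ] <- ev$mask
    fit[i] <- ev$fitness
    err[i] <- ev$error
  }
  if (config$elite_opposition) {
    st <- elite_opposition_step(X, fit, masks, err, eval_fn,
                                config$elite_fraction, lb, ub)
    X <- st$X; fit <- st$fit; masks <- st$masks; err <- st$err
  }

  gb <- which.min(fit)
  gbest_x <- X[gb, ]
  gbest_mask <- masks[gb, ]
  gbest_fit <- fit[gb]
  gbest_err <- err[gb]
  trace <- numeric(config$max_iter)

  for (iter in seq_len(config$max_iter)) {
    for (i in seq_len(n)) {
      # stage 1: collection
      theta <- stats::runif(1)
      cand <- stage1_collect(i, X, theta, config$dual_difference, lb, ub)
      ev <- .eval_with_context(eval_fn, cand, iter, i)
      # ties accepted: the binarized landscape is piecewise constant, so
      # equal-fitness moves let the continuous search drift across plateaus
      if (ev$fitness <= fit[i]) {
        X[i, ] <- cand; fit[i] <- ev$fitness
        masks[i, ] <- ev$mask; err[i] <- ev$error
      }

      # per-agent stochastic factors
      xi <- subjective_influence()
      phi <- quality_factor(iter, config$max_iter)
      gam <- reliability_factor(iter, config$max_iter, phi)
      delta <- subjective_error(gam, xi)

      # stage 2: filtering
      x_rand <- X[sample.int(n, 1L), ]
      r5 <- stats::runif(1, 0, 2 * pi)
      branch <- stats::runif(1)
      step <- stats::runif(1)
      cand <- stage2_filter(X[i, ], x_rand, delta, r5, branch, step,
                            config$sine_cosine_stage2, lb, ub)
      ev <- .eval_with_context(eval_fn, cand, iter, i)
      if (ev$fitness <= fit[i]) {
        X[i, ] <- cand; fit[i] <- ev$fitness
        masks[i, ] <- ev$mask; err[i] <- ev$error
      }
      if (fit[i] < gbest_fit) {
        gbest_fit <- fit[i]; gbest_x <- X[i, ]
        gbest_mask <- masks[i, ]; gbest_err <- err[i]
      }

      # stage 3: organization around the global best
      draws <- stats::runif(4)
      levy <- if (config$levy_stage3) {
        levy_step(d, config$levy_exponent, config$levy_scale, lb, ub)
      } else NULL
      cand <- stage3_organize(gbest_x, gam, phi, draws[1], draws[2],
                              draws[3], draws[4], levy, lb, ub)
      ev <- .eval_with_context(eval_fn, cand, iter, i)
      # strict here: stage-3 candidates derive from the global best, and
      # accepting ties would collapse population diversity onto it
      if (ev$fitness < fit[i]) {
        X[i, ] <- cand; fit[i] <- ev$fitness
        masks[i, ] <- ev$mask; err[i] <- ev$error
      }
      if (fit[i] < gbest_fit) {
        gbest_fit <- fit[i]; gbest_x <- X[i, ]
        gbest_mask <- masks[i, ]; gbest_err <- err[i]
      }
    }

    if (config$laplace_crossover) {
      j <- sample.int(n, 1L)
      off <- laplace_crossover(gbest_x, X[j, ], config$laplace_p,
                               config$laplace_q, config$laplace_variant,
                               lb, ub)
      ev1 <- .eval_with_context(eval_fn, off$y1, iter, j)
      ev2 <- .eval_with_context(eval_fn, off$y2, iter, j)
      best_off <- if (ev1$fitness <= ev2$fitness) list(x = off$y1, ev = ev1)
                  else list(x = off$y2, ev = ev2)
      if (best_off$ev$fitness < fit[j]) {
        X[j, ] <- best_off$x
        fit[j] <- best_off$ev$fitness
        masks[j, ] <- best_off$ev$mask
        err[j] <- best_off$ev$error
      }
      if (fit[j] < gbest_fit) {
        gbest_fit <- fit[j]; gbest_x <- X[j, ]
        gbest_mask <- masks[j, ]; gbest_err <- err[j]
      }
    }
    trace[iter] <- gbest_fit
  }

  selection_result(
    best_mask = gbest_mask, best_fitness = gbest_fit, best_error = gbest_err,
    trace = trace,
    algorithm = if (all_flags_off(config)) "iao" else "eiao",
    seed = config$seed, config = config
  )
}

all_flags_off <- function(config) {
  !config$dual_difference && !config$sine_cosine_stage2 &&
    !config$levy_stage3 && !config$laplace_crossover &&
    !config$elite_opposition
}

.eval_with_context <- function(eval_fn, x, iter, agent) {
  tryCatch(eval_fn(x), error = function(e) {
    stop(sprintf("fitness evaluation failed at iteration %d, agent %d: %s",
                 iter, agent, conditionMessage(e)), call. = FALSE)
  })
}

#' Selection result container
#'
#' Common result schema for [run_optimizer], [binary_pso] and [binary_sca],
#' so comparison tables across algorithms are mechanical.
#'
#' @param best_mask Logical vector, the best band subset found.
#' @param best_fitness Its fitness value.
#' @param best_error Its classifier error (or `NA`).
#' @param trace Numeric vector of per-iteration global best fitness.
#' @param algorithm Algorithm label.
#' @param seed RNG seed used.
#' @param config The configuration object.
#' @return A list of class `selection_result`.
#' @export
selection_result <- function(best_mask, best_fitness, best_error = NA_real_,
                             trace, algorithm, seed, config) {
  stopifnot(sum(best_mask) >= 1L)
  structure(
    list(best_mask = as.logical(best_mask),
         best_fitness = as.numeric(best_fitness),
         best_error = as.numeric(best_error),
         best_accuracy = 1 - as.numeric(best_error),
         n_selected = sum(best_mask),
         trace = data.frame(iteration = seq_along(trace),
                            best_fitness = as.numeric(trace)),
         algorithm = algorithm, seed = seed, config = config),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d/%d features, fitness %.5f",
              x$algorithm, x$n_selected, length(x$best_mask), x$best_fitness))
  if (is.finite(x$best_accuracy)) {
    cat(sprintf(", wrapper accuracy %.4f", x$best_accuracy))
  }
  cat(sprintf("\n  %d iterations, seed %d\n", nrow(x$trace), x$seed))
  invisible(x)
}

#' Serialize a selection result
#'
#' `write_selection_result` writes the mask (as 1-based index list plus
#' bitstring), fitness, accuracy and seed to JSON; `write_trace` writes the
#' per-iteration convergence trace as CSV.
#'
#' @param x A `selection_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  obj <- list(
    algorithm = x$algorithm,
    seed = x$seed,
    best_fitness = x$best_fitness,
    best_error = x$best_error,
    best_accuracy = x$best_accuracy,
    n_selected = x$n_selected,
    n_total = length(x$best_mask),
    selected_indices = which(x$best_mask),
    mask_bitstring = paste(as.integer(x$best_mask), collapse = "")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_result
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  utils::write.csv(x$trace, path, row.names = FALSE)
  invisible(path)
}
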