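#' Binary particle swarm optimization
#'
#' Sigmoid-binarized PSO comparator sharing the fitness, binarization,
#' repair and trace contracts of [run_optimizer]. Velocity update
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with per-dimension
#' uniform draws and a symmetric velocity clamp; positions are clipped to
#' the bounds, binarized and scored, with greedy personal/global best
#' archiving.
#'
#' @param fitness_fn Function(logical mask) -> fitness (lower is better),
#'   optionally with an `"error"` attribute.
#' @param config An [optimizer_config] providing the shared budget
#'   (`n_pop`, `max_iter`, bounds, `threshold_mode`, `seed`).
#' @param c1,c2 Cognitive and social coefficients (default 2, 2).
#' @param inertia Inertia weight `w` (default 1).
#' @param v_max Velocity clamp (default 6).
#' @return A `selection_result` (see [selection_result]).
#' @export
binary_pso <- function(fitness_fn, config, c1 = 2, c2 = 2, inertia = 1,
                       v_max = 6) {
  stopifnot(inherits(config, "optimizer_config"))
  if (c1 <= 0 || c2 <= 0 || inertia <= 0 || v_max <= 0) {
    stop("PSO parameters must be positive", call. = FALSE)
  }
  set.seed(config$seed)
  d <- config$dim
  n <- config$n_pop
  lb <- config$lb
  ub <- config$ub
  eval_fn <- .make_eval(fitness_fn, config$threshold_mode)

  X <- matrix(stats::runif(n * d), n, d) *
    matrix(ub - lb, n, d, byrow = TRUE) + matrix(lb, n, d, byrow = TRUE)
  V <- matrix(0, n, d)
  fit <- numeric(n)
  err <- numeric(n)
  masks <- matrix(FALSE, n, d)
  for (i in seq_len(n)) {
    ev <- .eval_with_context(eval_fn, X[i, ], 0L, i)
    fit[i] <- ev$fitness; err[i] <- ev$error; masks[i, ] <- ev$mask
  }
  P <- X                      # personal bests
  pfit <- fit; perr <- err; pmask <- masks
  gb <- which.min(pfit)
  gbest_x <- P[gb, ]; gbest_fit <- pfit[gb]
  gbest_err <- perr[gb]; gbest_mask <- pmask[gb, ]

  trace <- numeric(config$max_iter)
  for (iter in seq_len(config$max_iter)) {
    for (i in seq_len(n)) {
      r1 <- stats::runif(d)
      r2 <- stats::runif(d)
      V[i, ] <- clamp(inertia * V[i, ] + c1 * r1 * (P[i, ] - X[i, ]) +
                        c2 * r2 * (gbest_x - X[i, ]), -v_max, v_max)
      X[i, ] <- clamp(X[i, ] + V[i, ], lb, ub)
      ev <- .eval_with_context(eval_fn, X[i, ], iter, i)
      if (ev$fitness < pfit[i]) {
        P[i, ] <- X[i, ]; pfit[i] <- ev$fitness
        perr[i] <- ev$error; pmask[i, ] <- ev$mask
      }
      if (pfit[i] < gbest_fit) {
        gbest_fit <- pfit[i]; gbest_x <- P[i, ]
        gbest_err <- perr[i]; gbest_mask <- pmask[i, ]
      }
    }
    trace[iter] <- gbest_fit
  }
  selection_result(gbest_mask, gbest_fit, gbest_err, trace,
                   algorithm = "pso", seed = config$seed, config = config)
}

#' Binary sine-cosine algorithm
#'
#' Sigmoid-binarized SCA comparator. The step amplitude decays linearly,
#' `r1 = a - iter * a / max_iter`, and each coordinate moves toward (or
#' away from) the global best: `x + r1*sin(r2)*|r3*gbest - x|` when
#' `r4 < 0.5`, the cosine form otherwise, with `r2 ~ U(0, 2*pi)`,
#' `r3 ~ U(0, 2)`, `r4 ~ U(0, 1)` per dimension. The global best is
#' archived greedily, so the trace is non-increasing.
#'
#' @inheritParams binary_pso
#' @param a Amplitude schedule constant (default 2).
#' @return A `selection_result`.
#' @export
binary_sca <- function(fitness_fn, config, a = 2) {
  stopifnot(inherits(config, "optimizer_config"))
  if (a <= 0) stop("a must be positive", call. = FALSE)
  set.seed(config$seed)
  d <- config$dim
  n <- config$n_pop
  lb <- config$lb
  ub <- config$ub
  eval_fn <- .make_eval(fitness_fn, config$threshold_mode)

  X <- matrix(stats::runif(n * d), n, d) *
    matrix(ub - lb, n, d, byrow = TRUE) + matrix(lb, n, d, byrow = TRUE)
  fit <- numeric(n)
  err <- numeric(n)
  masks <- matrix(FALSE, n, d)
  for (i in seq_len(n)) {
    ev <- .eval_with_context(eval_fn, X[i, ], 0L, i)
    fit[i] <- ev$fitness; err[i] <- ev$error; masks[i, ] <- ev$mask
  }
  gb <- which.min(fit)
  gbest_x <- X[gb, ]; gbest_fit <- fit[gb]
  gbest_err <- err[gb]; gbest_mask <- masks[gb, ]

  trace <- numeric(config$max_iter)
  for (iter in seq_len(config$max_iter)) {
    r1 <- a - iter * a / config$max_iter
    for (i in seq_len(n)) {
      r2 <- stats::runif(d, 0, 2 * pi)
      r3 <- stats::runif(d, 0, 2)
      r4 <- stats::runif(d)
      gap <- abs(r3 * gbest_x - X[i, ])
      X[i, ] <- clamp(ifelse(r4 < 0.5,
                             X[i, ] + r1 * sin(r2) * gap,
                             X[i, ] + r1 * cos(r2) * gap), lb, ub)
      ev <- .eval_with_context(eval_fn, X[i, ], iter, i)
      fit[i] <- ev$fitness; err[i] <- ev$error; masks[i, ] <- ev$mask
      if (fit[i] < gbest_fit) {
        gbest_fit <- fit[i]; gbest_x <- X[i, ]
        gbest_err <- err[i]; gbest_mask <- masks[i, ]
      }
    }
    trace[iter] <- gbest_fit
  }
  selection_result(gbest_mask, gbest_fit, gbest_err, trace,
                   algorithm = "sca", seed = config$seed, config = config)
}

#' Run a selector by name
#'
#' Dispatch helper used by the CLI and the experiment grid: `"eiao"` and
#' `"iao"` map to [run_optimizer] (with the enhancement flags on or off),
#' `"pso"` to [binary_pso] and `"sca"` to [binary_sca].
#'
#' @param algorithm One of `"eiao"`, `"iao"`, `"pso"`, `"sca"`.
#' @param fitness_fn Fitness closure.
#' @param config An [optimizer_config].
#' @param ... Extra arguments for the baseline (e.g. `c1`, `a`).
#' @return A `selection_result`.
#' @export
run_selector <- function(algorithm = c("eiao", "iao", "pso", "sca"),
                         fitness_fn, config, ...) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    eiao = run_optimizer(fitness_fn, config),
    iao = {
      cfg <- config
      cfg$dual_difference <- FALSE
      cfg$sine_cosine_stage2 <- FALSE
      cfg$levy_stage3 <- FALSE
      cfg$laplace_crossover <- FALSE
      cfg$elite_opposition <- FALSE
      run_optimizer(fitness_fn, cfg)
    },
    pso = binary_pso(fitness_fn, config, ...),
    sca = binary_sca(fitness_fn, config, ...)
  )
}
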