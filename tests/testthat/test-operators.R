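test_that("logistic sequence iterates the map and rejects degenerate seeds", {
  expect_equal(logistic_sequence(0.3, 4, 1), 0.84)
  expect_error(logistic_sequence(0.5, 4, 3), "degenerate")
  expect_error(logistic_sequence(0.75, 4, 3), "degenerate")
  th <- logistic_sequence(0.312, 4, 1000)
  expect_true(all(th >= 0 & th <= 1))
})

test_that("chaotic init stays in bounds and maps the box affinely", {
  set.seed(10)
  cfg <- optimizer_config(dim = 10, n_pop = 20, lb = -4, ub = 4)
  X <- chaotic_init(cfg)
  expect_equal(dim(X), c(20L, 10L))
  expect_true(all(X >= -4 & X <= 4))

  set.seed(10)
  cfg01 <- optimizer_config(dim = 10, n_pop = 20, lb = 0, ub = 1)
  X01 <- chaotic_init(cfg01)
  # identity scaling: positions are raw logistic iterates in [0,1]
  expect_true(all(X01 >= 0 & X01 <= 1))
  expect_equal(unname(X01[1, 2]), 4 * X01[1, 1] * (1 - X01[1, 1]))
})

test_that("sigmoid transfer and binarization behave as specified", {
  expect_equal(transfer_sigmoid(0), 0.5)
  expect_equal(transfer_sigmoid(4), 1 / (1 + exp(-4)), tolerance = 1e-12)
  x <- rnorm(50)
  expect_equal(transfer_sigmoid(x) + transfer_sigmoid(-x), rep(1, 50))

  expect_equal(binarize(c(3, -3), "fixed_half"), c(TRUE, FALSE))
  set.seed(11)
  b <- binarize(rep(-10, 8), "fixed_half")
  expect_equal(sum(b), 1L)  # repair sets exactly one bit

  # uniform_random threshold at x = 0: P(bit) = 0.5
  set.seed(12)
  rate <- mean(replicate(2e4, binarize(c(0, 5), "uniform_random")[1]))
  expect_lt(abs(rate - 0.5), 0.02)
})

test_that("iteration factors match their closed forms", {
  expect_equal(subjective_influence(nu = 0, beta_r = 0.3, gamma_r = 0.7), 0)
  expect_equal(subjective_influence(nu = 0.4, beta_r = 1, gamma_r = 0.7), 0)
  set.seed(13)
  xi <- replicate(1e4, subjective_influence())
  expect_true(all(xi >= 0 & xi < 2))

  expect_equal(quality_factor(10, 10, delta_r = 0.123), 0)
  expect_equal(quality_factor(3, 10, delta_r = (pi / 2 - 1) / 2), 0,
               tolerance = 1e-12)
  for (it in 1:9) {
    expect_lte(abs(quality_factor(it, 10)), 1 - it / 10 + 1e-12)
  }

  expect_equal(reliability_factor(10, 10, phi = 0), sin(pi / 4),
               tolerance = 1e-12)
  expect_equal(reliability_factor(1, 10, phi = 0), sin(pi / 40) - 1 / 8,
               tolerance = 1e-12)
  expect_error(reliability_factor(0, 10, phi = 0), "iter")

  expect_equal(control_factor(2), 0)
  expect_equal(control_factor(-3), 2)
  # signed power keeps negative bases real
  expect_equal(subjective_error(gamma = 1, xi = 1.7), 0, tolerance = 1e-12)
  expect_equal(subjective_error(gamma = 1.5, xi = 2),
               -abs(cos(0.75 * pi))^2, tolerance = 1e-12)
})

test_that("stage updates honour their algebraic identities", {
  set.seed(14)
  X <- matrix(rnorm(6 * 5), 6, 5)
  lb <- rep(-4, 5); ub <- rep(4, 5)

  # theta = 0 leaves the agent unchanged
  set.seed(1)
  expect_equal(stage1_collect(1, X, 0, FALSE, lb, ub), X[1, ])
  # dual off vs on with identical donor draws differ by theta*(x_r3 - x_r4)
  set.seed(7); c_off <- stage1_collect(2, X, 0.5, FALSE, lb, ub)
  set.seed(7); c_on <- stage1_collect(2, X, 0.5, TRUE, lb, ub)
  set.seed(7); donors <- sample(setdiff(1:6, 2), 4)
  expect_equal(c_on - c_off, 0.5 * (X[donors[3], ] - X[donors[4], ]),
               tolerance = 1e-12)
  expect_error(stage1_collect(1, X[1:4, ], 0.5, TRUE, lb, ub), "donors")

  # x_rand = x is a fixed point of stage 2 in both variants
  x <- X[3, ]
  for (sc in c(TRUE, FALSE)) {
    expect_equal(stage2_filter(x, x, 0.7, 1.1, 0.2, 0.9, sc, lb, ub), x)
  }
  # sin(0) = 0 freezes the minus branch of the sine/cosine variant
  expect_equal(stage2_filter(x, X[4, ], 0.7, 0, 0.2, 0.9, TRUE, lb, ub), x)
  # delta = 0 freezes both variants
  expect_equal(stage2_filter(x, X[4, ], 0, 2, 0.8, 0.9, FALSE, lb, ub), x)

  # stage 3: constant best vector, phi >= 0.5 -> pure cosine scaling
  cb <- rep(1.5, 5)
  got <- stage3_organize(cb, gamma = 1, phi = 0.6, eps = 0.4, zeta = 0.1,
                         kap = 0.2, omg = 0.9, levy = NULL, lb, ub)
  lam <- 2 * (abs(1) - 2)
  expect_equal(got, clamp(cb * cos(pi / 2 * sign(lam) * abs(lam)^(1 / 3)),
                          lb, ub))
  # |gamma| = 2 -> lambda = 0 -> leading factor is x_best itself
  got2 <- stage3_organize(cb, gamma = 2, phi = 0.6, eps = 0, zeta = 0,
                          kap = 0, omg = 0.5, levy = NULL, lb, ub)
  expect_equal(got2, cb)
  # levy on vs off differ exactly by the levy vector
  lv <- rep(0.01, 5)
  g_off <- stage3_organize(X[5, ], 1.2, 0.3, 0.1, 0.2, 0.3, 0.4, NULL, lb, ub)
  g_on <- stage3_organize(X[5, ], 1.2, 0.3, 0.1, 0.2, 0.3, 0.4, lv, lb, ub)
  expect_equal(g_on, clamp(g_off + lv, lb, ub))
})

test_that("levy steps are heavy-tailed", {
  set.seed(15)
  expect_equal(levy_step(5, scale = 0), rep(0, 5))
  expect_length(levy_step(7), 7L)
  s <- levy_step(1e5, exponent = 1.5, scale = 1, lb = 0, ub = 1)
  kurt <- mean((s - mean(s))^4) / stats::var(s)^2
  expect_gt(kurt, 50)  # far beyond Gaussian (3)
  expect_gt(max(abs(s)) / stats::median(abs(s)), 100)
})

test_that("laplace sampling matches its stated distributions", {
  set.seed(16)
  p <- 1.3; q <- 0.7
  s <- laplace_sample(1e5, p, q, "two_uniform")
  expect_lt(abs(mean(s) - p), 0.05 * q)
  expect_lt(abs(stats::var(s) - 2 * q^2) / (2 * q^2), 0.05)

  # single-uniform variant has an empty support band [p, p + q*log 2)
  sp <- laplace_sample(1e5, p, q, "as_printed")
  expect_equal(sum(sp >= p & sp < p + q * log(2)), 0L)
  expect_error(laplace_sample(10, 0, -1), "q must be")
})

test_that("laplace crossover preserves parent geometry", {
  set.seed(17)
  x1 <- rnorm(6); x2 <- rnorm(6)
  off <- laplace_crossover(x1, x2, 0, 0.5)
  expect_equal(off$y1 - off$y2, x1 - x2)
  same <- laplace_crossover(x1, x1, 0, 0.5)
  expect_equal(same$y1, x1)
  expect_equal(same$y2, x1)
  expect_error(laplace_crossover(x1, x2[1:3], 0, 0.5), "equal length")
})

test_that("elite opposition is greedy and sized by ceiling(fraction * N)", {
  set.seed(18)
  d <- 4L
  sphere <- function(mask) sum(mask) / length(mask)  # fewer bits better
  eval_fn <- eiaoselect:::.make_eval(sphere, "fixed_half")
  X <- matrix(runif(20 * d, -4, 4), 20, d)
  masks <- matrix(FALSE, 20, d); fit <- numeric(20); err <- numeric(20)
  for (i in 1:20) {
    ev <- eval_fn(X[i, ]); masks[i, ] <- ev$mask; fit[i] <- ev$fitness
  }
  st <- eiaoselect:::elite_opposition_step(X, fit, masks, err, eval_fn,
                                           0.1, rep(-4, d), rep(4, d))
  elite <- order(fit)[1:2]  # ceiling(0.1 * 20) = 2
  expect_true(all(st$fit[elite] <= fit[elite]))
  untouched <- setdiff(1:20, elite)
  expect_equal(st$X[untouched, ], X[untouched, ])
})
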