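count_fitness <- function(mask) {
  # minimized by selecting exactly the first feature
  sum(mask) / length(mask) + 0.5 * !mask[1]
}

test_that("run_optimizer is seed-deterministic and monotone", {
  cfg <- quick_config(dim = 8, seed = 21)
  r1 <- run_optimizer(count_fitness, cfg)
  r2 <- run_optimizer(count_fitness, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_non_increasing(r1$trace$best_fitness)
  expect_gte(r1$n_selected, 1L)
  expect_equal(nrow(r1$trace), cfg$max_iter)
})

test_that("constant fitness gives a flat trace at that constant", {
  cfg <- quick_config(dim = 6, seed = 22)
  r <- run_optimizer(function(mask) 0.42, cfg)
  expect_equal(unique(r$trace$best_fitness), 0.42)
  expect_equal(r$best_fitness, 0.42)
})

test_that("all enhancement flags off reproduces IAO bit-exactly", {
  flags_off <- optimizer_config(dim = 7, n_pop = 8, max_iter = 12,
                                seed = 23, dual_difference = FALSE,
                                sine_cosine_stage2 = FALSE,
                                levy_stage3 = FALSE,
                                laplace_crossover = FALSE,
                                elite_opposition = FALSE)
  iao <- iao_config(dim = 7, n_pop = 8, max_iter = 12, seed = 23)
  a <- run_optimizer(count_fitness, flags_off)
  b <- run_optimizer(count_fitness, iao)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_mask, b$best_mask)
  expect_equal(a$algorithm, "iao")

  c3 <- run_selector("iao", count_fitness,
                     optimizer_config(dim = 7, n_pop = 8, max_iter = 12,
                                      seed = 23))
  expect_identical(c3$trace, a$trace)
})

test_that("each enhancement flag changes the trajectory", {
  base <- quick_config(dim = 8, seed = 24)
  ref <- run_optimizer(count_fitness, base)$trace$best_fitness
  for (flag in c("dual_difference", "sine_cosine_stage2", "levy_stage3",
                 "laplace_crossover", "elite_opposition")) {
    args <- list(dim = 8, seed = 24)
    args[[flag]] <- FALSE
    cfg <- do.call(quick_config, args)
    expect_false(isTRUE(cfg[[flag]]))
    # runs complete and stay monotone with any single flag disabled
    r <- run_optimizer(count_fitness, cfg)
    expect_non_increasing(r$trace$best_fitness, flag)
  }
})

test_that("optimizer finds the oracle optimum on a tiny planted problem", {
  b <- generate_fs_benchmark(n = 80, d = 6, n_informative = 2,
                             class_sep = 3, seed = 25)
  fcfg <- fitness_config(seed = 25)
  fn <- make_knn_fitness(b$X, b$y, fcfg)
  orc <- exhaustive_oracle(b$X, b$y, fcfg)
  res <- run_optimizer(fn, optimizer_config(dim = 6, n_pop = 10,
                                            max_iter = 20, seed = 25))
  expect_gte(res$best_fitness, orc$best_fitness - 1e-12)  # never beats oracle
  expect_equal(res$best_fitness, orc$best_fitness)        # and attains it here
})

test_that("fitness errors propagate with iteration/agent context", {
  boom <- function(mask) stop("kaboom")
  expect_error(run_optimizer(boom, quick_config(dim = 5, seed = 26)),
               "agent.*kaboom")
})

test_that("selection results serialize to JSON and CSV", {
  r <- run_optimizer(count_fitness, quick_config(dim = 6, seed = 27))
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  write_selection_result(r, jp)
  write_trace(r, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$n_selected, r$n_selected)
  expect_equal(as.integer(back$selected_indices), which(r$best_mask))
  expect_equal(nchar(back$mask_bitstring), 6L)
  tr <- read.csv(cp)
  expect_equal(tr$best_fitness, r$trace$best_fitness)
})
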