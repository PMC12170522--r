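# Small in-code fixtures shared across test files.

# tiny labeled spectra table written to a temp CSV
write_tiny_spectra_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("400,500,600,label",
               "0.1,0.2,0.3,a",
               "0.2,0.3,0.4,a",
               "0.5,0.4,0.2,b"), path)
  path
}

# two well-separated Gaussian classes in few dimensions
separable_data <- function(n_per_class = 20, d = 3, gap = 8, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d, 0, 0.5), n_per_class),
             matrix(rnorm(n_per_class * d, gap, 0.5), n_per_class))
  list(X = X, y = factor(rep(c("lo", "hi"), each = n_per_class)))
}

# small optimizer config for fast runs
quick_config <- function(dim, seed = 1L, ...) {
  optimizer_config(dim = dim, n_pop = 8L, max_iter = 10L, seed = seed, ...)
}

expect_non_increasing <- function(x, label = "trace") {
  expect_true(all(diff(x) <= 1e-12),
              label = paste(label, "is non-increasing"))
}
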