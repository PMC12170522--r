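Package: eiaoselect
Title: Enhanced Information Acquisition Optimization for Hyperspectral
    Wavelength Selection
Version: 0.1.0
Authors@R:
    person("eiaoselect", "authors", email = "dev@example.org", role = c("aut", "cre"))
Description: Binary metaheuristic wavelength selection for hyperspectral
    chemometrics. Implements the Enhanced Information Acquisition
    Optimization (EIAO) algorithm with chaotic logistic initialization,
    elite opposition-based learning, sine-cosine stage updates, Levy
    flight, and Laplace crossover, together with the plain IAO ablation
    and binary PSO / binary SCA comparators. A KNN wrapper fitness scores
    candidate band subsets as a weighted sum of classifier error and
    subset size. Includes spectral preprocessing (multiplicative scatter
    correction, standard normal variate, Savitzky-Golay smoothing), an
    evaluation harness with extreme learning machine, random forest and
    RBF support vector machine classifiers, a synthetic seed-spectra
    generator with planted discriminative bands, an exhaustive-search
    oracle for small problems, and a command-line interface for
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    quadprog,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
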