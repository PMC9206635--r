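# The model-agnostic evaluation suite, checked against stubs with known
# answers and brute-force oracles.

# stub generative model: items are numerics; reconstruction adds a known
# per-item shift, encoding is the identity on a stored latent table
make_shift_stub <- function(env = parent.frame()) {
  stub_method("reconstruct_item", "shift_stub",
              function(model, x, ...) x + attr(x, "shift"), env = env)
  structure(list(), class = "shift_stub")
}

test_that("generalization ability is the mean reconstruction distance", {
  stub <- make_shift_stub()
  items <- lapply(c(10, 20, 30), function(v) {
    structure(v, shift = v / 10)
  })
  expect_equal(generalization_ability(stub, items, function(a, b) abs(a - b)), 2)
  id <- structure(list(), class = "shift_stub")
  items0 <- lapply(items, function(x) { attr(x, "shift") <- 0; x })
  expect_equal(generalization_ability(id, items0, function(a, b) abs(a - b)), 0)
  expect_error(generalization_ability(stub, list(), abs), "empty")
})

test_that("specificity takes the min over real items, 0 for a replayer", {
  stub_method("sample_items", "fixed_sampler",
              function(model, n, latent_stats = NULL, seed = 1, ...) {
                model$samples[seq_len(n)]
              })
  gen <- structure(list(samples = list(5)), class = "fixed_sampler")
  real <- list(8, 4, 7) # distances 3, 1, 2
  expect_equal(specificity(gen, real, n_samples = 1,
                           dist = function(a, b) abs(a - b)), 1)
  replayer <- structure(list(samples = real), class = "fixed_sampler")
  expect_identical(specificity(replayer, real, dist = function(a, b) abs(a - b)), 0)
  # brute-force double loop on random stub distances
  withr::with_seed(31, {
    real_r <- as.list(runif(7, 0, 10))
    samp_r <- as.list(runif(5, 0, 10))
    gen_r <- structure(list(samples = samp_r), class = "fixed_sampler")
    got <- specificity(gen_r, real_r, n_samples = 5,
                       dist = function(a, b) abs(a - b))
    want <- mean(vapply(samp_r, function(s) {
      min(vapply(real_r, function(r) abs(r - s), numeric(1)))
    }, numeric(1)))
    expect_equal(got, want)
    # adding a far outlier sample never decreases specificity
    gen_out <- structure(list(samples = c(samp_r, 1e6)), class = "fixed_sampler")
    expect_gte(specificity(gen_out, real_r, n_samples = 6,
                           dist = function(a, b) abs(a - b)), got)
  })
  expect_error(specificity(gen, list(), dist = abs), "empty")
})

test_that("ks_statistic equals the brute-force ECDF supremum", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(5, 6)), 1)
  withr::with_seed(32, {
    for (rep in 1:100) {
      a <- sample(0:20, sample(2:25, 1), replace = TRUE) + round(runif(1), 2)
      b <- c(sample(0:20, sample(2:25, 1), replace = TRUE),
             if (runif(1) < 0.5) a[1]) # occasional ties across samples
      expect_identical(ks_statistic(a, b), oracle_ks(a, b))
    }
    # cross-check against the field-standard implementation
    a <- rnorm(40); b <- rnorm(35, mean = 0.4)
    expect_equal(ks_statistic(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
  })
})

test_that("DSI matches a hand-enumerated 3 + 3 example and orders configurations", {
  real <- list(0, 1, 2)
  synth <- list(10, 11, 12)
  adist <- function(a, b) abs(a - b)
  d_r <- c(1, 2, 1)          # pairs (0,1) (0,2) (1,2)
  d_s <- c(1, 2, 1)
  d_rs <- c(10, 11, 12, 9, 10, 11, 8, 9, 10) # all 9 cross pairs
  want <- (oracle_ks(d_r, d_rs) + oracle_ks(d_s, d_rs)) / 2
  expect_equal(likeness_dsi(real, synth, adist), want)
  expect_equal(want, 1) # fully separated classes
  near <- likeness_dsi(real, list(0.1, 1.1, 2.2), adist)
  expect_lte(near, likeness_dsi(real, synth, adist))
  expect_gte(near, 0)
  same <- likeness_dsi(real, real, adist)
  expect_lte(same, near + 1e-12)
  expect_error(likeness_dsi(real, list(1), adist))
})

test_that("DSI subsamples pairs deterministically for large sets", {
  withr::with_seed(33, items <- as.list(rnorm(250)))
  d1 <- likeness_dsi(items, lapply(items, function(x) x + 0.05),
                     function(a, b) abs(a - b))
  d2 <- likeness_dsi(items, lapply(items, function(x) x + 0.05),
                     function(a, b) abs(a - b))
  expect_identical(d1, d2)
  expect_true(d1 >= 0 && d1 <= 1)
})

test_that("normality fraction is calibrated on known distributions", {
  withr::with_seed(34, {
    gauss <- matrix(rnorm(500 * 40), 500, 40)
    frac <- normality_fraction(gauss, alpha = 0.05)
    expect_gte(frac, 0)
    expect_lte(frac, 15) # binomial band around the 5% level
    two_point <- matrix(sample(c(0, 10), 500 * 5, replace = TRUE), 500, 5)
    expect_equal(as.numeric(normality_fraction(two_point)), 100)
    logn <- matrix(exp(rnorm(500)), 500, 1)
    expect_equal(as.numeric(normality_fraction(logn)), 100)
  })
  expect_warning(f <- normality_fraction(cbind(rnorm(100), rep(1, 100))),
                 "constant")
  expect_equal(as.numeric(f), 50)
  expect_error(normality_fraction(matrix(rnorm(10), 5, 2)), "at least 8")
})

test_that("latent ambiguity score follows its definition", {
  # stub with hand-set encodings: f(r_i) from a table, f(g(f(r_i))) shifted
  enc_tab <- list("1" = c(0, 0), "2" = c(3, 0), "3" = c(0, 4),
                  "r1" = c(1, 0), "r2" = c(3, 0), "r3" = c(0, 3))
  stub_method("encode", "las_stub", function(model, x, ...) enc_tab[[x]])
  stub_method("reconstruct_item", "las_stub",
              function(model, x, ...) paste0("r", x))
  stub <- structure(list(), class = "las_stub")
  got <- latent_ambiguity_score(stub, list("1", "2", "3"))
  D <- mean(c(1, 0, 1))
  D_base <- mean(c(3, 4, 5, 3, 5, 4)) # ordered pairs
  expect_equal(got, D / D_base)
  # fixed point f(g(f(x))) = f(x) gives exactly 0
  stub_method("reconstruct_item", "fp_stub", function(model, x, ...) x)
  stub_method("encode", "fp_stub", function(model, x, ...) c(x, 2 * x))
  expect_equal(latent_ambiguity_score(structure(list(), class = "fp_stub"),
                                      list(1, 2, 5)), 0)
  # degenerate: identical encodings
  stub_method("encode", "const_stub", function(model, x, ...) c(1, 1))
  stub_method("reconstruct_item", "const_stub", function(model, x, ...) x)
  expect_error(latent_ambiguity_score(structure(list(), class = "const_stub"),
                                      list(1, 2)), "undefined")
})

test_that("any fitted PCA shape model has LAS 0 (analytic property)", {
  pop <- landmark_population()
  X <- population_shapes(pop, "train")
  ho <- population_shapes(pop, "test")
  items <- lapply(seq_len(nrow(ho)), function(i) ho[i, ])
  for (thr in c(0.9, 0.95, 1)) {
    m <- fit_ssm(X, variability_threshold = thr)
    expect_lt(latent_ambiguity_score(m, items), 1e-8)
  }
  lssm <- fit_lssm(X)
  expect_lt(latent_ambiguity_score(lssm, items), 1e-8)
})

test_that("compactness reports latent dimensionality per family", {
  pop <- landmark_population()
  m <- fit_ssm(population_shapes(pop, "train"))
  expect_equal(compactness(m), m$p)
  net <- build_network(network_spec("ae", c(16, 16), in_channels = 3,
                                    latent_dim = 512, seed = 1))
  expect_equal(compactness(net), 512)
  expect_equal(format_compactness(compactness(net)), "512")
  adae <- build_network(network_spec("adae", c(16, 16), in_channels = 1,
                                     latent_dim = 1024,
                                     appearance_latent_dim = 64,
                                     data_mode = "intensity", seed = 1))
  expect_equal(compactness(adae), c(1024, 64))
  expect_equal(format_compactness(compactness(adae)), "1024+64")
})
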