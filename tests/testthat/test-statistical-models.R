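# PCA shape models, locality-based models, and appearance models.

test_that("fit_ssm finds the rank of tiny training sets", {
  base <- c(0, 0, 1, 0, 1, 1, 0, 1) # unit square, interleaved x/y
  shapes <- rbind(base, base + 0.3)
  m <- fit_ssm(shapes)
  expect_equal(m$p, 1)
  expect_warning(m0 <- fit_ssm(rbind(base, base, base)), "identical")
  expect_equal(m0$p, 0)
  expect_error(fit_ssm(list(base, base[1:6])), "inconsistent")
})

test_that("projection and reconstruction are exact inverses on the subspace", {
  pop <- landmark_population()
  X <- population_shapes(pop, "train")
  m <- fit_ssm(X, variability_threshold = 1)
  expect_equal(project(m, reconstruct(m, numeric(m$p)) + 0), numeric(m$p),
               tolerance = 1e-8)
  expect_lt(max(abs(project(m, m$mean))), 1e-8)
  # full-rank reconstruction of training shapes
  recon <- reconstruct(m, project(m, X))
  expect_lt(max(abs(recon - X)), 1e-8)
  # project(reconstruct(z)) = z by orthonormality
  withr::with_seed(2, z <- rnorm(m$p))
  expect_equal(project(m, reconstruct(m, z)), z, tolerance = 1e-10)
  expect_error(project(m, X[1, 1:10]), "mismatch")
  expect_error(reconstruct(m, numeric(m$p + 1)), "mismatch")
})

test_that("PCA recovers the ground-truth mode subspace (parameter recovery)", {
  tpl <- thorax_template()
  basis <- build_deformation_basis(tpl, k = 2, seed = 12)
  pop <- sample_population(tpl, basis, n = 60, seed = 12,
                           representations = "landmarks")
  m <- fit_ssm(population_shapes(pop))
  expect_equal(m$p, 2)
  td <- tidy(m)
  expect_gte(td$cumulative[2], 0.99)
  # principal angles between fitted and true landmark-mode spans
  pts <- as.matrix(tpl$landmarks[, c("x", "y")])
  true_modes <- vapply(basis$modes, function(mode) {
    as.vector(t(shapearena:::interp_field(mode, pts)))
  }, numeric(2 * nrow(pts)))
  Qa <- qr.Q(qr(true_modes))
  cosines <- svd(crossprod(Qa, m$basis))$d
  angles <- acos(pmin(cosines, 1)) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("latent-statistics sampling behaves like the fitted Normal", {
  pop <- landmark_population()
  m <- fit_ssm(population_shapes(pop, "train"))
  fixed <- sample_ssm(m, 5, latent_stats = list(mean = m$latent_mean,
                                                sd = rep(0, m$p)), seed = 1)
  expect_equal(fixed[1, ], fixed[5, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fixed[1, ], as.numeric(reconstruct(m, m$latent_mean)),
               tolerance = 1e-12, ignore_attr = TRUE)
  s1 <- sample_ssm(m, 10, seed = 7)
  expect_identical(s1, sample_ssm(m, 10, seed = 7))
  # CLT bound on the latent sample mean over 5000 draws
  big <- sample_ssm(m, 5000, seed = 8)
  Z <- project(m, big)
  for (j in seq_len(m$p)) {
    expect_lt(abs(mean(Z[, j]) - m$latent_mean[j]),
              3 * m$latent_sd[j] / sqrt(5000) + 1e-9)
  }
  expect_error(sample_ssm(m, 0), "positive")
})

test_that("LSSM with no attenuation reduces exactly to the plain SSM", {
  pop <- landmark_population()
  X <- population_shapes(pop, "train")
  ssm <- fit_ssm(X)
  lssm <- fit_lssm(X, locality_schedule(1e9, taper = function(r) rep(1, length(r))))
  expect_equal(lssm$p, ssm$p)
  expect_equal(lssm$mode_variances, ssm$mode_variances, tolerance = 1e-6)
  # same subspace: projections of the data agree up to sign flips
  Za <- project(ssm, X); Zb <- project(lssm, X)
  for (j in seq_len(ssm$p)) {
    expect_equal(abs(stats::cor(Za[, j], Zb[, j])), 1, tolerance = 1e-6)
  }
  recon <- reconstruct(lssm, project(lssm, X))
  expect_equal(max(abs(recon - reconstruct(ssm, project(ssm, X)))), 0,
               tolerance = 1e-6)
})

test_that("covariance tapering matches the hand-computed attenuation", {
  # 3 landmarks in 2D on a toy covariance
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  withr::with_seed(4, {
    A <- matrix(rnorm(36), 6)
    C <- crossprod(A) / 6
  })
  D <- as.matrix(dist(pts))
  radius <- 2.5
  got <- shapearena:::tapered_covariance(C, D, radius, wendland_taper, d = 2)
  for (i in 1:6) for (j in 1:6) {
    li <- ceiling(i / 2); lj <- ceiling(j / 2)
    expect_equal(got[i, j], C[i, j] * wendland_taper(D[li, lj] / radius),
                 tolerance = 1e-12)
  }
  # radius -> 0: only within-landmark blocks survive
  tiny <- shapearena:::tapered_covariance(C, D, 1e-9, wendland_taper, d = 2)
  for (i in 1:6) for (j in 1:6) {
    if (ceiling(i / 2) != ceiling(j / 2)) expect_equal(tiny[i, j], 0)
    else expect_equal(tiny[i, j], C[i, j])
  }
})

test_that("locality schedules are validated and add flexibility", {
  expect_error(locality_schedule(c(1, 2)), "decreasing")
  expect_error(locality_schedule(10, taper = function(r) 0 * r), "taper")
  pop <- landmark_population()
  X <- population_shapes(pop)[1:8, , drop = FALSE]
  attr(X, "layout") <- attr(population_shapes(pop), "layout")
  attr(X, "d") <- 2
  ssm <- fit_ssm(X)
  lssm <- fit_lssm(X)
  expect_gte(lssm$p, ssm$p) # compactness(SSM) <= compactness(LSSM)
  expect_gte(compactness(lssm), compactness(ssm))
  U <- lssm$basis
  expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), 1e-8)
  expect_warning(fb <- fit_lssm(X, locality_schedule(numeric(0))), "empty")
  expect_equal(fb$p, ssm$p)
})

test_that("SSM generalizes below rasterization tolerance once N > k + 1", {
  tpl <- thorax_template()
  basis <- thorax_basis() # k = 3
  pop <- sample_population(tpl, basis, n = 30, seed = 14,
                           representations = "landmarks")
  m <- fit_ssm(population_shapes(pop, "train")) # N = 18 > 4
  ho <- population_shapes(pop, "test")
  for (i in seq_len(nrow(ho))) {
    a <- landmarks_to_label(landmarks_unflatten(ho[i, ], attr(ho, "layout")),
                            tpl$grid_shape, tpl$structure_order)
    r <- reconstruct(m, project(m, ho[i, ]))
    b <- landmarks_to_label(landmarks_unflatten(as.numeric(r), attr(ho, "layout")),
                            tpl$grid_shape, tpl$structure_order)
    expect_lt(assd(a, b), 1)
  }
})

test_that("locality helps generalization from small samples of local variation", {
  tpl <- thorax_template()
  local_basis <- build_deformation_basis(tpl, k = 6, smoothness = 3,
                                         amplitudes = rep(1.2, 6), seed = 21)
  pop <- sample_population(tpl, local_basis, n = 40, seed = 21,
                           representations = "landmarks")
  X <- population_shapes(pop)
  layout <- attr(X, "layout")
  ga_of <- function(model) {
    ho <- X[31:40, , drop = FALSE]
    mean(vapply(seq_len(nrow(ho)), function(i) {
      r <- reconstruct(model, project(model, ho[i, ]))
      sqrt(mean((r - ho[i, ])^2))
    }, numeric(1)))
  }
  tr <- X[1:5, , drop = FALSE]
  attr(tr, "layout") <- layout; attr(tr, "d") <- 2
  expect_lte(ga_of(fit_lssm(tr)), ga_of(fit_ssm(tr)) + 1e-9)
})

test_that("SAM degenerates gracefully and reconstructs training data", {
  tpl2 <- build_template("brain-like", c(32, 32), seed = 5)
  basis2 <- build_deformation_basis(tpl2, k = 2, seed = 5,
                                    amplitudes = c(1.5, 1))
  pop <- sample_population(tpl2, basis2, n = 10, seed = 5, offset_scale = 0.05)
  X <- population_shapes(pop, "train")
  apps <- population_appearances(pop, "train")
  # identical shapes & appearances: appearance p = 0, reconstruction = input
  same <- X[rep(1, 3), , drop = FALSE]
  attr(same, "layout") <- attr(X, "layout"); attr(same, "d") <- 2
  suppressWarnings(m0 <- fit_sam(same, apps[c(1, 1, 1)]))
  expect_equal(m0$intensity_model$p, 0)
  r0 <- reconstruct_sam(m0, same[1, ], apps[[1]])
  expect_lt(mean(abs(r0$appearance - apps[[1]])), 0.02)
  expect_equal(dim(r0$appearance), dim(apps[[1]]))
  # full-rank SAM: shape-normalized reconstruction error below warp tolerance
  m <- fit_sam(X, apps, variability_threshold = 1)
  r <- reconstruct_sam(m, X[2, ], apps[[2]])
  expect_lt(mean(abs(r$appearance - apps[[2]])), 0.05)
  s <- sample_sam(m, 2, seed = 3)
  expect_equal(dim(s[[1]]$appearance), tpl2$grid_shape)
  expect_identical(sample_sam(m, 2, seed = 3), s)
})

test_that("tidy and glance summarise fitted shape models", {
  pop <- landmark_population()
  m <- fit_ssm(population_shapes(pop, "train"))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), m$p)
  expect_true(all(diff(td$variance) <= 1e-12))
  gl <- glance(m)
  expect_equal(gl$p, m$p)
  expect_equal(gl$n_train, 48)
})
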