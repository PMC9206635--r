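# Network generative models: architecture, losses, gradients, training
# behaviour and the shared generative contract.

tiny_labels <- function(n = 6, gs = c(16, 16), L = 2, seed = 41) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) random_label_image(gs, L)))
}

tiny_intensities <- function(n = 6, gs = c(16, 16), seed = 42) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    pmin(pmax(smooth_gaussian(array(runif(prod(gs)), gs), 1.5), 0), 1)
  }))
}

test_that("network architecture follows the shared fixed layout", {
  spec <- network_spec("ae", c(64, 64), in_channels = 6, latent_dim = 32, seed = 1)
  m <- build_network(spec)
  convs <- Filter(function(l) l$type == "conv", m$enc)
  expect_equal(vapply(convs, `[[`, numeric(1), "cout"), c(20, 40, 80))
  dconvs <- Filter(function(l) l$type == "conv", m$dec)
  expect_equal(vapply(dconvs, `[[`, numeric(1), "cout"), c(40, 20, 6))
  # VAE differs from the AE only by the second latent head
  mv <- build_network(network_spec("vae", c(64, 64), in_channels = 6,
                                   latent_dim = 32, seed = 1))
  expect_equal(n_parameters(mv) - n_parameters(m), (prod(c(8, 8)) * 80 + 1) * 32)
  # DAE decoder emits one displacement channel per spatial dimension
  md <- build_network(network_spec("dae", c(64, 64), in_channels = 6,
                                   latent_dim = 32, seed = 1))
  dlast <- Filter(function(l) l$type == "conv", md$dec)
  expect_equal(dlast[[length(dlast)]]$cout, 2)
  expect_error(build_network(network_spec("ae", c(60, 64), in_channels = 6)),
               "divisible by 8")
  expect_error(network_spec("adae", c(16, 16), in_channels = 3,
                            data_mode = "label"), "intensities")
})

test_that("generalized Dice loss follows its closed form and oracle", {
  lab <- tiny_labels(1)[[1]]
  oh <- label_to_onehot(lab, 2)
  expect_lt(generalized_dice_loss(oh, oh), 1e-6)
  a <- array(0, c(4, 4, 2)); a[, , 1][1:8] <- 1; a[, , 2] <- 1 - a[, , 1]
  b <- array(0, c(4, 4, 2)); b[, , 1] <- 1 - a[, , 1]; b[, , 2] <- a[, , 1]
  expect_equal(generalized_dice_loss(a, b), 1)
  withr::with_seed(43, {
    for (rep in 1:20) {
      soft <- array(runif(6 * 6 * 3), c(6, 6, 3))
      norm <- array(apply(soft, c(1, 2), sum), c(6, 6))
      for (ch in 1:3) soft[, , ch] <- soft[, , ch] / norm
      target <- label_to_onehot(random_label_image(c(6, 6), 2), 2)
      expect_equal(generalized_dice_loss(soft, target),
                   oracle_gdl(soft, target), tolerance = 1e-12)
    }
  })
  expect_error(generalized_dice_loss(a, b, weights = c(0, 0)), "zero")
})

test_that("SSIM, KL and adversarial losses match their closed forms", {
  x <- tiny_intensities(1)[[1]]
  expect_lt(ssim_loss(x, x), 1e-6)
  y <- tiny_intensities(1, seed = 99)[[1]]
  expect_gt(ssim_loss(x, y), 0.01)
  expect_error(ssim_loss(x, array(NA_real_, dim(x))), "finite")
  expect_equal(kl_loss(0, 0), 0)
  expect_equal(kl_loss(1, 0), 0.5)
  expect_equal(kl_loss(matrix(c(1, 1), 2, 1), matrix(0, 2, 1)), 0.5)
  adv <- adversarial_losses(c(0, 0), c(0, 0))
  expect_equal(adv$gen_term, log(2), tolerance = 1e-12)
  expect_equal(adv$disc_term, log(2), tolerance = 1e-12)
  strong <- adversarial_losses(c(10, 10), c(-10, -10))
  expect_lt(strong$disc_term, 1e-3)
  expect_gt(strong$gen_term, 5)
  expect_error(adversarial_losses(c(1, Inf), 0), "finite")
})

test_that("displacement regularizer equals diffusion + L1 with weight 10", {
  zero <- array(0, c(8, 8, 2))
  expect_equal(displacement_regularizer(zero), 0)
  const <- array(0.7, c(8, 8, 2))
  expect_equal(displacement_regularizer(const), 10 * 0.7 * 2)
  withr::with_seed(44, {
    f <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    expect_equal(displacement_regularizer(f), oracle_displacement_reg(f),
                 tolerance = 1e-12)
  })
})

test_that("backpropagated gradients match finite differences", {
  labs <- tiny_labels(2)
  ints <- tiny_intensities(2)
  check_kind <- function(kind, data_mode, items, n_probe = 3) {
    spec <- network_spec(kind, c(16, 16),
                         in_channels = if (data_mode == "label") 3 else 1,
                         latent_dim = 4, appearance_latent_dim = 3,
                         data_mode = data_mode, seed = 7)
    m <- build_network(spec)
    mats <- lapply(items, function(x) shapearena:::item_to_mat(m, x))
    if (kind %in% c("dae", "adae")) {
      avg <- Reduce(`+`, mats) / length(mats)
      if (data_mode == "label") {
        hard <- max.col(t(avg), ties.method = "first")
        tm <- matrix(0, nrow(avg), m$nvox)
        tm[cbind(hard, seq_len(m$nvox))] <- 1
        m$template_mat <- tm
      } else {
        m$template_mat <- avg
      }
    }
    X <- do.call(cbind, mats)
    B <- length(mats)
    # the discriminator is trained on its own objective; all other parts on
    # the generator loss
    loss_at <- function(part) {
      st <- withr::with_seed(123, shapearena:::network_step(m, X, B))
      if (part == "disc") st$parts[["disc"]] else st$loss
    }
    st <- withr::with_seed(123, shapearena:::network_step(m, X, B))
    worst <- 0
    withr::with_seed(50 + nchar(kind), {
      for (part in names(st$grads)) {
        for (li in seq_along(st$grads[[part]])) {
          gl <- st$grads[[part]][[li]]
          if (length(gl) == 0) next
          nm <- names(gl)[1] # weight matrix of this layer
          pv <- m[[part]][[li]]$params[[nm]]
          for (i in sample(length(pv), min(n_probe, length(pv)))) {
            eps <- 1e-5
            m[[part]][[li]]$params[[nm]][i] <- pv[i] + eps
            lp <- loss_at(part)
            m[[part]][[li]]$params[[nm]][i] <- pv[i] - eps
            lm <- loss_at(part)
            m[[part]][[li]]$params[[nm]][i] <- pv[i]
            num <- (lp - lm) / (2 * eps)
            worst <- max(worst, abs(num - gl[[nm]][i]) /
                           max(1e-6, abs(num), abs(gl[[nm]][i])))
          }
        }
      }
    })
    expect_lt(worst, 5e-3)
  }
  check_kind("ae", "label", labs)      # conv/dense/softmax + Dice path
  check_kind("vae", "label", labs)     # reparameterization + KL head
  check_kind("aegan", "label", labs)   # adversarial generator/discriminator
  check_kind("dae", "label", labs)     # template warp + regularizer
  check_kind("adae", "intensity", ints) # split latent, offset, SSIM path
})

test_that("training runs, records history, aborts on divergence, is seeded", {
  labs <- tiny_labels(4)
  spec <- network_spec("ae", c(16, 16), in_channels = 3, latent_dim = 4, seed = 2)
  m1 <- train(build_network(spec), labs, train_config(epochs = 1, seed = 5))
  expect_length(m1$loss_history, 1)
  expect_true(is.finite(m1$loss_history))
  expect_true(m1$trained)
  m2 <- train(build_network(spec), labs, train_config(epochs = 3, seed = 5))
  m3 <- train(build_network(spec), labs, train_config(epochs = 3, seed = 5))
  expect_identical(m2$loss_history, m3$loss_history)
  expect_error(train(build_network(spec), list()), "empty")
  poisoned <- build_network(spec)
  poisoned$enc[[1]]$params$W[1] <- NaN
  expect_error(train(poisoned, labs, train_config(epochs = 1)), "loss")
})

test_that("an AE can memorize a single repeated shape", {
  lab <- tiny_labels(1)[[1]]
  spec <- network_spec("ae", c(16, 16), in_channels = 3, latent_dim = 8, seed = 3)
  m <- train(build_network(spec), rep(list(lab), 4),
             train_config(epochs = 200, seed = 3))
  recon <- reconstruct_item(m, lab)
  expect_lt(generalized_dice_loss(label_to_onehot(recon, 2),
                                  label_to_onehot(lab, 2)), 0.1)
  expect_length(encode(m, lab), 8)
})

test_that("sampling is seeded and degenerate stats collapse to one image", {
  labs <- tiny_labels(5)
  spec <- network_spec("vae", c(16, 16), in_channels = 3, latent_dim = 4, seed = 4)
  m <- train(build_network(spec), labs, train_config(epochs = 5, seed = 4))
  s1 <- sample_items(m, 3, seed = 11)
  expect_identical(s1, sample_items(m, 3, seed = 11))
  sd0 <- sample_items(m, 3, latent_stats = list(mean = m$latent_stats$mean,
                                                sd = rep(0, 4)), seed = 12)
  expect_identical(sd0[[1]], sd0[[3]])
  expect_error(sample_items(build_network(spec), 2), "untrained")
})

test_that("a DAE with zero decoder output reproduces its template", {
  labs <- tiny_labels(5)
  spec <- network_spec("dae", c(16, 16), in_channels = 3, latent_dim = 4, seed = 6)
  m <- train(build_network(spec), labs, train_config(epochs = 1, seed = 6))
  last <- length(m$dec)
  m$dec[[last]]$params$W[] <- 0
  m$dec[[last]]$params$b[] <- 0
  recon <- reconstruct_item(m, labs[[1]])
  expect_identical(recon, m$template_label)
  expect_equal(dim(recon), dim(labs[[1]]))
})

test_that("template-deformation models never drop structures the template has", {
  pop <- thorax_population()
  labs <- population_labels(pop, "train")
  spec <- network_spec("dae", c(64, 64), in_channels = 6, latent_dim = 8, seed = 8)
  m <- train(build_network(spec), labs, train_config(epochs = 8, seed = 8))
  expect_equal(missing_structures(m$template_label, 1:5), 0)
  for (s in sample_items(m, 6, seed = 9)) {
    expect_equal(missing_structures(s, 1:5), 0)
  }
})

test_that("all five kinds satisfy the generative contract through the metrics", {
  labs <- tiny_labels(6)
  ints <- tiny_intensities(6)
  for (kind in c("ae", "vae", "aegan", "dae", "adae")) {
    mode <- if (kind == "adae") "intensity" else "label"
    items <- if (mode == "label") labs else ints
    spec <- network_spec(kind, c(16, 16),
                         in_channels = if (mode == "label") 3 else 1,
                         latent_dim = 4, appearance_latent_dim = 3,
                         data_mode = mode, seed = 10)
    m <- train(build_network(spec), items[1:4], train_config(epochs = 2, seed = 10))
    dist <- if (mode == "label") {
      function(a, b) suppressWarnings(assd(a, b, structures = 1:2))
    } else {
      l1_distance
    }
    ga <- generalization_ability(m, items[5:6], dist)
    sp <- specificity(m, items[5:6], n_samples = 2, dist = dist, seed = 1)
    las <- latent_ambiguity_score(m, items[5:6])
    expect_true(is.finite(ga) && ga >= 0)
    expect_true(is.finite(sp) && sp >= 0)
    expect_true(is.finite(las) && las >= 0)
    expect_length(encode(m, items[[1]]),
                  if (kind == "adae") 7 else 4)
  }
})

test_that("VAE latents are at least as normal as AE latents (trend, 3 seeds)", {
  tpl <- build_template("thorax-like", c(32, 32), seed = 2)
  basis <- build_deformation_basis(tpl, k = 3, seed = 2)
  pop <- sample_population(tpl, basis, n = 110, seed = 2,
                           split_fractions = c(10 / 11, 0, 1 / 11),
                           representations = c("landmarks", "label"))
  labs <- population_labels(pop, "train")
  frac <- function(kind, seed) {
    spec <- network_spec(kind, c(32, 32), in_channels = 6, latent_dim = 16,
                         seed = seed)
    m <- train(build_network(spec), labs,
               train_config(epochs = 12, seed = seed))
    Z <- do.call(rbind, lapply(labs, function(x) encode(m, x)))
    suppressWarnings(as.numeric(normality_fraction(Z)))
  }
  seeds <- c(101, 202, 303)
  vae <- vapply(seeds, function(s) frac("vae", s), numeric(1))
  ae <- vapply(seeds, function(s) frac("ae", s), numeric(1))
  # trend assertion with a one-dimension margin (100 / latent_dim)
  expect_lte(mean(vae), mean(ae) + 100 / 16)
})
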