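test_that("mish matches its closed form and asymptotes", {
  expect_equal(mish(0), 0)
  expect_equal(mish(1), tanh(log(1 + exp(1))), tolerance = 1e-12)
  expect_equal(mish(1), 0.86509, tolerance = 1e-5)
  expect_gt(mish(20) / 20, 0.999)
  expect_equal(mish(-20), 0, tolerance = 1e-6)
})

test_that("dense-block layer k consumes in_ch + (k-1) * growth channels", {
  cfg <- model_config(n_levels = 3, growth_channels = 8, in_channels = 17)
  m <- build_model(cfg)
  for (k in 1:4) {
    w <- m$params[[paste0("e1_l", k, "_w")]]
    expect_equal(dim(w)[1], 17 + (k - 1) * 8)
    expect_equal(dim(w)[2], 8)
  }
  # deeper blocks consume the 4 * growth block output (doubled by the skip
  # concatenation on the decoder path)
  expect_equal(dim(m$params$e2_l1_w)[1], 32)
  expect_equal(dim(m$params$d1_l1_w)[1], 64)
  expect_gt(n_parameters(m), 0)
})

test_that("forward pass preserves spatial shape with probabilities in (0,1)", {
  m <- build_model(model_config(n_levels = 3, growth_channels = 4,
                                in_channels = 17, seed = 2))
  x <- array(0L, c(16, 16, 16, 17))
  x[8, 8, 8, 3] <- 1L
  h1 <- predict(m, x)
  expect_equal(dim(h1$values), c(16, 16, 16))
  expect_true(all(h1$values > 0 & h1$values < 1))
  # non-pool-divisible shapes are padded internally and cropped back
  x2 <- array(0L, c(13, 10, 11, 17))
  expect_equal(dim(predict(m, x2)$values), c(13, 10, 11))
  # eval-mode determinism
  expect_identical(h1$values, predict(m, x)$values)
  expect_error(predict(m, array(0L, c(8, 8, 8, 5))), "channel")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(9)
  m <- build_model(model_config(n_levels = 2, growth_channels = 2,
                                in_channels = 3, seed = 5))
  s <- list(x = array(rnorm(3 * 6 * 6 * 6), c(3, 6, 6, 6)),
            y = array(rbinom(216, 1, 0.3), c(6, 6, 6)))
  lg <- voxbind:::sample_loss_grad(m, s)
  for (nm in c("e1_l1_w", "e2_l3_w", "d1_l2_w", "head_w", "head_b")) {
    i <- sample(length(m$params[[nm]]), 1)
    eps <- 1e-6
    m2 <- m
    m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    up <- voxbind:::sample_loss_grad(m2, s)$loss
    m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
    dn <- voxbind:::sample_loss_grad(m2, s)$loss
    expect_equal(lg$grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4,
                 label = nm)
  }
})

test_that("binary cross-entropy matches its closed forms", {
  y <- array(rbinom(125, 1, 0.2), c(5, 5, 5))
  # constant 0.5 predictor scores ln 2 regardless of class balance
  expect_equal(bce_loss(array(0.5, dim(y)), y), log(2), tolerance = 1e-12)
  y2 <- array(rbinom(125, 1, 0.9), c(5, 5, 5))
  expect_equal(bce_loss(array(0.5, dim(y2)), y2), log(2), tolerance = 1e-12)
  # perfect prediction collapses to ~0
  expect_lt(bce_loss(array(as.double(y), dim(y)), y), 1e-5)
  # single-voxel hand value
  expect_equal(bce_loss(array(0.9, c(1, 1, 1)), array(1L, c(1, 1, 1))),
               -log(0.9), tolerance = 1e-12)
  expect_error(bce_loss(array(0.5, c(2, 2, 2)), y), "shapes differ")
})

test_that("initial loss sits near the uninformative baseline", {
  m <- build_model(model_config(n_levels = 3, growth_channels = 4, seed = 31))
  task <- generate_planted_task(seed = 3, n_samples = 2)
  s <- voxbind:::as_sample_cf(task[[1]])
  loss <- voxbind:::sample_loss_grad(m, s)$loss
  expect_equal(loss, log(2), tolerance = 0.2)
})

test_that("the 9:1 split keeps complexes together and routes oversized ones", {
  ids <- sprintf("c%03d", 1:100)
  sp <- split_dataset(ids, seed = 4)
  expect_length(sp$train, 90)
  expect_length(sp$val, 10)
  expect_length(intersect(sp$train, sp$val), 0)
  # identical under the same seed
  expect_identical(split_dataset(ids, seed = 4), sp)
  # oversized complex forced into validation
  gv <- stats::setNames(rep(1000, 100), ids)
  gv["c050"] <- 1e9
  sp2 <- split_dataset(ids, grid_voxels = gv, max_grid_voxels = 1e6, seed = 4)
  expect_true("c050" %in% sp2$val)
  expect_length(sp2$val, 10)
  expect_error(split_dataset("only_one"), "at least 2")
})

test_that("a short training run reduces validation loss from its baseline", {
  task <- generate_planted_task(seed = 19, n_samples = 10,
                                grid_shape = c(8, 8, 8))
  m <- build_model(model_config(n_levels = 2, growth_channels = 4, seed = 3))
  fit <- train_model(m, task[1:8], task[9:10],
                     train_config(steps = 40, log_every = 10, seed = 3))
  expect_equal(nrow(fit$history), 4)
  expect_true(all(diff(fit$history$step) > 0))
  expect_lt(min(fit$history$val_bce), log(2))
  expect_error(train_model(m, list(), NULL, train_config()), "empty")
})

test_that("checkpoints restore weights and config exactly", {
  m <- build_model(model_config(n_levels = 2, growth_channels = 2,
                                in_channels = 4, seed = 8))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_equal(m2$config$growth_channels, 2L)
  x <- array(rbinom(4 * 8^3, 1, 0.1), c(8, 8, 8, 4))
  expect_identical(predict(m, x)$values, predict(m2, x)$values)
})

test_that("rotation-averaged prediction is shape-preserving", {
  m <- build_model(model_config(n_levels = 2, growth_channels = 2, seed = 6))
  s <- generate_complex(synth_spec(seed = 37, n_residues = 5, dna_length = 2))
  s <- assign_atom_types(flag_surface(compute_sasa(s)))
  g <- voxelize(s)
  rots <- enumerate_rotations()
  acc <- array(0, dim(g$values)[1:3])
  for (r in rots[c(1, 7, 13)]) {
    hr <- predict(m, rotate_grid(g, r))
    hb <- rotate_grid(structure(list(spec = g$spec, values = hr$values),
                                class = "vb_mask"), t(r))
    acc <- acc + hb$values
  }
  acc <- acc / 3
  expect_equal(dim(acc), dim(g$values)[1:3])
  expect_true(all(acc > 0 & acc < 1))
})
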