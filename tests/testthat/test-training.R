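test_that("segmentation loss matches hand-computed values", {
  # perfect prediction
  m <- array(c(1, 0, 0, 1, 1, 0, 0, 0), c(2, 2, 2))
  expect_lt(seg_loss(m, m), 1e-3)
  # empty reference, empty prediction: Dice-loss term vanishes under
  # the eps-smoothing convention, BCE is ~0
  z <- array(0, c(2, 2, 2))
  expect_lt(seg_loss(z, z), 1e-3)
  # uniform 0.5 on 8 voxels with 4 foreground: BCE = ln 2, soft Dice = 0.5
  p <- array(0.5, c(2, 2, 2))
  r <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  expect_equal(seg_loss(p, r), log(2) + 0.5, tolerance = 1e-5)
  expect_error(seg_loss(array(0.5, c(2, 2, 1)), r), "mismatch")
})

test_that("segmentation loss decomposes as BCE + Dice against a brute force", {
  set.seed(11)
  for (i in 1:20) {
    d <- sample(2:3, 3, replace = TRUE)
    p <- array(runif(prod(d)), d)
    m <- array(runif(prod(d)) > 0.5, d)
    got <- plaseg:::seg_loss_grad(p, m)
    # independent elementwise computation
    pv <- as.numeric(p)
    pc <- pmin(pmax(pv, 1e-7), 1 - 1e-7)
    mv <- as.numeric(m)
    bce <- -mean(mv * log(pc) + (1 - mv) * log(1 - pc))
    dice_soft <- (2 * sum(pv * mv) + 1e-5) / (sum(pv) + sum(mv) + 1e-5)
    expect_equal(got$loss, bce + 1 - dice_soft, tolerance = 1e-12)
    expect_equal(got$bce, bce, tolerance = 1e-12)
    expect_gte(got$loss, 0)
  }
})

test_that("classification loss is clipped cross-entropy", {
  expect_lt(class_loss(c(1, 0, 0), 0L), 1e-6)
  expect_equal(class_loss(rep(1 / 3, 3), 1L), log(3), tolerance = 1e-12)
  expect_equal(class_loss(c(0.7, 0.2, 0.1), 2L), -log(0.1), tolerance = 1e-12)
  expect_error(class_loss(c(0.7, 0.2, 0.1), 3L), "label")
})

test_that("multi-task loss is the beta-weighted sum", {
  expect_equal(multitask_loss(0.2, 0.1, 4), 0.6)
  expect_identical(multitask_loss(0.37, 0, 4), 0.37)
  for (x in c(0, 0.5, 2))
    expect_equal(multitask_loss(x, x, 1), 2 * x)
  # linear in l_seg with slope beta
  for (beta in c(1, 2.5, 4)) {
    l0 <- multitask_loss(0.3, 0.2, beta)
    l1 <- multitask_loss(0.3, 1.2, beta)
    expect_equal(l1 - l0, beta * 1.0, tolerance = 1e-12)
  }
  expect_error(multitask_loss(0.1, 0.1, -1), "beta")
})

test_that("alternating schedule realizes the 1:beta ratio and consumes all batches", {
  expect_equal(alternating_schedule(1, 4, 4), c("C", "S", "S", "S", "S"))
  expect_equal(alternating_schedule(2, 2, 1), c("C", "S", "C", "S"))
  plan <- alternating_schedule(3, 12, 4)
  expect_equal(sum(plan == "C"), 3)
  expect_equal(sum(plan == "S"), 12)
  expect_equal(plan, rep(c("C", rep("S", 4)), 3))
  # leftovers of either task still drain
  plan2 <- alternating_schedule(5, 4, 4)
  expect_equal(sum(plan2 == "C"), 5)
  expect_equal(sum(plan2 == "S"), 4)
  expect_error(alternating_schedule(1, 1, 2.5), "integer")
})

test_that("transfer initialization copies encoder (and head/gate) weights only", {
  set.seed(21)
  cfg <- tiny_config()
  src <- build_encnet(cfg)
  tun <- build_model("tunet", cfg)
  before_dec <- model_state(tun)[["dec1.conv1"]]
  transfer_init(tun, src)
  st_src <- model_state(src)
  st_tgt <- model_state(tun)
  enc_names <- grep("^enc", names(st_src), value = TRUE)
  for (nm in enc_names) expect_identical(st_tgt[[nm]], st_src[[nm]])
  expect_identical(st_tgt[["dec1.conv1"]], before_dec)
  # fresh target differs from source before init, matches after
  tmt <- build_model("tmtunet", cfg)
  expect_false(identical(model_state(tmt)[["enc1.conv1"]],
                         st_src[["enc1.conv1"]]))
  transfer_init(tmt, src)
  st2 <- model_state(tmt)
  for (nm in c(enc_names, "att.convx", "head.lin"))
    expect_identical(st2[[nm]], st_src[[nm]])
  # shape mismatch reports the offending layers
  small <- build_encnet(network_config(n_levels = 3,
                                       features_per_level = c(2, 4, 8),
                                       input_shape = c(16, 16, 16),
                                       attention_level = 2, gn_groups = 2))
  expect_error(transfer_init(build_model("tunet", cfg), small), "enc")
  expect_error(transfer_init(build_unet(cfg), src), "tunet")
})

test_that("augmentation applies one transform to image and mask alike", {
  r <- small_phantom("anterior", seed = 2)
  # flip involution
  expect_identical(flip_axis(flip_axis(r$volume$intensities, "x"), "x"),
                   r$volume$intensities)
  expect_identical(flip_axis(flip_axis(r$volume$intensities, "z"), "z"),
                   r$volume$intensities)
  expect_error(augment_spec(flip_axes = c("x", "y")), "never flipped")
  # zero-range spec reproduces the input
  id_spec <- augment_spec(flip_axes = character(0), translation_range = 0,
                          rotation_range = 0, scaling_range = 0,
                          shearing_range = 0)
  a <- augment(r$volume, r$mask, id_spec, seed = 1)
  expect_equal(a$volume$intensities, r$volume$intensities, tolerance = 1e-12)
  expect_identical(a$mask$voxels, r$mask$voxels)
  # random draws keep the mask binary and roughly volume-preserving
  set.seed(31)
  for (i in 1:5) {
    a <- augment(r$volume, r$mask, augment_spec(), seed = i)
    expect_true(is.logical(a$mask$voxels))
    n0 <- sum(r$mask$voxels)
    expect_lt(abs(sum(a$mask$voxels) - n0) / n0, 0.35)
    expect_identical(a$mask$voxels,
                     augment(r$volume, r$mask, augment_spec(), seed = i)$mask$voxels)
  }
})

test_that("training runs, logs, schedules the lr and reduces the loss", {
  set.seed(41)
  cfg <- tiny_config(shape = c(16L, 16L, 16L), features = c(4L, 8L))
  ds <- lapply(1:6, function(i) {
    r <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                       spacing = c(5, 5, 5),
                                       placenta_class = "anterior",
                                       speckle_sigma = 0.1, seed = i))
    list(volume = r$volume, mask = r$mask, class_label = r$class_label)
  })
  out <- tempfile("trainout")
  tc <- train_config("unet", lr = 2e-3, max_epochs = 6, batch_size = 3,
                     lr_milestones = 5L, seed = 2)
  m <- build_unet(cfg)
  fit <- train(m, ds, tc, out = out)
  expect_equal(nrow(fit$log), 6)
  expect_true(file.exists(fit$checkpoint))
  expect_lt(fit$log$l_seg[6], fit$log$l_seg[1])
  # milestone halves the rate by the configured factor
  expect_equal(fit$log$lr[5], 0.1 * fit$log$lr[4], tolerance = 1e-12)
  expect_equal(fit$log$lr[1], 2e-3)
  unlink(out, recursive = TRUE)
})
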