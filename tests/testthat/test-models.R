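test_that("default config matches the published architecture widths", {
  cfg <- network_config()
  expect_equal(cfg$n_levels, 5L)
  expect_equal(cfg$features, c(16L, 32L, 64L, 128L, 256L))
  expect_equal(cfg$decoder_dropout_rate, 0.2)
  expect_equal(cfg$attention_level, 3L)
  m <- build_unet(cfg)
  expect_equal(vapply(m$enc, function(b) b$conv1$cout, 1L),
               c(16L, 32L, 64L, 128L, 256L))
  expect_error(network_config(input_shape = c(100, 100, 100)), "divisible")
})

test_that("unet forward obeys the shape and range contracts", {
  set.seed(1)
  m <- build_unet(tiny_config())
  x <- array(runif(16^3), c(16, 16, 16))
  o <- model_forward(m, x)
  expect_equal(dim(o$seg_probs), c(16L, 16L, 16L))
  expect_true(all(o$seg_probs >= 0 & o$seg_probs <= 1))
  expect_null(o$class_probs)
  expect_error(model_forward(m, array(0, c(15, 16, 16))), "divisible")
  # deterministic without dropout, stochastic with
  expect_identical(model_forward(m, x)$seg_probs, o$seg_probs)
  set.seed(2)
  o_dp <- model_forward(m, x, training = TRUE)
  expect_false(identical(o_dp$seg_probs, o$seg_probs))
})

test_that("encnet emits normalized class probabilities and an attention map", {
  set.seed(3)
  m <- build_encnet(tiny_config())
  x <- array(runif(16^3), c(16, 16, 16))
  o <- model_forward(m, x)
  expect_null(o$seg_probs)
  expect_length(o$class_probs, 3)
  expect_equal(sum(o$class_probs), 1, tolerance = 1e-5)
  expect_equal(dim(o$attention_map), c(16L, 16L, 16L))
  expect_gte(min(o$attention_map), 0)
  expect_equal(predicted_class(o$class_probs),
               which.max(o$class_probs) - 1L)
})

test_that("mtunet shares one encoder between both tasks", {
  set.seed(4)
  cfg <- tiny_config()
  m <- build_mtunet(cfg)
  x <- array(runif(16^3), c(16, 16, 16))
  o <- model_forward(m, x)
  expect_equal(dim(o$seg_probs), c(16L, 16L, 16L))
  expect_length(o$class_probs, 3)
  expect_equal(dim(o$attention_map), c(16L, 16L, 16L))
  # mutating an encoder weight changes both task outputs (shared, not copied)
  m$enc[[1]]$conv1$params$W <- m$enc[[1]]$conv1$params$W + 0.5
  o2 <- model_forward(m, x)
  expect_false(identical(o2$seg_probs, o$seg_probs))
  expect_false(identical(o2$class_probs, o$class_probs))
  # shared encoder means fewer parameters than two separate networks
  expect_lt(n_parameters(m),
            n_parameters(build_unet(cfg)) + n_parameters(build_encnet(cfg)))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(5)
  cfg <- network_config(n_levels = 3, features_per_level = c(2, 3, 4),
                        input_shape = c(8, 8, 8), attention_level = 2,
                        gn_groups = 1)
  m <- build_mtunet(cfg)
  x <- array(runif(8^3), c(8, 8, 8))
  mask <- array(runif(8^3) > 0.7, c(8, 8, 8))
  label <- 2L
  loss_of <- function() {
    o <- model_forward(m, x)
    plaseg:::class_loss_grad(o$class_probs, label)$loss +
      4 * plaseg:::seg_loss_grad(o$seg_probs, mask)$loss
  }
  o <- model_forward(m, x)
  sg <- plaseg:::seg_loss_grad(o$seg_probs, mask)
  cg <- plaseg:::class_loss_grad(o$class_probs, label)
  plaseg:::zero_grads(m)
  plaseg:::model_backward(m, dseg = 4 * sg$grad, dclass = cg$grad)
  layers <- plaseg:::collect_layers(m)
  eps <- 1e-5
  for (nm in sample(names(layers), 10)) {
    ly <- layers[[nm]]
    pn <- sample(names(ly$params), 1)
    k <- sample(length(ly$params[[pn]]), 1)
    orig <- ly$params[[pn]][k]
    ly$params[[pn]][k] <- orig + eps
    lp <- loss_of()
    ly$params[[pn]][k] <- orig - eps
    lm <- loss_of()
    ly$params[[pn]][k] <- orig
    g_num <- (lp - lm) / (2 * eps)
    g_an <- ly$grads[[pn]][k]
    expect_equal(g_an, g_num, tolerance = 1e-4,
                 label = sprintf("grad of %s.%s", nm, pn))
  }
})

test_that("checkpoints round-trip the model exactly", {
  set.seed(6)
  m <- build_mtunet(tiny_config())
  x <- array(runif(16^3), c(16, 16, 16))
  o <- model_forward(m, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  o2 <- model_forward(m2, x)
  expect_identical(o2$seg_probs, o$seg_probs)
  expect_identical(o2$class_probs, o$class_probs)
  unlink(path)
})
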