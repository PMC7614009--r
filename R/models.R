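## Network variants: residual 3D U-Net (segmentation), EncNet (position
## classification with an additive attention gate) and the multi-task U-Net
## sharing one encoder between both tasks. The transfer variants TUNet and
## TMTUNet reuse these architectures and differ only in their
## initialization (see transfer_init()).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Network configuration
#'
#' @param n_levels number of encoder levels (the deepest is the bottleneck).
#' @param features_per_level integer vector of feature widths, one per level.
#' @param decoder_dropout_rate dropout probability applied after each
#'   decoder level (also used for Monte-Carlo dropout at test time).
#' @param attention_level encoder level carrying the additive attention gate
#'   (classification variants).
#' @param n_classes number of position classes.
#' @param input_shape expected input grid; each component must be divisible
#'   by `2^(n_levels - 1)`.
#' @param gn_groups group count for group normalization.
#' @return an object of class `network_config`.
#' @export
network_config <- function(n_levels = 5L,
                           features_per_level = c(16L, 32L, 64L, 128L, 256L),
                           decoder_dropout_rate = 0.2,
                           attention_level = 3L,
                           n_classes = 3L,
                           input_shape = c(128L, 128L, 128L),
                           gn_groups = 8L) {
  cfg <- list(n_levels = as.integer(n_levels),
              features = as.integer(features_per_level),
              decoder_dropout_rate = decoder_dropout_rate,
              attention_level = as.integer(attention_level),
              n_classes = as.integer(n_classes),
              input_shape = as.integer(input_shape),
              gn_groups = as.integer(gn_groups))
  if (length(cfg$features) != cfg$n_levels)
    stop("features_per_level must have one entry per level")
  if (cfg$attention_level < 1 || cfg$attention_level > cfg$n_levels)
    stop("attention_level must lie in 1..n_levels")
  if (cfg$decoder_dropout_rate < 0 || cfg$decoder_dropout_rate >= 1)
    stop("decoder_dropout_rate must lie in [0, 1)")
  if (any(cfg$input_shape %% 2^(cfg$n_levels - 1) != 0))
    stop("input_shape must be divisible by 2^(n_levels - 1)")
  class(cfg) <- "network_config"
  cfg
}

MODEL_VARIANTS <- c("unet", "encnet", "tunet", "mtunet", "tmtunet")

#' Build a network variant
#'
#' `build_unet()` builds the segmentation baseline (encoder-decoder with
#' residual blocks, group normalization, ReLU, max-pool downsampling, skip
#' connections, decoder dropout and a single-channel sigmoid output).
#' `build_encnet()` builds the classification network: the same encoder
#' followed by a pretext head (conv block with layer normalization, then a
#' linear block whose sigmoid scores are renormalized to probabilities) and
#' one additive attention gate at `attention_level`. `build_mtunet()`
#' combines both on one shared encoder. `build_model()` dispatches on the
#' variant name; `tunet` and `tmtunet` share the unet/mtunet architectures
#' and differ only in their transfer initialization.
#'
#' @param config a [network_config()].
#' @param variant one of `"unet"`, `"encnet"`, `"tunet"`, `"mtunet"`,
#'   `"tmtunet"`.
#' @return a model object (environment).
#' @export
build_model <- function(variant, config = network_config()) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  arch <- switch(variant, tunet = "unet", tmtunet = "mtunet", variant)
  m <- new.env(parent = emptyenv())
  m$variant <- variant
  m$config <- config
  m$has_decoder <- arch != "encnet"
  m$has_head <- arch %in% c("encnet", "mtunet")
  L <- config$n_levels; f <- config$features; gg <- config$gn_groups
  m$enc <- vector("list", L)
  m$pools <- vector("list", max(L - 1, 0))
  cin <- 1L
  for (i in seq_len(L)) {
    m$enc[[i]] <- res_block(cin, f[i], gg)
    cin <- f[i]
    if (i < L) m$pools[[i]] <- ly_pool()
  }
  if (m$has_decoder) {
    m$ups <- vector("list", L - 1)
    m$dec <- vector("list", L - 1)
    m$drops <- vector("list", L - 1)
    for (i in seq_len(L - 1)) {
      m$ups[[i]] <- ly_up()
      m$dec[[i]] <- res_block(f[i] + f[i + 1], f[i], gg)
      m$drops[[i]] <- ly_dropout(config$decoder_dropout_rate)
    }
    m$final <- ly_conv(f[1], 1L, k = 1)
    m$out_sig <- ly_sigmoid()
  }
  if (m$has_head) {
    al <- config$attention_level
    fa <- f[al]
    m$att <- list(convx = ly_conv(f[al], fa, 1), convg = ly_conv(f[L], fa, 1),
                  psi = ly_conv(fa, 1L, 1), relu = ly_relu(),
                  sig = ly_sigmoid(),
                  gups = lapply(seq_len(L - al), function(i) ly_up()))
    m$head <- list(conv = ly_conv(f[L], f[L]), ln = ly_gn(f[L], 1L),
                   relu = ly_relu(),
                   lin = ly_linear(f[L] + f[al], config$n_classes),
                   ln2 = ly_gn(config$n_classes, 1L), sig = ly_sigmoid())
  }
  m
}

#' @rdname build_model
#' @export
build_unet <- function(config = network_config()) build_model("unet", config)

#' @rdname build_model
#' @export
build_encnet <- function(config = network_config()) build_model("encnet", config)

#' @rdname build_model
#' @export
build_mtunet <- function(config = network_config()) build_model("mtunet", config)

## Nearest upsampling of a 3D array to an integer-multiple target shape.
upsample_nearest_array <- function(arr, target) {
  d <- dim(arr)
  f <- target %/% d
  idx1 <- rep(seq_len(d[1]), each = f[1])
  idx2 <- rep(seq_len(d[2]), each = f[2])
  idx3 <- rep(seq_len(d[3]), each = f[3])
  arr[idx1, idx2, idx3, drop = FALSE]
}

#' Forward pass
#'
#' Runs the network on one volume. Returns per-voxel foreground
#' probabilities (segmentation variants), a class-probability vector
#' summing to one (classification variants), and the non-negative attention
#' map resampled to the input shape (attention variants). The pass is
#' deterministic when dropout is inactive.
#'
#' @param model a model from [build_model()].
#' @param x 3D numeric array or [volume3d].
#' @param training logical; enables dropout.
#' @param dropout_active override for dropout only (Monte-Carlo dropout uses
#'   `training = FALSE, dropout_active = TRUE`).
#' @return list with `seg_probs`, `class_probs`, `attention_map` (NULL where
#'   not applicable).
#' @export
model_forward <- function(model, x, training = FALSE, dropout_active = NULL) {
  if (inherits(x, "volume3d")) x <- x$intensities
  ish <- dim(x)
  cfg <- model$config
  L <- cfg$n_levels
  if (any(ish %% 2^(L - 1) != 0))
    stop("input shape must be divisible by 2^(n_levels - 1)")
  if (is.null(dropout_active)) dropout_active <- training
  X <- matrix(as.numeric(x), ncol = 1)
  dims <- as.integer(ish)
  skips <- vector("list", L)
  sdims <- vector("list", L)
  for (i in seq_len(L)) {
    X <- rb_fwd(model$enc[[i]], X, dims)
    skips[[i]] <- X
    sdims[[i]] <- dims
    if (i < L) {
      X <- pool_fwd(model$pools[[i]], X, dims)
      dims <- dims %/% 2L
    }
  }
  b <- skips[[L]]
  bdims <- sdims[[L]]
  ca <- list(skips = skips, sdims = sdims, ish = ish)
  gated <- NULL; amap <- NULL; p <- NULL; seg <- NULL
  if (model$has_head) {
    al <- cfg$attention_level
    g <- b; gdims <- bdims
    for (u in seq_along(model$att$gups)) {
      g <- up_fwd(model$att$gups[[u]], g, gdims)
      gdims <- gdims * 2L
    }
    qx <- conv_fwd(model$att$convx, skips[[al]], sdims[[al]])
    qg <- conv_fwd(model$att$convg, g, sdims[[al]])
    q <- relu_fwd(model$att$relu, qx + qg)
    alpha <- sigmoid_fwd(model$att$sig, conv_fwd(model$att$psi, q, sdims[[al]]))
    gated <- skips[[al]] * alpha[, 1]
    ca$alpha <- alpha
    ca$gated <- gated
    amap <- upsample_nearest_array(array(alpha[, 1], sdims[[al]]), ish)
  }
  if (model$has_decoder) {
    Y <- b; ydims <- bdims
    for (i in rev(seq_len(L - 1))) {
      Y <- up_fwd(model$ups[[i]], Y, ydims)
      ydims <- ydims * 2L
      sk <- if (model$has_head && i == cfg$attention_level) gated else skips[[i]]
      Y <- rb_fwd(model$dec[[i]], cbind(sk, Y), ydims)
      Y <- dropout_fwd(model$drops[[i]], Y, dropout_active)
    }
    segm <- sigmoid_fwd(model$out_sig, conv_fwd(model$final, Y, ydims))
    seg <- array(segm[, 1], ish)
  }
  if (model$has_head) {
    h <- relu_fwd(model$head$relu,
                  gn_fwd(model$head$ln, conv_fwd(model$head$conv, b, bdims)))
    vb <- colMeans(h)
    va <- colMeans(gated)
    z <- linear_fwd(model$head$lin, c(vb, va))
    z2 <- drop(gn_fwd(model$head$ln2, matrix(z, 1)))
    s <- drop(sigmoid_fwd(model$head$sig, matrix(z2, 1)))
    p <- s / sum(s)
    ca$s <- s
    ca$p <- p
    ca$h_nvox <- nrow(h)
  }
  model$cache <- ca
  list(seg_probs = seg, class_probs = p, attention_map = amap)
}

#' Predicted class from a probability vector
#'
#' @param class_probs probability vector from [model_forward()].
#' @return the 0-based class code of the argmax (0 anterior, 1 none,
#'   2 posterior).
#' @export
predicted_class <- function(class_probs) which.max(class_probs) - 1L

## Backward pass for the most recent model_forward() call. dseg is the
## gradient w.r.t. seg_probs (array/vector) and dclass w.r.t. class_probs;
## either may be NULL. Parameter gradients accumulate into the layers.
model_backward <- function(model, dseg = NULL, dclass = NULL) {
  cfg <- model$config
  L <- cfg$n_levels
  ca <- model$cache
  add <- function(a, b) if (is.null(a)) b else a + b
  contrib <- vector("list", L)
  dgated <- NULL
  db <- NULL
  if (!is.null(dseg) && model$has_decoder) {
    dY <- sigmoid_bwd(model$out_sig, matrix(as.numeric(dseg), ncol = 1))
    dY <- conv_bwd(model$final, dY)
    for (i in seq_len(L - 1)) {
      dY <- dropout_bwd(model$drops[[i]], dY)
      dY <- rb_bwd(model$dec[[i]], dY)
      fi <- cfg$features[i]
      dsk <- dY[, seq_len(fi), drop = FALSE]
      dup <- dY[, -seq_len(fi), drop = FALSE]
      if (model$has_head && i == cfg$attention_level) dgated <- add(dgated, dsk)
      else contrib[[i]] <- add(contrib[[i]], dsk)
      dY <- up_bwd(model$ups[[i]], dup)
    }
    db <- add(db, dY)
  }
  if (!is.null(dclass) && model$has_head) {
    p <- ca$p; s <- ca$s; S <- sum(s)
    ds <- dclass / S - sum(dclass * p) / S
    dz2 <- drop(sigmoid_bwd(model$head$sig, matrix(ds, 1)))
    dz <- drop(gn_bwd(model$head$ln2, matrix(dz2, 1)))
    dv <- linear_bwd(model$head$lin, dz)
    fL <- cfg$features[L]
    dvb <- dv[seq_len(fL)]
    dva <- dv[-seq_len(fL)]
    nh <- ca$h_nvox
    dh <- matrix(rep(dvb / nh, each = nh), nh)
    dh <- relu_bwd(model$head$relu, dh)
    dh <- conv_bwd(model$head$conv, gn_bwd(model$head$ln, dh))
    db <- add(db, dh)
    ng <- nrow(ca$gated)
    dgated <- add(dgated, matrix(rep(dva / ng, each = ng), ng))
  }
  if (!is.null(dgated) && model$has_head) {
    al <- cfg$attention_level
    x3 <- ca$skips[[al]]
    alpha <- ca$alpha[, 1]
    dalpha <- matrix(rowSums(dgated * x3), ncol = 1)
    dx3 <- dgated * alpha
    dq <- conv_bwd(model$att$psi, sigmoid_bwd(model$att$sig, dalpha))
    dq <- relu_bwd(model$att$relu, dq)
    dx3 <- dx3 + conv_bwd(model$att$convx, dq)
    dg <- conv_bwd(model$att$convg, dq)
    for (u in rev(seq_along(model$att$gups))) dg <- up_bwd(model$att$gups[[u]], dg)
    db <- add(db, dg)
    contrib[[al]] <- add(contrib[[al]], dx3)
  }
  if (is.null(db)) return(invisible(NULL))
  g <- db
  for (i in L:1) {
    gin <- rb_bwd(model$enc[[i]], g)
    if (i > 1) {
      g <- pool_bwd(model$pools[[i - 1]], gin)
      if (!is.null(contrib[[i - 1]])) g <- g + contrib[[i - 1]]
    }
  }
  invisible(NULL)
}

## Flat named list of all parameterized primitive layers.
collect_layers <- function(model) {
  out <- list()
  for (i in seq_along(model$enc))
    out <- c(out, rb_layers(model$enc[[i]], paste0("enc", i)))
  if (model$has_decoder) {
    for (i in seq_along(model$dec))
      out <- c(out, rb_layers(model$dec[[i]], paste0("dec", i)))
    out$final <- model$final
  }
  if (model$has_head) {
    out$att.convx <- model$att$convx
    out$att.convg <- model$att$convg
    out$att.psi <- model$att$psi
    out$head.conv <- model$head$conv
    out$head.ln <- model$head$ln
    out$head.lin <- model$head$lin
    out$head.ln2 <- model$head$ln2
  }
  out
}

#' Number of trainable parameters
#'
#' @param model a model object.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(collect_layers(model),
             function(ly) sum(vapply(ly$params, length, 1L)), 1))
}

#' Model state as a nested list of parameter arrays
#'
#' @param model a model object.
#' @return named list `layer -> param -> array`.
#' @export
model_state <- function(model) lapply(collect_layers(model), function(ly) ly$params)

#' Load a state into a model
#'
#' @param model target model.
#' @param state a state from [model_state()]; layer and parameter shapes
#'   must match.
#' @param layers optional character vector restricting which layers to load.
#' @export
load_state <- function(model, state, layers = NULL) {
  tgt <- collect_layers(model)
  nms <- layers %||% intersect(names(tgt), names(state))
  bad <- character()
  for (nm in nms) {
    if (is.null(state[[nm]]) || is.null(tgt[[nm]])) { bad <- c(bad, nm); next }
    for (pn in names(tgt[[nm]]$params)) {
      src <- state[[nm]][[pn]]
      if (is.null(src) || !identical(dim(src) %||% length(src),
                                     dim(tgt[[nm]]$params[[pn]]) %||%
                                       length(tgt[[nm]]$params[[pn]]))) {
        bad <- c(bad, paste0(nm, ".", pn))
      }
    }
  }
  if (length(bad))
    stop("state mismatch for layers: ", paste(unique(bad), collapse = ", "))
  for (nm in nms)
    for (pn in names(tgt[[nm]]$params))
      tgt[[nm]]$params[[pn]] <- state[[nm]][[pn]]
  invisible(model)
}

#' Save / load model checkpoints
#'
#' Checkpoints embed the variant name, the [network_config()] and all
#' parameter arrays.
#'
#' @param model a model object.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(variant = model$variant, config = model$config,
               state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- build_model(ck$variant, ck$config)
  load_state(m, ck$state)
  m
}
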