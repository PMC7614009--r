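## Losses, augmentation, the alternating multi-task schedule, transfer
## initialization and the training loop.

as_prob_grid <- function(x) {
  if (inherits(x, "volume3d")) x <- x$intensities
  as.numeric(x)
}
as_mask_grid <- function(x) {
  if (inherits(x, "seg_mask")) x <- x$voxels
  as.numeric(x != 0)
}

#' Segmentation loss: binary cross-entropy plus Dice loss
#'
#' `BCE(p, m) + (1 - softDice(p, m))` with probabilities clipped at 1e-7 and
#' a smoothing constant `eps = 1e-5` added to both the numerator and the
#' denominator of the soft Dice, so an empty prediction of an empty
#' reference has zero Dice loss.
#'
#' @param seg_probs probability grid (array or [volume3d]).
#' @param reference binary reference ([seg_mask] or array).
#' @return non-negative scalar loss.
#' @export
seg_loss <- function(seg_probs, reference) seg_loss_grad(seg_probs, reference)$loss

seg_loss_grad <- function(seg_probs, reference, eps = 1e-5, clip = 1e-7) {
  p <- as_prob_grid(seg_probs)
  m <- as_mask_grid(reference)
  if (length(p) != length(m)) stop("segmentation/reference shape mismatch")
  if (any(p < -1e-9 | p > 1 + 1e-9)) stop("seg_probs must lie in [0, 1]")
  pc <- pmin(pmax(p, clip), 1 - clip)
  n <- length(p)
  bce <- -mean(m * log(pc) + (1 - m) * log(1 - pc))
  # the Dice term uses the raw probabilities; clipping is a BCE-only guard
  inter <- sum(p * m)
  denom <- sum(p) + sum(m) + eps
  dice <- (2 * inter + eps) / denom
  loss <- bce + (1 - dice)
  dbce <- (pc - m) / (pc * (1 - pc)) / n
  ddice <- -(2 * m * denom - (2 * inter + eps)) / denom^2
  list(loss = loss, grad = dbce + ddice,
       bce = bce, dice_loss = 1 - dice)
}

#' Classification loss: cross-entropy
#'
#' `-log(class_probs[label])` with probability clipping at 1e-7. Labels use
#' the 0-based class codes (0 anterior, 1 none, 2 posterior).
#'
#' @param class_probs probability vector.
#' @param label integer class code.
#' @return non-negative scalar loss.
#' @export
class_loss <- function(class_probs, label) class_loss_grad(class_probs, label)$loss

class_loss_grad <- function(class_probs, label, clip = 1e-7) {
  k <- length(class_probs)
  if (length(label) != 1 || is.na(label) || !(label %in% 0:(k - 1)))
    stop("label must be a class code in 0..", k - 1)
  p <- pmin(pmax(class_probs, clip), 1)
  i <- as.integer(label) + 1L
  g <- numeric(k)
  g[i] <- -1 / p[i]
  list(loss = -log(p[i]), grad = g)
}

#' Multi-task loss
#'
#' Combines the classification and segmentation losses as
#' `l_class + beta * l_seg`; `beta > 1` emphasizes the segmentation
#' downstream task.
#'
#' @param l_class classification loss term.
#' @param l_seg segmentation loss term.
#' @param beta positive weighting scalar.
#' @return scalar combined loss.
#' @export
multitask_loss <- function(l_class, l_seg, beta) {
  if (!is.finite(l_class) || !is.finite(l_seg)) stop("loss terms must be finite")
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  l_class + beta * l_seg
}

#' Augmentation specification
#'
#' Spatial augmentation: flips about the x and z axes only (the depth axis
#' is never flipped so the frustum keeps its orientation), voxel
#' translations, rotation about the depth axis, isotropic scaling (percent)
#' and a lateral shear expressed as the voxel offset reached at the deepest
#' image plane.
#'
#' @param flip_axes axes eligible for flipping; only `"x"` and `"z"` are
#'   allowed.
#' @param translation_range maximum absolute translation, voxels.
#' @param rotation_range maximum absolute rotation, degrees.
#' @param scaling_range maximum absolute scaling, percent.
#' @param shearing_range maximum absolute shear offset, voxels.
#' @return an object of class `augment_spec`.
#' @export
augment_spec <- function(flip_axes = c("x", "z"), translation_range = 10,
                         rotation_range = 15, scaling_range = 10,
                         shearing_range = 15) {
  if (length(flip_axes) && !all(flip_axes %in% c("x", "z")))
    stop("the depth (up/down) axis is never flipped; flip_axes may only contain 'x' and 'z'")
  structure(list(flip_axes = flip_axes, translation_range = translation_range,
                 rotation_range = rotation_range, scaling_range = scaling_range,
                 shearing_range = shearing_range), class = "augment_spec")
}

#' Flip a 3D array about one axis
#'
#' @param arr 3D array.
#' @param axis `"x"` (first) or `"z"` (third axis).
#' @return the flipped array.
#' @export
flip_axis <- function(arr, axis = c("x", "z")) {
  axis <- match.arg(axis)
  if (axis == "x") arr[dim(arr)[1]:1, , , drop = FALSE]
  else arr[, , dim(arr)[3]:1, drop = FALSE]
}

#' Random spatial augmentation of an image/mask pair
#'
#' Draws one transform (flips, translation, rotation about the depth axis,
#' scaling, shear) and applies it identically to the image (trilinear), the
#' mask and the frustum (nearest neighbour). A zero-range spec reproduces
#' the input.
#'
#' @param volume a [volume3d].
#' @param mask a [seg_mask] or NULL.
#' @param spec an [augment_spec()].
#' @param seed integer seed for the draw.
#' @return list with transformed `volume` and `mask`.
#' @export
augment <- function(volume, mask = NULL, spec = augment_spec(), seed = NULL) {
  d <- dim(volume$intensities)
  with_seed(seed, {
    flips <- c(x = FALSE, z = FALSE)
    for (ax in spec$flip_axes) flips[ax] <- runif(1) < 0.5
    tr <- runif(3, -1, 1) * spec$translation_range
    th <- runif(1, -1, 1) * spec$rotation_range * pi / 180
    sc <- 1 + runif(1, -1, 1) * spec$scaling_range / 100
    sh <- runif(1, -1, 1) * spec$shearing_range
    apply_affine(volume, mask, flips, tr, th, sc, sh)
  })
}

## Forward model about the grid centre: flip -> shear -> scale -> rotate
## (about depth axis) -> translate. Resampling uses the inverse map.
apply_affine <- function(volume, mask, flips, tr, theta, scale, shear_vox) {
  d <- dim(volume$intensities)
  ctr <- (d + 1) / 2
  Fm <- diag(c(if (flips["x"]) -1 else 1, 1, if (flips["z"]) -1 else 1))
  Sh <- diag(3); Sh[1, 2] <- shear_vox / ((d[2] - 1) / 2 + 1e-12)
  Sc <- diag(rep(scale, 3))
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3)
  A <- R %*% Sc %*% Sh %*% Fm
  Ainv <- solve(A)
  g <- voxel_index_grid(d)
  p <- sweep(g, 2, ctr)
  p <- sweep(p, 2, tr)
  src <- sweep(p %*% t(Ainv), 2, ctr, "+")
  vi <- array(interp_trilinear(volume$intensities, src), d)
  fr <- array(interp_nearest(volume$frustum + 0, src) > 0.5, d)
  vi[!fr] <- 0
  vol <- volume3d(clip01(vi), volume$spacing, fr, volume$origin)
  mk <- NULL
  if (!is.null(mask)) {
    mv <- array(interp_nearest(mask$voxels + 0, src) > 0.5, d)
    mk <- seg_mask(mv & fr, mask$spacing)
  }
  list(volume = vol, mask = mk)
}

#' Alternating multi-task iteration plan
#'
#' One cycle runs one classification sub-iteration (mini-batch step)
#' followed by `beta` segmentation sub-iterations; cycles repeat until both
#' loaders are exhausted for the epoch (a depleted loader simply drops out
#' of the cycle).
#'
#' @param n_class_batches classification batches available this epoch.
#' @param n_seg_batches segmentation batches available this epoch.
#' @param beta positive integer; segmentation sub-iterations per cycle.
#' @return character vector of `"C"` / `"S"` steps.
#' @export
alternating_schedule <- function(n_class_batches, n_seg_batches, beta) {
  if (!is.finite(beta) || beta <= 0 || beta != round(beta))
    stop("beta must be a positive integer for scheduling; round it first")
  cr <- n_class_batches; sr <- n_seg_batches
  plan <- character(0)
  while (cr > 0 || sr > 0) {
    if (cr > 0) { plan <- c(plan, "C"); cr <- cr - 1 }
    k <- min(beta, sr)
    if (k > 0) { plan <- c(plan, rep("S", k)); sr <- sr - k }
  }
  plan
}

#' Transfer-learning initialization
#'
#' Copies pretrained classification (EncNet) weights into a target model:
#' for variant `tunet` the encoder and bottleneck; for `tmtunet`
#' additionally the pretext head and the attention gate. Decoder weights
#' are left untouched.
#'
#' @param target_model a model with variant `tunet` or `tmtunet`.
#' @param source an EncNet model, a checkpoint list or a checkpoint path.
#' @return the target model, invisibly.
#' @export
transfer_init <- function(target_model, source) {
  if (!target_model$variant %in% c("tunet", "tmtunet"))
    stop("transfer_init applies to variants tunet and tmtunet")
  state <- if (is.environment(source)) model_state(source)
  else if (is.character(source)) readRDS(source)$state
  else source$state %||% source
  nms <- grep("^enc", names(state), value = TRUE)
  if (target_model$variant == "tmtunet")
    nms <- c(nms, grep("^(att|head)\\.", names(state), value = TRUE))
  load_state(target_model, state, layers = nms)
  invisible(target_model)
}

#' Training configuration
#'
#' Defaults follow the per-variant protocol: EncNet lr 1e-5 for 400 epochs;
#' UNet lr 1e-4 with decay 0.1 at epochs 30/70/90 for 100 epochs;
#' multi-task variants lr 5e-5 with decay at 20/30/40 for 50 epochs; all
#' with Adam and multi-task weight `beta = 4`. Every default can be
#' overridden, which the scaled-down phantom experiments use.
#'
#' @param variant one of `"unet"`, `"encnet"`, `"tunet"`, `"mtunet"`,
#'   `"tmtunet"`.
#' @param beta positive multi-task weight (and sub-iteration ratio).
#' @param lr initial learning rate (variant default when NULL).
#' @param lr_milestones epochs at which the rate is multiplied by
#'   `lr_gamma`.
#' @param lr_gamma decay factor.
#' @param max_epochs training epochs.
#' @param batch_size mini-batch size.
#' @param augmentation an [augment_spec()] or NULL to disable.
#' @param seed integer seed covering weight init, data order, dropout and
#'   augmentation draws.
#' @return an object of class `train_config`.
#' @export
train_config <- function(variant, beta = 4, lr = NULL, lr_milestones = NULL,
                         lr_gamma = 0.1, max_epochs = NULL, batch_size = 2L,
                         augmentation = NULL, seed = 1L) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  defaults <- switch(variant,
    encnet = list(lr = 1e-5, milestones = integer(0), epochs = 400L),
    unet = , tunet = list(lr = 1e-4, milestones = c(30L, 70L, 90L), epochs = 100L),
    mtunet = , tmtunet = list(lr = 5e-5, milestones = c(20L, 30L, 40L), epochs = 50L))
  structure(list(variant = variant, beta = beta,
                 optimizer = "adam",
                 lr = lr %||% defaults$lr,
                 lr_milestones = lr_milestones %||% defaults$milestones,
                 lr_gamma = lr_gamma,
                 max_epochs = as.integer(max_epochs %||% defaults$epochs),
                 batch_size = as.integer(batch_size),
                 augmentation = augmentation, seed = as.integer(seed)),
            class = "train_config")
}

## Adam optimizer over all parameterized layers of a model.
adam_state <- function(model, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$layers <- collect_layers(model)
  e$m <- lapply(e$layers, function(ly) lapply(ly$params, function(p) p * 0))
  e$v <- e$m
  e$t <- 0L
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(opt$layers)) {
    ly <- opt$layers[[nm]]
    for (pn in names(ly$params)) {
      g <- ly$grads[[pn]]
      opt$m[[nm]][[pn]] <- b1 * opt$m[[nm]][[pn]] + (1 - b1) * g
      opt$v[[nm]][[pn]] <- b2 * opt$v[[nm]][[pn]] + (1 - b2) * g * g
      mhat <- opt$m[[nm]][[pn]] / c1
      vhat <- opt$v[[nm]][[pn]] / c2
      ly$params[[pn]] <- ly$params[[pn]] - lr * mhat / (sqrt(vhat) + opt$eps)
      ly$grads[[pn]] <- g * 0
    }
  }
  invisible(NULL)
}

zero_grads <- function(model) {
  for (ly in collect_layers(model))
    ly$grads <- lapply(ly$grads, function(g) g * 0)
  invisible(NULL)
}

epoch_lr <- function(config, epoch) {
  config$lr * config$lr_gamma^sum(epoch >= config$lr_milestones)
}

record_input <- function(rec) {
  if (inherits(rec$volume, "volume3d")) rec$volume$intensities else rec$volume
}

#' Train a model variant
#'
#' Runs the variant-appropriate loop: plain mini-batch training for
#' `unet`/`encnet`, the alternating 1:beta multi-task schedule for
#' `mtunet`/`tmtunet`, and transfer initialization from a pretrained EncNet
#' first for `tunet`/`tmtunet`. Images of class `none` (no mask)
#' participate only in the classification term. Aborts with a diagnostic if
#' a loss becomes non-finite.
#'
#' @param model a model from [build_model()] whose variant matches
#'   `config$variant`.
#' @param dataset list of records, each with elements `volume`
#'   ([volume3d] or array), `mask` ([seg_mask] or NULL) and `class_label`
#'   (code 0/1/2).
#' @param config a [train_config()].
#' @param pretrained EncNet checkpoint (path, list or model) required for
#'   variants `tunet`/`tmtunet`.
#' @param validation optional list of records; per-epoch mean validation
#'   Dice is logged.
#' @param out optional directory; checkpoint and training log are written
#'   there.
#' @param verbose print per-epoch losses.
#' @return list with `model`, `log` (data.frame epoch/l_class/l_seg/l_mt/
#'   lr/val_dice) and `checkpoint` (path or NULL).
#' @export
train <- function(model, dataset, config, pretrained = NULL,
                  validation = NULL, out = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(dataset) == 0) stop("dataset is empty")
  if (model$variant != config$variant)
    stop("model variant and config variant disagree")
  if (config$variant %in% c("tunet", "tmtunet")) {
    if (is.null(pretrained))
      stop("variants tunet/tmtunet require a pretrained EncNet checkpoint")
    transfer_init(model, pretrained)
  }
  has_mask <- vapply(dataset, function(r) !is.null(r$mask), TRUE)
  seg_idx <- which(has_mask)
  cls_idx <- seq_along(dataset)
  needs_seg <- model$has_decoder
  needs_cls <- model$has_head
  if (needs_seg && length(seg_idx) == 0) stop("no records with masks")
  opt <- NULL
  log <- NULL

  with_seed(config$seed, {
    opt <- adam_state(model)
    zero_grads(model)
    bs <- config$batch_size
    mk_batches <- function(idx) {
      idx <- idx[sample.int(length(idx))]
      split(idx, ceiling(seq_along(idx) / bs))
    }
    aug_rec <- function(rec) {
      if (is.null(config$augmentation)) return(rec)
      vol <- if (inherits(rec$volume, "volume3d")) rec$volume
      else volume3d(rec$volume, c(1, 1, 1))
      a <- augment(vol, rec$mask, config$augmentation,
                   seed = sample.int(.Machine$integer.max, 1))
      rec$volume <- a$volume
      rec$mask <- a$mask
      rec
    }
    step_seg <- function(batch, lr, multitask, beta) {
      lc <- ls <- 0
      for (i in batch) {
        rec <- aug_rec(dataset[[i]])
        o <- model_forward(model, record_input(rec), training = TRUE)
        sg <- seg_loss_grad(o$seg_probs, rec$mask)
        ls <- ls + sg$loss
        dseg <- beta * sg$grad / length(batch)
        dcls <- NULL
        if (multitask) {
          cg <- class_loss_grad(o$class_probs, rec$class_label)
          lc <- lc + cg$loss
          dcls <- cg$grad / length(batch)
        }
        model_backward(model, dseg = dseg, dclass = dcls)
      }
      adam_step(opt, lr)
      c(lc, ls) / length(batch)
    }
    step_cls <- function(batch, lr) {
      lc <- 0
      for (i in batch) {
        rec <- aug_rec(dataset[[i]])
        o <- model_forward(model, record_input(rec), training = TRUE)
        cg <- class_loss_grad(o$class_probs, rec$class_label)
        lc <- lc + cg$loss
        model_backward(model, dclass = cg$grad / length(batch))
      }
      adam_step(opt, lr)
      lc / length(batch)
    }
    rows <- vector("list", config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      lr <- epoch_lr(config, epoch)
      lcs <- numeric(0); lss <- numeric(0)
      if (model$variant %in% c("mtunet", "tmtunet")) {
        cb <- mk_batches(cls_idx)
        sb <- mk_batches(seg_idx)
        plan <- alternating_schedule(length(cb), length(sb), round(config$beta))
        ci <- si <- 0L
        for (stp in plan) {
          if (stp == "C") {
            ci <- ci + 1L
            lcs <- c(lcs, step_cls(cb[[ci]], lr))
          } else {
            si <- si + 1L
            r <- step_seg(sb[[si]], lr, multitask = TRUE, beta = config$beta)
            lcs <- c(lcs, r[1]); lss <- c(lss, r[2])
          }
        }
      } else if (model$variant == "encnet") {
        for (b in mk_batches(cls_idx)) lcs <- c(lcs, step_cls(b, lr))
      } else {
        for (b in mk_batches(seg_idx)) {
          r <- step_seg(b, lr, multitask = FALSE, beta = 1)
          lss <- c(lss, r[2])
        }
      }
      l_class <- if (length(lcs)) mean(lcs) else NA_real_
      l_seg <- if (length(lss)) mean(lss) else NA_real_
      l_mt <- if (model$variant %in% c("mtunet", "tmtunet"))
        multitask_loss(l_class, l_seg, config$beta) else NA_real_
      if (any(!is.finite(c(l_class, l_seg)) &
              !is.na(c(l_class, l_seg))))
        stop(sprintf("non-finite loss at epoch %d (l_class=%g, l_seg=%g); aborting",
                     epoch, l_class, l_seg))
      vd <- NA_real_
      if (!is.null(validation)) {
        ds <- vapply(validation, function(r) {
          o <- model_forward(model, record_input(r), training = FALSE)
          dice(seg_mask(o$seg_probs >= 0.5, c(1, 1, 1)),
               seg_mask(as_mask_grid_array(r$mask), c(1, 1, 1)))
        }, 1.0)
        vd <- mean(ds)
      }
      rows[[epoch]] <- data.frame(epoch = epoch, l_class = l_class,
                                  l_seg = l_seg, l_mt = l_mt, lr = lr,
                                  val_dice = vd)
      if (verbose)
        message(sprintf("epoch %3d lr %.2g l_class %.4f l_seg %.4f val %.3f",
                        epoch, lr, l_class, l_seg, vd))
    }
    log <- do.call(rbind, rows)
  })

  ckpt <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    ckpt <- file.path(out, sprintf("%s_checkpoint.rds", config$variant))
    save_checkpoint(model, ckpt)
    write.csv(log, file.path(out, sprintf("%s_log.csv", config$variant)),
              row.names = FALSE)
  }
  list(model = model, log = log, checkpoint = ckpt)
}

as_mask_grid_array <- function(x) {
  if (inherits(x, "seg_mask")) x$voxels else (x != 0)
}
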