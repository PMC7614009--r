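## NIfTI I/O, resampling, patient-grouped cross-validation splits and the
## in-distribution / out-of-distribution experiment harness.

#' Read / write volumes as NIfTI-1
#'
#' Volumes are stored with their spacing in the NIfTI pixdim header and
#' intensities as float64, so a write/read round trip preserves the grid
#' bitwise and the spacing to well below 1e-6 mm.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return `read_volume()` returns a [volume3d] (frustum all-true; apply
#'   masks separately).
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(errorCondition(
                    paste0("not a readable NIfTI file: ", path, " (",
                           conditionMessage(e), ")"),
                    class = c("plaseg_format_error", "error", "condition"))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    stop(errorCondition(paste0("expected a 3D NIfTI volume: ", path),
                        class = c("plaseg_format_error", "error", "condition")))
  sp <- RNifti::pixdim(img)[1:3]
  origin <- -RNifti::worldToVoxel(c(0, 0, 0), img)[1:3] * sp
  volume3d(arr, sp, origin = origin)
}

#' @rdname read_volume
#' @param volume a [volume3d] (or [seg_mask], written as 0/1).
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "seg_mask"))
    volume <- volume3d(volume$voxels + 0, volume$spacing)
  arr <- volume$intensities
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Resample a volume or mask to a target grid
#'
#' Trilinear interpolation for intensities and nearest neighbour for masks
#' and the frustum; the voxel spacing is rescaled so the physical extent is
#' preserved. The mapping is cell-centred, so resampling to the input's
#' own shape is the identity.
#'
#' @param x a [volume3d] or [seg_mask].
#' @param target_shape positive integer triple.
#' @return object of the same class on the target grid.
#' @export
resample <- function(x, target_shape) {
  target_shape <- as.integer(target_shape)
  if (any(target_shape < 1)) stop("target_shape must be positive")
  src <- if (inherits(x, "seg_mask")) dim(x$voxels) else dim(x$intensities)
  scale <- src / target_shape
  g <- voxel_index_grid(target_shape)
  coords <- sweep(sweep(g, 2, 0.5) %*% diag(scale), 2, 0.5, "+")
  if (inherits(x, "seg_mask")) {
    v <- array(interp_nearest(x$voxels + 0, coords) > 0.5, target_shape)
    return(seg_mask(v, x$spacing * scale))
  }
  vi <- array(interp_trilinear(x$intensities, coords), target_shape)
  fr <- array(interp_nearest(x$frustum + 0, coords) > 0.5, target_shape)
  vi[!fr] <- 0
  volume3d(clip01(vi), x$spacing * scale, fr, x$origin)
}

#' Patient-grouped cross-validation splits
#'
#' Assigns whole patients to train/validation/test partitions per fold
#' (images from one patient never cross partitions), stratified by class so
#' each fold sees both placenta classes. With `n_folds = 5` the fractions
#' are approximately 60/20/20 and every patient is in exactly one test set
#' across folds. `mode` controls the segmentation training distribution:
#' `"A"` anterior-only, `"P"` posterior-only, `"AP"` both.
#'
#' @param manifest data.frame with `patient_id` and `class` columns.
#' @param n_folds number of folds (default 5).
#' @param mode `"A"`, `"P"` or `"AP"`.
#' @param seed integer seed.
#' @return object of class `split_plan`: per-fold patient assignments plus
#'   the mode.
#' @export
make_splits <- function(manifest, n_folds = 5L, mode = c("AP", "A", "P"),
                        seed = 1L) {
  mode <- match.arg(mode)
  pts <- unique(manifest[, c("patient_id", "class")])
  if (any(duplicated(pts$patient_id)))
    stop("a patient_id maps to more than one class")
  if (nrow(pts) < n_folds) stop("fewer patients than folds")
  groups <- vector("list", n_folds)
  with_seed(seed, {
    for (cl in unique(pts$class)) {
      ids <- pts$patient_id[pts$class == cl]
      ids <- ids[sample.int(length(ids))]
      for (i in seq_along(ids)) {
        k <- ((i - 1) %% n_folds) + 1
        groups[[k]] <- c(groups[[k]], ids[i])
      }
    }
  })
  folds <- lapply(seq_len(n_folds), function(k) {
    vk <- (k %% n_folds) + 1
    list(test = groups[[k]], validation = groups[[vk]],
         train = unlist(groups[-c(k, vk)], use.names = FALSE))
  })
  structure(list(folds = folds, n_folds = as.integer(n_folds), mode = mode),
            class = "split_plan")
}

## Image-level roles for one fold of a split plan. Segmentation training/
## validation images are restricted to the mode's class(es); classification
## uses all classes; the test set keeps both placenta classes.
split_images <- function(plan, manifest, fold = 1L) {
  f <- plan$folds[[fold]]
  seg_classes <- switch(plan$mode,
                        A = PLACENTA_CLASSES[["anterior"]],
                        P = PLACENTA_CLASSES[["posterior"]],
                        AP = PLACENTA_CLASSES[c("anterior", "posterior")])
  in_part <- function(pids) manifest$patient_id %in% pids
  list(
    seg_train = which(in_part(f$train) & manifest$class %in% seg_classes),
    seg_val = which(in_part(f$validation) & manifest$class %in% seg_classes),
    cls_train = which(in_part(f$train)),
    cls_val = which(in_part(f$validation)),
    test = which(in_part(f$test)),
    test_seg = which(in_part(f$test) &
                       manifest$class != PLACENTA_CLASSES[["none"]]))
}

## Materialize manifest rows once into memory.
materialize_records <- function(manifest, idx = seq_len(nrow(manifest))) {
  recs <- lapply(idx, function(i) phantom_record(manifest, i))
  names(recs) <- manifest$id[idx]
  recs
}

#' Run the in-distribution / out-of-distribution experiment
#'
#' Trains the requested variants on each training-set mode (`A`
#' anterior-only, `P` posterior-only, `AP` both), evaluates segmentation
#' metrics on the held-out test images split into InD (class present in
#' segmentation training) and OoD (class absent), scores classification for
#' head variants, and computes paired Wilcoxon effect sizes of each variant
#' against the `unet` baseline on the per-image Dice scores. Transfer
#' variants pretrain one EncNet per mode on the classification task first.
#'
#' @param manifest a phantom manifest from [generate_dataset()].
#' @param variants subset of `c("unet","encnet","tunet","mtunet","tmtunet")`.
#' @param modes subset of `c("A","P","AP")`.
#' @param net_config a [network_config()].
#' @param train_args named list of [train_config()] overrides applied to
#'   every segmentation variant (e.g. `list(max_epochs = 20, lr = 1e-3)`).
#' @param encnet_args overrides for the EncNet pretraining.
#' @param fold fold index evaluated (default 1).
#' @param n_folds folds in the split plan.
#' @param seed integer seed covering splits, init and training.
#' @param out optional directory for CSV/JSON reports.
#' @param verbose print progress.
#' @return list with `per_image` (data.frame of metrics), `summary`
#'   (mean/sd by variant, mode, InD/OoD), `classification`, `effects`, and
#'   `models`.
#' @export
run_ood_experiment <- function(manifest,
                               variants = c("unet", "tmtunet"),
                               modes = c("A", "P"),
                               net_config = network_config(
                                 n_levels = 3,
                                 features_per_level = c(4L, 8L, 16L),
                                 input_shape = c(32L, 32L, 32L)),
                               train_args = list(),
                               encnet_args = list(),
                               fold = 1L, n_folds = 5L, seed = 1L,
                               out = NULL, verbose = FALSE) {
  variants <- match.arg(variants, MODEL_VARIANTS, several.ok = TRUE)
  recs <- materialize_records(manifest)
  mk_cfg <- function(variant, args) {
    do.call(train_config, c(list(variant = variant), args,
                            list(seed = seed + 1L)))
  }
  per_image <- list()
  cls_rows <- list()
  models <- list()
  for (mode in modes) {
    plan <- make_splits(manifest, n_folds = n_folds, mode = mode, seed = seed)
    si <- split_images(plan, manifest, fold)
    ind_classes <- switch(mode,
                          A = PLACENTA_CLASSES[["anterior"]],
                          P = PLACENTA_CLASSES[["posterior"]],
                          AP = PLACENTA_CLASSES[c("anterior", "posterior")])
    seg_set <- manifest$id[si$seg_train]
    mk_dataset <- function(idx, masks_for = seg_set) {
      lapply(idx, function(i) {
        r <- recs[[manifest$id[i]]]
        list(volume = r$volume,
             mask = if (r$id %in% masks_for) r$mask else NULL,
             class_label = r$class_label)
      })
    }
    pretrained <- NULL
    if (any(variants %in% c("tunet", "tmtunet"))) {
      if (verbose) message(sprintf("[mode %s] pretraining encnet", mode))
      enc <- with_seed(seed + 11L, build_model("encnet", net_config))
      cfg <- mk_cfg("encnet", encnet_args)
      fit <- train(enc, mk_dataset(si$cls_train, masks_for = character()),
                   cfg, verbose = verbose)
      pretrained <- list(state = model_state(fit$model))
      models[[paste0("encnet_", mode)]] <- fit$model
    }
    for (variant in setdiff(variants, "encnet")) {
      if (verbose) message(sprintf("[mode %s] training %s", mode, variant))
      model <- with_seed(seed + 23L, build_model(variant, net_config))
      cfg <- mk_cfg(variant, train_args)
      ds_idx <- if (variant %in% c("unet", "tunet")) si$seg_train else si$cls_train
      fit <- train(model, mk_dataset(ds_idx), cfg,
                   pretrained = if (variant %in% c("tunet", "tmtunet"))
                     pretrained else NULL,
                   verbose = verbose)
      models[[paste0(variant, "_", mode)]] <- fit$model
      preds <- integer(0); labs <- integer(0)
      for (i in si$test) {
        r <- recs[[manifest$id[i]]]
        o <- model_forward(fit$model, r$volume, training = FALSE)
        if (!is.null(o$class_probs)) {
          preds <- c(preds, predicted_class(o$class_probs))
          labs <- c(labs, r$class_label)
        }
        if (r$class_label == PLACENTA_CLASSES[["none"]]) next
        pred_mask <- seg_mask(o$seg_probs >= 0.5, r$volume$spacing)
        mr <- metrics_report(pred_mask, r$mask)
        per_image[[length(per_image) + 1L]] <- cbind(
          data.frame(variant = variant, mode = mode, id = r$id,
                     class = class_name(r$class_label),
                     distribution = if (r$class_label %in% ind_classes)
                       "InD" else "OoD"), mr)
      }
      if (length(labs)) {
        cs <- classification_scores(preds, labs)
        cls_rows[[length(cls_rows) + 1L]] <-
          cbind(data.frame(variant = variant, mode = mode), cs)
      }
    }
  }
  per_image <- do.call(rbind, per_image)
  groups <- split(per_image,
                  interaction(per_image$variant, per_image$mode,
                              per_image$distribution, drop = TRUE))
  agg <- do.call(rbind, lapply(groups, function(g) data.frame(
    variant = g$variant[1], mode = g$mode[1],
    distribution = g$distribution[1], n = nrow(g),
    dice_mean = mean(g$dice), dice_sd = sd(g$dice),
    iou_mean = mean(g$iou),
    asd_mean = mean(g$asd_mm, na.rm = TRUE),
    rhd95_mean = mean(g$rhd95_mm, na.rm = TRUE))))
  rownames(agg) <- NULL
  effects <- list()
  if ("unet" %in% variants) {
    for (mode in modes) for (dist in c("InD", "OoD")) {
      base <- per_image[per_image$variant == "unet" & per_image$mode == mode &
                          per_image$distribution == dist, c("id", "dice")]
      for (variant in setdiff(variants, c("unet", "encnet"))) {
        cmp <- per_image[per_image$variant == variant & per_image$mode == mode &
                           per_image$distribution == dist, c("id", "dice")]
        mrg <- merge(base, cmp, by = "id")
        if (nrow(mrg) >= 5) {
          ef <- paired_wilcoxon_effect(mrg$dice.y, mrg$dice.x)
          effects[[paste(variant, mode, dist, sep = "_")]] <- ef
        }
      }
    }
  }
  classification <- if (length(cls_rows)) do.call(rbind, cls_rows) else NULL
  res <- list(per_image = per_image, summary = agg,
              classification = classification, effects = effects,
              models = models)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write.csv(per_image, file.path(out, "per_image_metrics.csv"),
              row.names = FALSE)
    if (!is.null(classification))
      write.csv(classification, file.path(out, "classification.csv"),
                row.names = FALSE)
  }
  res
}
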