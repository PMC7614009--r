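## Synthetic frustum phantoms: ultrasound-like volumes with a placenta-like
## slab, speckle and acoustic shadows, so the full pipeline is exercisable
## without clinical data.

PLACENTA_CLASSES <- c(anterior = 0L, none = 1L, posterior = 2L)

#' Placental position class codes
#'
#' Placental position is discretized into three classes: `anterior` (code 0,
#' placenta near the probe at the front uterine wall), `none` (code 1, no
#' placental tissue in the image) and `posterior` (code 2, placenta at the
#' back uterine wall, typically behind the fetus and affected by shadowing).
#'
#' @param x a class name (character) or code (integer).
#' @return `class_code()` returns the integer code; `class_name()` the name.
#' @export
class_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (!all(x %in% PLACENTA_CLASSES)) stop("class code must be 0, 1 or 2")
    return(x)
  }
  x <- match.arg(as.character(x), names(PLACENTA_CLASSES), several.ok = TRUE)
  unname(PLACENTA_CLASSES[x])
}

#' @rdname class_code
#' @export
class_name <- function(x) {
  names(PLACENTA_CLASSES)[match(as.integer(x), PLACENTA_CLASSES)]
}

#' Specification of a synthetic placenta phantom
#'
#' Parameters controlling one synthetic 3D ultrasound-like volume: the voxel
#' grid, the placental position class, the geometry of the placenta-like
#' slab (a curved shell segment), and artifact severity (acoustic-shadow
#' cones and multiplicative speckle). Identical specs (including `seed`)
#' always produce identical phantoms.
#'
#' @param grid_shape integer triple, voxels per axis (each >= 8). The second
#'   axis is depth with the frustum apex at index 1.
#' @param spacing positive mm/voxel triple.
#' @param placenta_class `"anterior"`, `"none"` or `"posterior"` (or codes
#'   0/1/2).
#' @param slab_thickness_frac slab thickness as a fraction of the depth
#'   extent, in (0, 0.4).
#' @param slab_lateral_extent_frac lateral slab extent as a fraction of the
#'   local frustum half-width, in (0.2, 1.0).
#' @param curvature non-negative bending of the slab shell (0 = flat).
#' @param shadow_count non-negative integer; number of occluding shadow
#'   cones cast between apex and a posterior slab.
#' @param shadow_strength attenuation inside a shadow cone, in \[0, 1\]
#'   (1 removes the signal entirely).
#' @param speckle_sigma non-negative blending weight of the multiplicative
#'   Rayleigh-like speckle field.
#' @param seed integer seed; the phantom is a deterministic function of the
#'   spec including this seed.
#' @param opening_angle_deg full opening angle of the pyramidal frustum
#'   sector in degrees (default 60).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(1.5, 1.5, 1.5),
                         placenta_class = "anterior",
                         slab_thickness_frac = 0.18,
                         slab_lateral_extent_frac = 0.75,
                         curvature = 0.12,
                         shadow_count = 2L,
                         shadow_strength = 0.6,
                         speckle_sigma = 0.35,
                         seed = 1L,
                         opening_angle_deg = 60) {
  spec <- list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    placenta_class = class_code(placenta_class),
    slab_thickness_frac = slab_thickness_frac,
    slab_lateral_extent_frac = slab_lateral_extent_frac,
    curvature = curvature, shadow_count = as.integer(shadow_count),
    shadow_strength = shadow_strength, speckle_sigma = speckle_sigma,
    seed = as.integer(seed), opening_angle_deg = opening_angle_deg)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  s <- spec
  if (length(s$grid_shape) != 3 || any(is.na(s$grid_shape)) || any(s$grid_shape < 8))
    stop_field("grid_shape", "must be an integer triple with components >= 8")
  if (length(s$spacing) != 3 || any(!is.finite(s$spacing)) || any(s$spacing <= 0))
    stop_field("spacing", "must be a positive mm/voxel triple")
  if (!(s$placenta_class %in% 0:2))
    stop_field("placenta_class", "must be anterior (0), none (1) or posterior (2)")
  if (!is.finite(s$slab_thickness_frac) || s$slab_thickness_frac <= 0 ||
      s$slab_thickness_frac >= 0.4)
    stop_field("slab_thickness_frac", "must lie in (0, 0.4)")
  if (!is.finite(s$slab_lateral_extent_frac) || s$slab_lateral_extent_frac <= 0.2 ||
      s$slab_lateral_extent_frac >= 1.0)
    stop_field("slab_lateral_extent_frac", "must lie in (0.2, 1.0)")
  if (!is.finite(s$curvature) || s$curvature < 0)
    stop_field("curvature", "must be a non-negative scalar")
  if (is.na(s$shadow_count) || s$shadow_count < 0)
    stop_field("shadow_count", "must be a non-negative integer")
  if (!is.finite(s$shadow_strength) || s$shadow_strength < 0 || s$shadow_strength > 1)
    stop_field("shadow_strength", "must lie in [0, 1]")
  if (!is.finite(s$speckle_sigma) || s$speckle_sigma < 0)
    stop_field("speckle_sigma", "must be non-negative")
  if (is.na(s$seed)) stop_field("seed", "must be an integer")
  if (!is.finite(s$opening_angle_deg) || s$opening_angle_deg <= 0 ||
      s$opening_angle_deg >= 180)
    stop_field("opening_angle_deg", "must lie in (0, 180)")
  invisible(spec)
}

#' 3D image volume container
#'
#' A scalar intensity grid in \[0, 1\] with voxel spacing in mm, a boolean
#' frustum mask (true inside the ultrasound sector) and the world coordinate
#' of voxel (1,1,1) in mm. Intensities outside the frustum are zero.
#'
#' @param intensities 3D numeric array in \[0, 1\].
#' @param spacing mm/voxel triple.
#' @param frustum logical array of the same shape (defaults to all-true).
#' @param origin world mm coordinate of the first voxel.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(intensities, spacing, frustum = NULL, origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3) stop("intensities must be a 3D array")
  if (is.null(frustum)) frustum <- array(TRUE, dim(intensities))
  if (!identical(dim(intensities), dim(frustum)))
    stop("intensities and frustum shapes disagree")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 frustum = frustum, origin = as.numeric(origin)),
            class = "volume3d")
}

#' Binary segmentation mask aligned to a volume
#'
#' @param voxels logical 3D array.
#' @param spacing mm/voxel triple.
#' @return an object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  structure(list(voxels = voxels != 0, spacing = as.numeric(spacing)),
            class = "seg_mask")
}

## Pyramidal frustum membership for a local grid: apex centred laterally at
## depth 0, half-angle from the opening angle; |x-ax| and |z-az| each bounded
## by tan(half) * depth.
frustum_mask <- function(grid_shape, spacing, opening_angle_deg) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  half <- opening_angle_deg / 2 * pi / 180
  ax <- (nx - 1) / 2 * spacing[1]
  az <- (nz - 1) / 2 * spacing[3]
  xmm <- abs((seq_len(nx) - 1) * spacing[1] - ax)
  dmm <- (seq_len(ny) - 1) * spacing[2]
  zmm <- abs((seq_len(nz) - 1) * spacing[3] - az)
  lim <- tan(half) * dmm + 1e-9 + spacing[2] / 2  # include the apex voxel row
  okx <- outer(xmm, lim, "<=")            # nx x ny
  okz <- outer(zmm, lim, "<=")            # nz x ny
  fr <- array(FALSE, grid_shape)
  for (k in seq_len(nz)) fr[, , k] <- okx & rep(okz[k, ], each = nx)
  fr
}

#' Generate one synthetic placenta phantom
#'
#' Builds an ultrasound-like volume: a pyramidal frustum sector with apex at
#' the top of the depth axis, a curved placenta-like slab placed in the
#' shallow third of the depth range for anterior phantoms and in the deep
#' third for posterior phantoms, depth-dependent attenuation, multiplicative
#' Rayleigh-like speckle and, for posterior phantoms, occluding shadow cones
#' cast from the apex through the region in front of the slab. Class `none`
#' contains no slab and returns an all-false mask.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` ([volume3d]), `mask` ([seg_mask])
#'   and `class_label` (integer code, see [class_code()]).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape; sp <- spec$spacing
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  half <- spec$opening_angle_deg / 2 * pi / 180
  fr <- frustum_mask(gs, sp, spec$opening_angle_deg)

  ax <- (nx - 1) / 2 * sp[1]
  az <- (nz - 1) / 2 * sp[3]
  D <- (ny - 1) * sp[2]
  xv <- (seq_len(nx) - 1) * sp[1] - ax
  dv <- (seq_len(ny) - 1) * sp[2]
  zv <- (seq_len(nz) - 1) * sp[3] - az
  X <- array(rep(xv, times = ny * nz), gs)
  Dp <- array(rep(rep(dv, each = nx), times = nz), gs)
  Z <- array(rep(zv, each = nx * ny), gs)

  with_seed(spec$seed, {
    ## Speckle field is drawn first with fixed RNG consumption so that
    ## phantoms differing only in shadow_count share the same speckle.
    ray <- sqrt(-2 * log(runif(prod(gs))))          # Rayleigh(1) draws
    ray <- ray / sqrt(pi / 2)                       # mean 1
    speckle <- array(1 + spec$speckle_sigma * (ray - 1), gs)

    cls <- spec$placenta_class
    mask <- array(FALSE, gs)
    intens <- array(0.3, gs)                        # background tissue level

    if (cls != PLACENTA_CLASSES[["none"]]) {
      anterior <- cls == PLACENTA_CLASSES[["anterior"]]
      yc <- if (anterior) 0.28 else 0.72            # slab centre depth fraction
      bend <- if (anterior) +1 else -1              # edges away from the wall
      rmax <- tan(half) * D
      r2 <- (X^2 + Z^2) / rmax^2
      ys <- yc * D + bend * spec$curvature * D * r2
      thick <- spec$slab_thickness_frac * D
      latlim <- spec$slab_lateral_extent_frac * tan(half) * pmax(Dp, sp[2])
      mask <- abs(Dp - ys) <= thick / 2 & abs(X) <= latlim & abs(Z) <= latlim & fr
      intens[mask] <- 0.75
    }

    ## Depth-dependent attenuation (time-gain compensation left imperfect).
    atten <- exp(-0.004 * Dp)
    intens <- intens * atten

    ## Occluding shadow cones: fetal parts between apex and a posterior slab.
    if (spec$placenta_class == PLACENTA_CLASSES[["posterior"]] &&
        spec$shadow_count > 0 && spec$shadow_strength > 0) {
      for (i in seq_len(spec$shadow_count)) {
        phix <- runif(1, -0.6, 0.6) * half
        phiz <- runif(1, -0.6, 0.6) * half
        psi <- runif(1, 0.06, 0.16) * half          # cone half-width
        dstart <- runif(1, 0.15, 0.35) * D
        angx <- atan2(X, pmax(Dp, 1e-6))
        angz <- atan2(Z, pmax(Dp, 1e-6))
        inside <- (angx - phix)^2 + (angz - phiz)^2 <= psi^2 & Dp >= dstart
        intens[inside] <- intens[inside] * (1 - spec$shadow_strength)
      }
    }

    intens <- clip01(intens * speckle)
    intens[!fr] <- 0
    mask <- mask & fr
    list(volume = volume3d(intens, sp, fr),
         mask = seg_mask(mask, sp),
         class_label = spec$placenta_class)
  })
}

#' Generate a manifest of phantoms with synthetic patients
#'
#' Emulates a cohort in which each synthetic patient contributes several
#' images of a single placental class. Spec fields are jittered per image
#' within their valid ranges; every image records its own derived seed so
#' the manifest fully determines every phantom. Use [phantom_record()] to
#' materialize a row.
#'
#' @param n_per_class images per class (>= 1).
#' @param spec_template a [phantom_spec()] whose fields are jittered.
#' @param seed integer seed for the cohort.
#' @return a data.frame manifest with columns `id`, `class` (code),
#'   `patient_id`, per-image spec fields and `seed`; the template is
#'   attached as attribute `spec_template`.
#' @export
generate_dataset <- function(n_per_class, spec_template = phantom_spec(),
                             seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  validate_phantom_spec(spec_template)
  with_seed(seed, {
    rows <- list()
    pt <- 0L
    for (cls in PLACENTA_CLASSES) {
      remaining <- n_per_class
      while (remaining > 0) {
        pt <- pt + 1L
        k <- min(sample(2:5, 1), remaining)
        remaining <- remaining - k
        for (j in seq_len(k)) {
          jit <- function(v, f, lo, hi) min(max(v * runif(1, 1 - f, 1 + f), lo), hi)
          rows[[length(rows) + 1L]] <- data.frame(
            class = cls,
            patient_id = sprintf("pt%04d", pt),
            slab_thickness_frac = jit(spec_template$slab_thickness_frac, 0.2, 0.02, 0.39),
            slab_lateral_extent_frac = jit(spec_template$slab_lateral_extent_frac, 0.15, 0.21, 0.99),
            curvature = jit(spec_template$curvature, 0.5, 0, 2),
            shadow_count = if (cls == PLACENTA_CLASSES[["posterior"]])
              spec_template$shadow_count else 0L,
            shadow_strength = spec_template$shadow_strength,
            speckle_sigma = jit(spec_template$speckle_sigma, 0.3, 0, 1),
            seed = sample.int(.Machine$integer.max, 1))
        }
      }
    }
    man <- do.call(rbind, rows)
    man <- cbind(id = sprintf("img%04d", seq_len(nrow(man))), man)
    rownames(man) <- NULL
    attr(man, "spec_template") <- spec_template
    man
  })
}

#' Materialize one manifest row as a phantom
#'
#' @param manifest a manifest from [generate_dataset()].
#' @param i row index.
#' @return as [generate_phantom()], plus `patient_id` and `id`.
#' @export
phantom_record <- function(manifest, i) {
  tmpl <- attr(manifest, "spec_template")
  row <- manifest[i, ]
  spec <- phantom_spec(
    grid_shape = tmpl$grid_shape, spacing = tmpl$spacing,
    placenta_class = row$class,
    slab_thickness_frac = row$slab_thickness_frac,
    slab_lateral_extent_frac = row$slab_lateral_extent_frac,
    curvature = row$curvature, shadow_count = row$shadow_count,
    shadow_strength = row$shadow_strength, speckle_sigma = row$speckle_sigma,
    seed = row$seed, opening_angle_deg = tmpl$opening_angle_deg)
  rec <- generate_phantom(spec)
  rec$patient_id <- row$patient_id
  rec$id <- row$id
  rec
}

#' Write a phantom dataset to disk as NIfTI plus a CSV manifest
#'
#' @param manifest a manifest from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the path of the written manifest CSV, invisibly.
#' @export
write_dataset <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- manifest
  out$image_path <- file.path(dir, paste0(out$id, ".nii.gz"))
  out$mask_path <- ifelse(out$class == PLACENTA_CLASSES[["none"]], "",
                          file.path(dir, paste0(out$id, "_mask.nii.gz")))
  for (i in seq_len(nrow(out))) {
    rec <- phantom_record(manifest, i)
    write_volume(rec$volume, out$image_path[i])
    if (nzchar(out$mask_path[i]))
      write_volume(volume3d(rec$mask$voxels + 0, rec$mask$spacing),
                   out$mask_path[i])
  }
  csv <- file.path(dir, "manifest.csv")
  write.csv(out[, c("image_path", "mask_path", "class", "patient_id")],
            csv, row.names = FALSE)
  invisible(csv)
}

## Centroid depth (mm from apex plane) of a mask; used to verify the
## anterior/posterior geometry contract.
mask_centroid_depth <- function(mask) {
  w <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(w) == 0) return(NA_real_)
  mean((w[, 2] - 1) * mask$spacing[2])
}
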