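## Multi-probe geometry and voxel-based weighted fusion of multi-view
## images and segmentations. World coordinates are mm, right-handed, with
## the shared frustum apex of a probe holder at the world origin.

rot4 <- function(R) { T_ <- diag(4); T_[1:3, 1:3] <- R; T_ }

#' Rigid transforms of a multi-probe holder
#'
#' The holder fixes two or three probes fanned about the shared apex line
#' (the z axis through the apex) at a fixed inter-probe angle: for three
#' probes the rotations are -angle, 0, +angle (the middle transform is the
#' identity); for two probes +/- angle/2.
#'
#' @param n_probes 2 or 3.
#' @param inter_angle_deg angle between adjacent probes (default 30).
#' @return list of 4x4 homogeneous rigid transforms.
#' @export
holder_transforms <- function(n_probes, inter_angle_deg = 30) {
  if (!n_probes %in% c(2L, 3L)) stop("n_probes must be 2 or 3")
  angs <- if (n_probes == 3) c(-1, 0, 1) * inter_angle_deg
  else c(-0.5, 0.5) * inter_angle_deg
  lapply(angs * pi / 180, function(a) {
    R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    rot4(R)
  })
}

#' One probe's view: volume, rigid pose and frustum geometry
#'
#' The local frame of a view follows the phantom convention: the apex is
#' centred laterally at depth zero. The transform maps apex-centred local
#' mm coordinates to world mm: `w = R (p_local - apex_local) + t`, so the
#' apex of every view of a holder lands at the holder origin.
#'
#' @param volume a [volume3d].
#' @param transform rigid 4x4 matrix (rotation block orthonormal, det +1).
#' @param half_angle_deg frustum opening half-angle.
#' @param depth_range mm depth interval (defaults to the volume's depth
#'   extent).
#' @return object of class `probe_view`.
#' @export
probe_view <- function(volume, transform = diag(4), half_angle_deg = 30,
                       depth_range = NULL) {
  R <- transform[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stop("rotation block must be orthonormal with det +1")
  d <- dim(volume$intensities)
  sp <- volume$spacing
  apex_local <- c((d[1] - 1) / 2 * sp[1], 0, (d[3] - 1) / 2 * sp[3])
  depth_range <- depth_range %||% c(0, (d[2] - 1) * sp[2])
  if (diff(depth_range) <= 0) stop("depth range must be positive")
  structure(list(volume = volume, transform = transform,
                 apex_local = apex_local, axis_local = c(0, 1, 0),
                 half_angle = half_angle_deg * pi / 180,
                 depth_range = depth_range),
            class = "probe_view")
}

#' Fusion weight parameters
#'
#' Per-voxel weights decay with lateral angle off the beam axis
#' (`cos^p(theta/theta_max * pi/2)`), with depth (`exp(-lambda * depth)`),
#' and optionally scale with the local image signal so that shadowed views
#' contribute less.
#'
#' @param lateral_sharpness exponent p >= 0 of the angular falloff.
#' @param depth_decay per-mm decay lambda >= 0.
#' @param signal_weighting multiply weights by local intensity + epsilon.
#' @param epsilon small positive floor for the signal term.
#' @return object of class `fusion_params`.
#' @export
fusion_params <- function(lateral_sharpness = 2, depth_decay = 0.01,
                          signal_weighting = TRUE, epsilon = 1e-3) {
  stopifnot(lateral_sharpness >= 0, depth_decay >= 0, epsilon > 0)
  structure(list(lateral_sharpness = lateral_sharpness,
                 depth_decay = depth_decay,
                 signal_weighting = signal_weighting, epsilon = epsilon),
            class = "fusion_params")
}

## World points (n x 3) -> local apex-centred mm coordinates of a view.
world_to_local <- function(view, W) {
  R <- view$transform[1:3, 1:3]
  t_ <- view$transform[1:3, 4]
  sweep(W, 2, t_) %*% R  # (w - t) %*% R == t(R^T (w - t)) rowwise
}

## Local mm (apex-centred) -> continuous 1-based voxel indices.
local_to_index <- function(view, P) {
  sp <- view$volume$spacing
  cbind((P[, 1] + view$apex_local[1]) / sp[1] + 1,
        P[, 2] / sp[2] + 1,
        (P[, 3] + view$apex_local[3]) / sp[3] + 1)
}

## Geometry + signal weights for world points; zero outside the frustum.
view_weights <- function(view, W, params, include_signal = TRUE) {
  P <- world_to_local(view, W)
  depth <- P[, 2]
  ax <- abs(atan2(P[, 1], depth))
  az <- abs(atan2(P[, 3], depth))
  theta <- pmax(ax, az)
  inside <- depth >= view$depth_range[1] & depth <= view$depth_range[2] &
    theta <= view$half_angle & depth >= 0
  w <- numeric(nrow(W))
  if (!any(inside)) return(w)
  th <- theta[inside] / view$half_angle * pi / 2
  w_in <- cos(th)^params$lateral_sharpness *
    exp(-params$depth_decay * depth[inside])
  if (include_signal && params$signal_weighting) {
    idx <- local_to_index(view, P[inside, , drop = FALSE])
    sig <- interp_trilinear(view$volume$intensities, idx)
    w_in <- w_in * (sig + params$epsilon)
  }
  w[inside] <- w_in
  w
}

#' Fusion weight of one view at world points
#'
#' @param view a [probe_view()].
#' @param world_point n x 3 matrix (or length-3 vector) of world mm points.
#' @param params a [fusion_params()].
#' @return numeric weights, zero outside the view's frustum.
#' @export
fusion_weight <- function(view, world_point, params = fusion_params()) {
  if (is.null(dim(world_point))) world_point <- matrix(world_point, 1)
  view_weights(view, world_point, params, include_signal = TRUE)
}

## Output grid covering the transformed frusta of all views.
fusion_grid <- function(views, out_spacing = NULL) {
  sp <- out_spacing %||% rep(min(vapply(views, function(v) min(v$volume$spacing), 1)), 3)
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (v in views) {
    d <- dim(v$volume$intensities)
    vsp <- v$volume$spacing
    w <- which(v$volume$frustum, arr.ind = TRUE)
    if (nrow(w) == 0) w <- voxel_index_grid(d)
    P <- cbind((w[, 1] - 1) * vsp[1] - v$apex_local[1],
               (w[, 2] - 1) * vsp[2],
               (w[, 3] - 1) * vsp[3] - v$apex_local[3])
    Wd <- P %*% t(v$transform[1:3, 1:3]) +
      matrix(v$transform[1:3, 4], nrow(P), 3, byrow = TRUE)
    lo <- pmin(lo, apply(Wd, 2, min))
    hi <- pmax(hi, apply(Wd, 2, max))
  }
  dims <- pmax(as.integer(ceiling((hi - lo) / sp)) + 1L, 1L)
  list(origin = lo, spacing = sp, dims = dims)
}

fuse_core <- function(views, value_arrays, params, include_signal,
                      out_grid = NULL) {
  if (length(views) == 0) stop("empty view list")
  grid <- out_grid %||% fusion_grid(views)
  g <- voxel_index_grid(grid$dims)
  W <- sweep(sweep(g, 2, c(1, 1, 1)) %*% diag(grid$spacing), 2, grid$origin, "+")
  acc <- numeric(nrow(W))
  wsum <- numeric(nrow(W))
  cov <- integer(nrow(W))
  for (i in seq_along(views)) {
    v <- views[[i]]
    w <- view_weights(v, W, params, include_signal = include_signal)
    pos <- w > 0
    if (!any(pos)) next
    idx <- local_to_index(v, world_to_local(v, W[pos, , drop = FALSE]))
    val <- interp_trilinear(value_arrays[[i]], idx)
    acc[pos] <- acc[pos] + w[pos] * val
    wsum[pos] <- wsum[pos] + w[pos]
    cov[pos] <- cov[pos] + 1L
  }
  fused <- ifelse(wsum > 0, acc / pmax(wsum, .Machine$double.eps), 0)
  list(values = array(fused, grid$dims),
       weight_sum = array(wsum, grid$dims),
       coverage = array(cov, grid$dims),
       spacing = grid$spacing, origin = grid$origin)
}

#' Weighted fusion of multi-view images
#'
#' Per output voxel the fused intensity is the weight-normalized mean of
#' the trilinearly resampled view intensities,
#' `F = sum_i w_i I_i / sum_i w_i`; voxels covered by no view are
#' background. The output grid is the axis-aligned bounding box of all
#' transformed frusta at the minimum input spacing (unless overridden).
#'
#' @param views list of [probe_view()].
#' @param params a [fusion_params()].
#' @param out_grid optional list(origin, spacing, dims).
#' @return object of class `fused_volume` with `intensities`,
#'   `weight_sum`, `coverage`, `spacing`, `origin`.
#' @export
fuse_images <- function(views, params = fusion_params(), out_grid = NULL) {
  r <- fuse_core(views, lapply(views, function(v) v$volume$intensities),
                 params, include_signal = TRUE, out_grid = out_grid)
  structure(list(intensities = r$values, weight_sum = r$weight_sum,
                 coverage = r$coverage, spacing = r$spacing,
                 origin = r$origin), class = "fused_volume")
}

#' Fuse per-view segmentation probabilities into a multi-view mask
#'
#' Combines one probability grid per view (aligned to that view's volume)
#' by the same geometric weights as [fuse_images()] with the signal term
#' disabled, then thresholds the weighted mean probability; a tie at the
#' threshold resolves to foreground.
#'
#' @param seg_probs list of probability grids, one per view.
#' @param views list of [probe_view()].
#' @param params a [fusion_params()].
#' @param threshold foreground threshold (default 0.5).
#' @param out_grid optional output grid (list(origin, spacing, dims)).
#' @return a [seg_mask()] on the fused grid, with the fused probability
#'   grid attached as attribute `probabilities`.
#' @export
fuse_segmentations <- function(seg_probs, views, params = fusion_params(),
                               threshold = 0.5, out_grid = NULL) {
  if (length(seg_probs) != length(views))
    stop("need exactly one probability grid per view")
  probs <- lapply(seg_probs, function(p) {
    if (inherits(p, "seg_mask")) p$voxels + 0
    else if (inherits(p, "volume3d")) p$intensities
    else p + 0
  })
  r <- fuse_core(views, probs, params, include_signal = FALSE,
                 out_grid = out_grid)
  m <- seg_mask(r$values >= threshold & r$weight_sum > 0, r$spacing)
  attr(m, "probabilities") <- r$values
  attr(m, "origin") <- r$origin
  m
}

#' Read / write 4x4 transforms as plain text
#'
#' @param path text file with a whitespace-separated 4x4 matrix (world mm).
#' @export
read_transform <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(4L, 4L))) stop("expected a 4x4 matrix")
  m
}

#' @rdname read_transform
#' @param transform 4x4 matrix.
#' @export
write_transform <- function(transform, path) {
  write.table(transform, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
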