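# Shared fixtures: tiny network configs, small phantoms, and independent
# brute-force oracles used across test files.

tiny_config <- function(shape = c(16L, 16L, 16L), features = c(4L, 8L, 16L),
                        attention_level = 2L) {
  network_config(n_levels = length(features), features_per_level = features,
                 input_shape = shape, attention_level = attention_level,
                 gn_groups = 2L)
}

small_phantom <- function(class = "anterior", seed = 1L, shape = c(32, 32, 32),
                          ...) {
  generate_phantom(phantom_spec(grid_shape = shape, spacing = c(3, 3, 3),
                                placenta_class = class, seed = seed, ...))
}

rand_mask <- function(dims, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seg_mask(array(runif(prod(dims)) < p, dims), c(1, 1, 1))
}

# Independent set-arithmetic overlap oracles (voxel index sets).
oracle_dice <- function(a, b) {
  ia <- which(a$voxels); ib <- which(b$voxels)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}
oracle_iou <- function(a, b) {
  ia <- which(a$voxels); ib <- which(b$voxels)
  u <- length(union(ia, ib))
  if (u == 0) return(1)
  length(intersect(ia, ib)) / u
}

# Independent double-loop GED oracle (distance 1 - overlap, with the
# empty-set conventions of the package's pairwise distance).
oracle_ged <- function(masks_a, masks_b, distance = "dice") {
  dd <- function(x, y) {
    ov <- if (distance == "dice") oracle_dice(x, y) else oracle_iou(x, y)
    1 - ov
  }
  cross <- 0
  for (x in masks_a) for (y in masks_b) cross <- cross + dd(x, y)
  cross <- cross / (length(masks_a) * length(masks_b))
  wa <- 0
  for (x in masks_a) for (y in masks_a) wa <- wa + dd(x, y)
  wa <- wa / length(masks_a)^2
  wb <- 0
  for (x in masks_b) for (y in masks_b) wb <- wb + dd(x, y)
  wb <- wb / length(masks_b)^2
  max(0, 2 * cross - wa - wb)
}

# Resample a "world" phantom volume into the local grid of a probe view
# with the given rigid transform (emulating what that probe would image).
view_of_world <- function(world, transform, grid_shape = NULL,
                          spacing = NULL, half_angle_deg = 30) {
  if (!inherits(world, "volume3d") && !is.null(world$volume))
    world <- world$volume
  grid_shape <- if (is.null(grid_shape)) dim(world$intensities) else grid_shape
  spacing <- if (is.null(spacing)) world$spacing else spacing
  blank <- volume3d(array(0, grid_shape), spacing)
  v <- probe_view(blank, transform, half_angle_deg = half_angle_deg)
  g <- plaseg:::voxel_index_grid(grid_shape)
  local_mm <- cbind((g[, 1] - 1) * spacing[1] - v$apex_local[1],
                    (g[, 2] - 1) * spacing[2],
                    (g[, 3] - 1) * spacing[3] - v$apex_local[3])
  R <- transform[1:3, 1:3]
  world_mm <- local_mm %*% t(R)
  apex_w <- c((dim(world$intensities)[1] - 1) / 2 * world$spacing[1], 0,
              (dim(world$intensities)[3] - 1) / 2 * world$spacing[3])
  idx <- cbind((world_mm[, 1] + apex_w[1]) / world$spacing[1] + 1,
               world_mm[, 2] / world$spacing[2] + 1,
               (world_mm[, 3] + apex_w[3]) / world$spacing[3] + 1)
  fr <- frustum_of(grid_shape, spacing, half_angle_deg)
  vi <- array(plaseg:::interp_trilinear(world$intensities, idx), grid_shape)
  vi[!fr] <- 0
  list(volume = volume3d(vi, spacing, fr),
       sample_world_mask = function(world_mask) {
         m <- array(plaseg:::interp_nearest(world_mask$voxels + 0, idx) > 0.5,
                    grid_shape)
         m & fr
       })
}

frustum_of <- function(grid_shape, spacing, half_angle_deg) {
  plaseg:::frustum_mask(grid_shape, spacing, 2 * half_angle_deg)
}
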