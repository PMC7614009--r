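test_that("holder transforms realize the fan geometry", {
  tr3 <- holder_transforms(3, 30)
  expect_equal(tr3[[2]], diag(4))
  expect_equal(tr3[[3]] %*% tr3[[1]], diag(4), tolerance = 1e-12)
  tr2 <- holder_transforms(2, 30)
  ax <- lapply(tr2, function(T_) drop(T_[1:3, 1:3] %*% c(0, 1, 0)))
  ang <- acos(sum(ax[[1]] * ax[[2]])) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-10)
  expect_error(holder_transforms(4), "2 or 3")
})

test_that("fusion weights vanish outside the frustum and normalize on-axis", {
  vol <- small_phantom("anterior", seed = 1, shape = c(32, 32, 32))$volume
  v <- probe_view(vol, half_angle_deg = 30)
  p_off <- fusion_params(signal_weighting = FALSE, depth_decay = 0)
  # far outside any frustum
  expect_equal(fusion_weight(v, c(500, 10, 0), p_off), 0)
  expect_equal(fusion_weight(v, c(0, -5, 0), p_off), 0)
  # on-axis at the apex
  expect_equal(fusion_weight(v, c(0, 0, 0), p_off), 1)
  # at the lateral frustum edge the angular falloff reaches zero
  d <- 40
  edge <- c(tan(30 * pi / 180) * d * 0.999, d, 0)
  expect_lt(fusion_weight(v, edge, p_off), 0.01)
  inside <- c(0, d, 0)
  expect_gt(fusion_weight(v, inside, p_off), 0.5)
  # weight decays with lateral angle and with depth
  w_mid <- fusion_weight(v, c(tan(15 * pi / 180) * d, d, 0), p_off)
  expect_true(fusion_weight(v, inside, p_off) > w_mid && w_mid >
                fusion_weight(v, edge, p_off))
  p_dep <- fusion_params(signal_weighting = FALSE, depth_decay = 0.05)
  expect_gt(fusion_weight(v, c(0, 10, 0), p_dep),
            fusion_weight(v, c(0, 50, 0), p_dep))
})

test_that("single-view fusion is the identity and duplicates are idempotent", {
  r <- small_phantom("anterior", seed = 2, shape = c(32, 32, 32),
                     speckle_sigma = 0.2)
  v <- probe_view(r$volume, half_angle_deg = 30)
  params <- fusion_params(signal_weighting = FALSE)
  f1 <- fuse_images(list(v), params)
  # compare on the voxels of the original grid: world position of voxel
  # (i,j,k) is ((i-1)s - ax, (j-1)s, (k-1)s - az)
  idx <- which(r$volume$frustum & r$volume$intensities > 0, arr.ind = TRUE)
  sp <- r$volume$spacing
  apex <- v$apex_local
  wpts <- cbind((idx[, 1] - 1) * sp[1] - apex[1],
                (idx[, 2] - 1) * sp[2],
                (idx[, 3] - 1) * sp[3] - apex[3])
  # stay safely inside the analytic frustum (the voxelized sector mask is
  # half a voxel wider at its rim, where the weight is legitimately zero)
  theta <- pmax(abs(atan2(wpts[, 1], wpts[, 2])),
                abs(atan2(wpts[, 3], wpts[, 2])))
  keep <- theta <= 0.9 * v$half_angle &
    wpts[, 2] >= 1.5 & wpts[, 2] <= v$depth_range[2] - 1.5
  idx <- idx[keep, , drop = FALSE]
  wpts <- wpts[keep, , drop = FALSE]
  gi <- cbind((wpts[, 1] - f1$origin[1]) / f1$spacing[1] + 1,
              (wpts[, 2] - f1$origin[2]) / f1$spacing[2] + 1,
              (wpts[, 3] - f1$origin[3]) / f1$spacing[3] + 1)
  fused_vals <- plaseg:::interp_trilinear(f1$intensities, gi)
  expect_equal(fused_vals, r$volume$intensities[idx], tolerance = 1e-6)
  # duplicated views change nothing (weighted mean of equals)
  f2 <- fuse_images(list(v, v), params)
  expect_equal(f2$intensities, f1$intensities, tolerance = 1e-12)
  expect_true(all(f2$coverage[f2$weight_sum > 0] >= 1))
  # permutation invariance with a second, rotated view
  r2 <- small_phantom("anterior", seed = 3, shape = c(32, 32, 32))
  v2 <- probe_view(r2$volume, holder_transforms(3, 30)[[3]],
                   half_angle_deg = 30)
  grid <- plaseg:::fusion_grid(list(v, v2))
  fa <- fuse_images(list(v, v2), params, out_grid = grid)
  fb <- fuse_images(list(v2, v), params, out_grid = grid)
  expect_equal(fa$intensities, fb$intensities, tolerance = 1e-12)
  expect_error(fuse_images(list()), "empty")
})

test_that("weighted-mean arithmetic: signal weights 1:3 mix 0 and 1 to 0.75", {
  d <- c(24, 24, 24)
  fr <- frustum_of(d, c(2, 2, 2), 30)
  dark <- volume3d(array(0, d) * fr, c(2, 2, 2), fr)
  bright <- volume3d(array(1, d) * (fr + 0), c(2, 2, 2), fr)
  # epsilon 0.5: weights (0 + 0.5) : (1 + 0.5) = 1 : 3 at equal geometry
  params <- fusion_params(lateral_sharpness = 0, depth_decay = 0,
                          signal_weighting = TRUE, epsilon = 0.5)
  views <- list(probe_view(dark), probe_view(bright))
  f <- fuse_images(views, params)
  interior <- f$coverage == 2 & f$weight_sum > 0
  expect_gt(sum(interior), 100)
  expect_equal(unique(round(f$intensities[interior], 10)), 0.75)
})

test_that("multi-view fusion extends the field of view of a wide slab", {
  world_spec <- phantom_spec(grid_shape = c(48, 32, 32), spacing = c(3, 3, 3),
                             placenta_class = "anterior",
                             slab_lateral_extent_frac = 0.95,
                             opening_angle_deg = 110, speckle_sigma = 0.1,
                             seed = 5)
  world <- generate_phantom(world_spec)
  transforms <- holder_transforms(3, 30)
  views <- list(); probs <- list(); single_vols <- numeric(3)
  for (i in 1:3) {
    vw <- view_of_world(world, transforms[[i]], grid_shape = c(32, 32, 32),
                        spacing = c(3, 3, 3), half_angle_deg = 15)
    mask_i <- vw$sample_world_mask(world$mask)
    views[[i]] <- probe_view(vw$volume, transforms[[i]], half_angle_deg = 15)
    probs[[i]] <- mask_i + 0
    single_vols[i] <- sum(mask_i) * prod(c(3, 3, 3)) / 1000
  }
  fused <- fuse_segmentations(probs, views,
                              fusion_params(signal_weighting = FALSE))
  fused_vol <- placental_volume(fused)
  expect_gt(fused_vol, max(single_vols))
})

test_that("probability fusion averages and breaks the 0.5 tie to foreground", {
  d <- c(16, 16, 16)
  fr <- frustum_of(d, c(3, 3, 3), 30)
  vol <- volume3d(array(0.5, d) * (fr + 0), c(3, 3, 3), fr)
  views <- list(probe_view(vol), probe_view(vol))
  ones <- array(1, d); zeros <- array(0, d)
  params <- fusion_params(lateral_sharpness = 0, depth_decay = 0,
                          signal_weighting = FALSE)
  m <- fuse_segmentations(list(ones, zeros), views, params)
  probs <- attr(m, "probabilities")
  covered <- m$voxels | (probs > 0)
  two_view <- plaseg:::fuse_core(views, list(ones, ones), params,
                                 include_signal = FALSE)$coverage == 2
  # equal weights, probabilities 1 and 0 -> fused probability 0.5 -> foreground
  expect_true(all(abs(probs[two_view] - 0.5) < 1e-9))
  expect_true(all(m$voxels[two_view]))
  expect_error(fuse_segmentations(list(ones), views, params), "one probability")
})

test_that("signal weighting pulls shadowed voxels toward the clean view", {
  shadowed <- small_phantom("posterior", seed = 6, shadow_count = 3,
                            shadow_strength = 0.85)
  clean <- small_phantom("posterior", seed = 6, shadow_count = 0)
  v_sh <- probe_view(shadowed$volume)
  v_cl <- probe_view(clean$volume)
  grid <- plaseg:::fusion_grid(list(v_sh, v_cl))
  f_on <- fuse_images(list(v_sh, v_cl),
                      fusion_params(signal_weighting = TRUE, epsilon = 1e-3),
                      out_grid = grid)
  f_off <- fuse_images(list(v_sh, v_cl),
                       fusion_params(signal_weighting = FALSE),
                       out_grid = grid)
  # voxels strongly attenuated in the shadowed view but bright in the clean
  att <- clean$volume$intensities - shadowed$volume$intensities > 0.25
  expect_gt(sum(att), 50)
  # fused-with-signal should sit closer to the clean intensity there
  idx <- which(att, arr.ind = TRUE)
  sp <- clean$volume$spacing
  apex <- v_cl$apex_local
  gi <- cbind(((idx[, 1] - 1) * sp[1] - apex[1] - grid$origin[1]) / grid$spacing[1] + 1,
              ((idx[, 2] - 1) * sp[2] - grid$origin[2]) / grid$spacing[2] + 1,
              ((idx[, 3] - 1) * sp[3] - apex[3] - grid$origin[3]) / grid$spacing[3] + 1)
  fon <- plaseg:::interp_trilinear(f_on$intensities, gi)
  foff <- plaseg:::interp_trilinear(f_off$intensities, gi)
  cl_int <- clean$volume$intensities[att]
  expect_lt(mean(abs(fon - cl_int)), mean(abs(foff - cl_int)))
})
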