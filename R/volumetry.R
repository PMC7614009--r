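## Placental volumetry: volume extraction from masks, a gestational-age
## reference growth curve, and Bland-Altman agreement analysis.

#' Placental volume of a mask in mL
#'
#' Foreground voxel count times voxel volume (mm^3) divided by 1000.
#' Partial-volume effects are ignored (pure voxel counting).
#'
#' @param mask a [seg_mask] or logical array.
#' @param spacing mm/voxel triple (taken from the mask when omitted).
#' @return volume in mL.
#' @export
placental_volume <- function(mask, spacing = NULL) {
  v <- mask_voxels(mask)
  sp <- mask_spacing(mask, spacing)
  sum(v) * prod(sp) / 1000
}

#' Reference placental volume from gestational age
#'
#' MRI-derived growth curve
#' `f(x) = -0.02 x^3 + 1.6 x^2 - 13.3 x + 8.3` (mL) with `x` the
#' gestational age in weeks; the study range is 19-33 weeks and evaluation
#' outside it raises a warning.
#'
#' @param ga_weeks gestational age in weeks.
#' @return reference volume in mL.
#' @export
reference_volume <- function(ga_weeks) {
  if (any(ga_weeks < 19 | ga_weeks > 33))
    warning("gestational age outside the supported 19-33 week range")
  -0.02 * ga_weeks^3 + 1.6 * ga_weeks^2 - 13.3 * ga_weeks + 8.3
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` summarized by their mean, sample standard deviation
#' (n - 1) and the 1.96-SD limits of agreement.
#'
#' @param pairs two-column matrix/data.frame of paired volumes, or a
#'   numeric vector `a` with `b` supplied separately.
#' @param b optional second vector.
#' @return list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n_pairs`.
#' @export
bland_altman <- function(pairs, b = NULL) {
  if (!is.null(b)) pairs <- cbind(pairs, b)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  d <- pairs[, 1] - pairs[, 2]
  m <- mean(d)
  s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n_pairs = nrow(pairs))
}
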