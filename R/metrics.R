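## Segmentation overlap and surface metrics, classification scores and the
## paired Wilcoxon effect-size protocol.

mask_voxels <- function(x) {
  if (inherits(x, "seg_mask")) x$voxels
  else if (inherits(x, "volume3d")) x$intensities != 0
  else x != 0
}
mask_spacing <- function(x, spacing = NULL) {
  if (!is.null(spacing)) as.numeric(spacing)
  else if (inherits(x, "seg_mask")) x$spacing
  else c(1, 1, 1)
}
check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
}

#' Overlap metrics: Dice and IoU
#'
#' `dice(A, B) = 2|A n B| / (|A| + |B|)` and
#' `iou(A, B) = |A n B| / |A u B|`; two empty masks score 1 by convention.
#'
#' @param a,b binary masks ([seg_mask] or logical arrays) of equal shape.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  va <- mask_voxels(a); vb <- mask_voxels(b)
  check_same_shape(va, vb)
  sa <- sum(va); sb <- sum(vb)
  if (sa + sb == 0) return(1)
  2 * sum(va & vb) / (sa + sb)
}

#' @rdname dice
#' @export
iou <- function(a, b) {
  va <- mask_voxels(a); vb <- mask_voxels(b)
  check_same_shape(va, vb)
  u <- sum(va | vb)
  if (u == 0) return(1)
  sum(va & vb) / u
}

## Surface voxels: foreground with at least one face-adjacent background
## neighbour (voxels on the grid boundary count as surface).
surface_voxels <- function(v) {
  d <- dim(v)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    s <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx
    if (by == 1) { idx[[ax]] <- seq_len(d[ax] - 1) + 1; src[[ax]] <- seq_len(d[ax] - 1) }
    else { idx[[ax]] <- seq_len(d[ax] - 1); src[[ax]] <- seq_len(d[ax] - 1) + 1 }
    s[idx[[1]], idx[[2]], idx[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
    acc & s
  }
  for (ax in 1:3) for (by in c(-1, 1)) interior <- shift_and(interior, ax, by)
  v & !interior
}

#' Directed surface distances between two masks
#'
#' Surface voxels are foreground voxels with a face-adjacent background
#' neighbour. Distances are Euclidean in mm, honouring anisotropic voxel
#' spacing, between surface voxel centres. Both directed multisets are
#' returned.
#'
#' @param a,b nonempty binary masks of equal shape.
#' @param spacing mm/voxel triple (taken from `a` when a [seg_mask]).
#' @return list with numeric vectors `a_to_b` and `b_to_a`.
#' @export
surface_distances <- function(a, b, spacing = NULL) {
  va <- mask_voxels(a); vb <- mask_voxels(b)
  check_same_shape(va, vb)
  sp <- mask_spacing(a, spacing)
  if (sum(va) == 0 || sum(vb) == 0)
    stop("surface undefined for an empty mask")
  pa <- which(surface_voxels(va), arr.ind = TRUE)
  pb <- which(surface_voxels(vb), arr.ind = TRUE)
  pa <- sweep(pa, 2, sp, "*")
  pb <- sweep(pb, 2, sp, "*")
  list(a_to_b = cpp_min_dists(pa, pb), b_to_a = cpp_min_dists(pb, pa))
}

#' Average surface distance (mm)
#'
#' Mean of the pooled union of both directed surface-distance multisets.
#'
#' @inheritParams surface_distances
#' @return non-negative mm scalar.
#' @export
asd <- function(a, b, spacing = NULL) {
  sd_ <- surface_distances(a, b, spacing)
  mean(c(sd_$a_to_b, sd_$b_to_a))
}

#' Robust 95th-percentile Hausdorff distance (mm)
#'
#' Maximum of the two directed 95th percentiles; robust to boundary
#' outliers compared to the exact Hausdorff distance.
#'
#' @inheritParams surface_distances
#' @return non-negative mm scalar.
#' @export
rhd95 <- function(a, b, spacing = NULL) {
  sd_ <- surface_distances(a, b, spacing)
  max(quantile(sd_$a_to_b, 0.95, names = FALSE),
      quantile(sd_$b_to_a, 0.95, names = FALSE))
}

#' Full segmentation metrics for one mask pair
#'
#' @inheritParams surface_distances
#' @return data.frame row with dice, iou, asd_mm, rhd95_mm (surface metrics
#'   NA when either mask is empty).
#' @export
metrics_report <- function(a, b, spacing = NULL) {
  am <- NA_real_; rh <- NA_real_
  if (sum(mask_voxels(a)) > 0 && sum(mask_voxels(b)) > 0) {
    sd_ <- surface_distances(a, b, spacing)
    am <- mean(c(sd_$a_to_b, sd_$b_to_a))
    rh <- max(quantile(sd_$a_to_b, 0.95, names = FALSE),
              quantile(sd_$b_to_a, 0.95, names = FALSE))
  }
  data.frame(dice = dice(a, b), iou = iou(a, b), asd_mm = am, rhd95_mm = rh)
}

#' One-vs-rest classification scores
#'
#' For each class: balanced accuracy `(sensitivity + specificity)/2`,
#' precision `TP/(TP+FP)` and F1 (harmonic mean of precision and recall).
#' Classes absent from the labels get NaN scores with a warning.
#'
#' @param predictions,labels integer class codes of equal length.
#' @param classes class codes to score (default 0/1/2).
#' @return data.frame with one row per class.
#' @export
classification_scores <- function(predictions, labels, classes = 0:2) {
  stopifnot(length(predictions) == length(labels))
  rows <- lapply(classes, function(k) {
    tp <- sum(predictions == k & labels == k)
    fp <- sum(predictions == k & labels != k)
    fn <- sum(predictions != k & labels == k)
    tn <- sum(predictions != k & labels != k)
    if (tp + fn == 0) {
      warning(sprintf("class %d absent from labels; recall undefined", k))
      return(data.frame(class = k, balanced_accuracy = NaN,
                        precision = NaN, f1 = NaN))
    }
    sens <- tp / (tp + fn)
    spec <- if (fp + tn > 0) tn / (fp + tn) else NaN
    prec <- if (tp + fp > 0) tp / (tp + fp) else NaN
    f1 <- if (is.finite(prec) && prec + sens > 0) 2 * prec * sens / (prec + sens)
    else if (isTRUE(prec + sens == 0)) 0 else NaN
    data.frame(class = k, balanced_accuracy = (sens + spec) / 2,
               precision = prec, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Paired Wilcoxon signed-rank test with effect size
#'
#' Signed-rank test with the normal approximation (tie-corrected, zero
#' differences dropped); the effect size is `|z| / sqrt(N)` with N the
#' number of pairs, categorized as small (r <= 0.3), moderate
#' (0.3 < r < 0.5) or strong (r >= 0.5). All-zero differences give the
#' degenerate result r = 0.
#'
#' @param scores_a,scores_b paired score vectors (N >= 5).
#' @return list with `z`, `n_pairs`, `r`, `category` and `p_value`.
#' @export
paired_wilcoxon_effect <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("paired vectors differ in length")
  n_pairs <- length(scores_a)
  if (n_pairs < 5) stop("need at least 5 pairs")
  d <- scores_a - scores_b
  dz <- d[d != 0]
  if (length(dz) == 0) {
    return(list(z = 0, n_pairs = n_pairs, r = 0,
                category = "small", p_value = 1))
  }
  n <- length(dz)
  rk <- rank(abs(dz))
  w <- sum(rk[dz > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sig2)
  r <- abs(z) / sqrt(n_pairs)
  list(z = z, n_pairs = n_pairs, r = r, category = effect_category(r),
       p_value = 2 * pnorm(-abs(z)))
}

effect_category <- function(r) {
  if (r <= 0.3) "small" else if (r < 0.5) "moderate" else "strong"
}

#' Relative change in percent
#'
#' `100 * (value - baseline) / baseline`; the sign convention follows the
#' direction of improvement for "higher is better" scores. For error
#' metrics where lower is better, pass `lower_is_better = TRUE` to report
#' the reduction `100 * (baseline - value) / baseline`.
#'
#' @param baseline reference value.
#' @param value comparison value.
#' @param lower_is_better report reduction instead of increase.
#' @return percentage.
#' @export
pct_change <- function(baseline, value, lower_is_better = FALSE) {
  if (lower_is_better) 100 * (baseline - value) / baseline
  else 100 * (value - baseline) / baseline
}
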