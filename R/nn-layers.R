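## Minimal 3D CNN engine with explicit backpropagation.
##
## Feature maps travel as nvox x C matrices (R array linearization, x
## fastest) with the spatial dims tracked alongside. Every primitive layer
## is an environment holding its parameters, accumulated gradients and the
## forward cache of the most recent call; forward and backward of one input
## must therefore be paired before the next forward (gradients are
## accumulated across such pairs to form mini-batch gradients).

new_layer <- function(type, params = list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) p * 0)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  e
}

## Weights are stored as (cin * k^3) x cout so the forward pass is a single
## GEMM on the nvox x (cin * k^3) patch matrix.
ly_conv <- function(cin, cout, k = 3) {
  k3 <- k^3
  sdv <- sqrt(2 / (cin * k3))
  new_layer("conv",
            params = list(W = matrix(rnorm(cout * cin * k3, 0, sdv), cin * k3),
                          b = numeric(cout)),
            extra = list(cin = cin, cout = cout, k = k, pad = k %/% 2))
}

conv_fwd <- function(ly, x, dims) {
  cols <- if (ly$k == 1) x else cpp_im2col3(x, as.integer(dims), ly$k, ly$pad)
  ly$cols <- cols
  ly$dims <- dims
  sweep(cols %*% ly$params$W, 2, ly$params$b, "+")
}

conv_bwd <- function(ly, dy) {
  ly$grads$W <- ly$grads$W + crossprod(ly$cols, dy)
  ly$grads$b <- ly$grads$b + colSums(dy)
  dcols <- tcrossprod(dy, ly$params$W)
  if (ly$k == 1) dcols
  else cpp_col2im3(dcols, as.integer(ly$dims), ly$cin, ly$k, ly$pad)
}

## Group normalization over (voxels x channels-in-group); groups = 1 gives a
## layer norm over the whole feature map with per-channel affine parameters.
ly_gn <- function(ch, groups = min(8L, ch)) {
  stopifnot(ch %% groups == 0)
  new_layer("gn", params = list(gamma = rep(1, ch), beta = rep(0, ch)),
            extra = list(ch = ch, groups = groups, eps = 1e-5))
}

gn_fwd <- function(ly, x) {
  cg <- ly$ch / ly$groups
  xhat <- x
  istd <- numeric(ly$groups)
  for (g in seq_len(ly$groups)) {
    cols <- ((g - 1) * cg + 1):(g * cg)
    v <- x[, cols, drop = FALSE]
    m <- mean(v)
    va <- mean((v - m)^2)
    istd[g] <- 1 / sqrt(va + ly$eps)
    xhat[, cols] <- (v - m) * istd[g]
  }
  ly$xhat <- xhat
  ly$istd <- istd
  sweep(sweep(xhat, 2, ly$params$gamma, "*"), 2, ly$params$beta, "+")
}

gn_bwd <- function(ly, dy) {
  cg <- ly$ch / ly$groups
  ly$grads$gamma <- ly$grads$gamma + colSums(dy * ly$xhat)
  ly$grads$beta <- ly$grads$beta + colSums(dy)
  dx <- dy
  for (g in seq_len(ly$groups)) {
    cols <- ((g - 1) * cg + 1):(g * cg)
    dxh <- sweep(dy[, cols, drop = FALSE], 2, ly$params$gamma[cols], "*")
    xh <- ly$xhat[, cols, drop = FALSE]
    n <- length(xh)
    dx[, cols] <- ly$istd[g] / n *
      (n * dxh - sum(dxh) - xh * sum(dxh * xh))
  }
  dx
}

ly_relu <- function() new_layer("relu")
relu_fwd <- function(ly, x) { ly$mask <- x > 0; x * ly$mask }
relu_bwd <- function(ly, dy) dy * ly$mask

ly_sigmoid <- function() new_layer("sigmoid")
sigmoid_fwd <- function(ly, x) { y <- 1 / (1 + exp(-x)); ly$y <- y; y }
sigmoid_bwd <- function(ly, dy) dy * ly$y * (1 - ly$y)

ly_dropout <- function(rate) new_layer("dropout", extra = list(rate = rate))
dropout_fwd <- function(ly, x, active) {
  if (!active || ly$rate <= 0) { ly$mask <- NULL; return(x) }
  keep <- 1 - ly$rate
  ly$mask <- matrix((runif(length(x)) < keep) / keep, nrow(x))
  x * ly$mask
}
dropout_bwd <- function(ly, dy) if (is.null(ly$mask)) dy else dy * ly$mask

ly_pool <- function() new_layer("pool")
pool_fwd <- function(ly, x, dims) {
  r <- cpp_maxpool3(x, as.integer(dims))
  ly$idx <- r$idx
  ly$nvox <- nrow(x)
  r$y
}
pool_bwd <- function(ly, dy) cpp_maxpool3_bw(dy, ly$idx, ly$nvox)

## Nearest-neighbour x2 upsampling via a cached child -> parent index map.
ly_up <- function() new_layer("up")
up_map <- function(dims) {
  # child grid has dims*2; parent voxel of child index c is (c+1) %/% 2
  cd <- dims * 2L
  g <- voxel_index_grid(cd)
  pi_ <- (g + 1L) %/% 2L
  pi_[, 1] + (pi_[, 2] - 1L) * dims[1] + (pi_[, 3] - 1L) * dims[1] * dims[2]
}
up_fwd <- function(ly, x, dims) {
  key <- paste(dims, collapse = "x")
  if (is.null(ly$maps)) ly$maps <- list()
  if (is.null(ly$maps[[key]])) ly$maps[[key]] <- up_map(as.integer(dims))
  ly$key <- key
  x[ly$maps[[key]], , drop = FALSE]
}
up_bwd <- function(ly, dy) {
  m <- ly$maps[[ly$key]]
  rowsum(dy, m, reorder = TRUE)
}

ly_linear <- function(nin, nout) {
  new_layer("linear",
            params = list(W = matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout),
                          b = numeric(nout)),
            extra = list(nin = nin, nout = nout))
}
linear_fwd <- function(ly, x) { ly$x <- x; drop(ly$params$W %*% x + ly$params$b) }
linear_bwd <- function(ly, dy) {
  ly$grads$W <- ly$grads$W + outer(dy, ly$x)
  ly$grads$b <- ly$grads$b + dy
  drop(crossprod(ly$params$W, dy))
}

## Residual block: conv3-GN-ReLU-conv3-GN plus identity shortcut (1x1
## projection conv when the channel width changes), then ReLU.
res_block <- function(cin, cout, groups = 8L) {
  e <- new.env(parent = emptyenv())
  e$type <- "resblock"
  e$conv1 <- ly_conv(cin, cout)
  e$gn1 <- ly_gn(cout, min(groups, cout))
  e$relu1 <- ly_relu()
  e$conv2 <- ly_conv(cout, cout)
  e$gn2 <- ly_gn(cout, min(groups, cout))
  e$proj <- if (cin != cout) ly_conv(cin, cout, k = 1) else NULL
  e$relu2 <- ly_relu()
  e
}

rb_fwd <- function(rb, x, dims) {
  h <- relu_fwd(rb$relu1, gn_fwd(rb$gn1, conv_fwd(rb$conv1, x, dims)))
  h <- gn_fwd(rb$gn2, conv_fwd(rb$conv2, h, dims))
  s <- if (is.null(rb$proj)) x else conv_fwd(rb$proj, x, dims)
  relu_fwd(rb$relu2, h + s)
}

rb_bwd <- function(rb, dy) {
  d <- relu_bwd(rb$relu2, dy)
  dxs <- if (is.null(rb$proj)) d else conv_bwd(rb$proj, d)
  dh <- conv_bwd(rb$conv2, gn_bwd(rb$gn2, d))
  dx <- conv_bwd(rb$conv1, gn_bwd(rb$gn1, relu_bwd(rb$relu1, dh)))
  dx + dxs
}

rb_layers <- function(rb, prefix) {
  out <- list(conv1 = rb$conv1, gn1 = rb$gn1, conv2 = rb$conv2, gn2 = rb$gn2)
  if (!is.null(rb$proj)) out$proj <- rb$proj
  names(out) <- paste0(prefix, ".", names(out))
  out
}
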